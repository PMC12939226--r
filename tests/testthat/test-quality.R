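test_that("colour difference is the CIELAB Euclidean distance", {
  expect_equal(delta_e(c(10, 5, -3), c(10, 5, -3)), 0)
  expect_equal(delta_e(c(3, 4, 0), c(0, 0, 0)), 5)
  # treatment means against the fresh reference
  expect_equal(delta_e(c(29.42, -17.17, 18.07), c(31.82, -21.23, 19.51)),
               sqrt(2.40^2 + 4.06^2 + 1.44^2), tolerance = 1e-3)
})

test_that("colour difference satisfies the metric axioms", {
  set.seed(11)
  for (i in 1:50) {
    a <- rnorm(3, 0, 20); b <- rnorm(3, 0, 20); c <- rnorm(3, 0, 20)
    expect_equal(delta_e(a, b), delta_e(b, a))
    expect_gte(delta_e(a, b) + delta_e(b, c), delta_e(a, c) - 1e-12)
    expect_gte(delta_e(a, b), 0)
  }
})

test_that("Chauvenet criterion rejects the gross outlier and nothing else", {
  x <- c(10, 10.1, 9.9, 10.05, 20)
  kept <- chauvenet_filter(x)
  expect_equal(kept, c(10, 10.1, 9.9, 10.05))
  expect_equal(chauvenet_filter(c(5, 5, 5)), c(5, 5, 5))   # sd = 0 guard
  expect_equal(chauvenet_filter(c(1, 2, 3)), c(1, 2, 3))   # within threshold
  expect_warning(chauvenet_filter(c(1, 2)), "fewer than 3")
  # single-pass idempotence
  expect_equal(chauvenet_filter(kept), kept)
})

test_that("dehiscence rate and amide content follow their formulas", {
  expect_equal(dehiscence_rate(0, 50), 0)
  expect_equal(dehiscence_rate(3, 4), 75)
  expect_equal(dehiscence_rate(17, 17), 100)
  expect_error(dehiscence_rate(1, 0), "positive")
  expect_error(dehiscence_rate(5, 4))
  expect_equal(amide_content(0, 5, 50, 1, 410), 0)
  expect_equal(amide_content(0.41, 5, 50, 1.0, 410), 0.25)
  expect_equal(amide_content(0.41, 10, 50, 1.0, 410),
               2 * amide_content(0.41, 5, 50, 1.0, 410))
  expect_error(amide_content(0.4, 5, 50, 0, 410), "positive")
})

test_that("indicator normalisation maps best to 1 and worst to 0", {
  x <- c(6.73, 3.75, 3.81, 5.59, 4.40, 2.52, 4.37, 5.70, 3.07, 5.44, 5.86, 8.68)
  d <- normalize_indicator(x, "cost")
  expect_equal(d[x == 8.68], 0)
  expect_equal(d[x == 2.52], 1)
  expect_equal(d[x == 3.81], (8.68 - 3.81) / (8.68 - 2.52), tolerance = 1e-12)
  expect_equal(d[x == 3.81], 0.791, tolerance = 1e-3)
  b <- normalize_indicator(c(1, 2, 5), "benefit")
  expect_equal(b, c(0, 0.25, 1))
  expect_warning(dd <- normalize_indicator(c(2, 2, 2), "cost"), "degenerate")
  expect_equal(dd, rep(0.5, 3))
})

test_that("entropy weights match hand computation and behave degenerately", {
  d <- matrix(c(1, 0, 0.5, 0.5), nrow = 2)
  W <- entropy_weights(d)
  expect_equal(unname(W), c(1, 0))
  # identical positive entries -> maximal entropy, zero weight contribution
  d2 <- cbind(c(1, 0, 0.5), c(0.3, 0.3, 0.3))
  W2 <- entropy_weights(d2)
  expect_equal(unname(W2[2]), 0)
  expect_equal(sum(W2), 1)
  expect_warning(W3 <- entropy_weights(matrix(0.4, 3, 2)), "equal weights")
  expect_equal(unname(W3), c(0.5, 0.5))
})

test_that("entropy weights sum to 1 and are permutation-equivariant", {
  set.seed(7)
  for (i in 1:20) {
    d <- matrix(runif(12 * 4), nrow = 12)
    W <- entropy_weights(d)
    expect_equal(sum(W), 1, tolerance = 1e-12)
    expect_true(all(W >= 0))
    pr <- sample(12); pc <- sample(4)
    expect_equal(unname(entropy_weights(d[pr, ])), unname(W), tolerance = 1e-12)
    expect_equal(unname(entropy_weights(d[, pc])), unname(W[pc]), tolerance = 1e-12)
  }
})

test_that("comprehensive score is bounded, linear and monotone", {
  W <- zb_reference_weights()
  expect_equal(sum(W), 1)
  expect_equal(comprehensive_score(rep(1, 4), W)$F, 10)
  expect_equal(comprehensive_score(rep(0, 4), W)$F, 0)
  sc <- comprehensive_score(c(0.791, 0.919, 1.0, 0.996), W)
  expect_equal(sc$F_raw, 0.940, tolerance = 1e-3)
  expect_equal(sc$F, 9.40, tolerance = 1e-2)
  expect_error(comprehensive_score(rep(0.5, 3), W), "same number")
  # improving any indicator never decreases F
  set.seed(3)
  for (i in 1:25) {
    d <- runif(4)
    j <- sample(4, 1)
    d2 <- d; d2[j] <- min(1, d2[j] + runif(1, 0, 0.3))
    expect_gte(comprehensive_score(d2, W)$F_raw,
               comprehensive_score(d, W)$F_raw - 1e-12)
  }
})

test_that("the scoring chain runs end to end on the reference table", {
  tab <- quality_table(zb_reference_quality()$table)
  sc_ref <- score_quality(tab, "reference")
  expect_equal(nrow(sc_ref$scores), 12)
  expect_true(all(sc_ref$d >= 0 & sc_ref$d <= 1))
  expect_true(all(sc_ref$scores$F >= 0 & sc_ref$scores$F <= 10))
  sc_ent <- score_quality(tab, "entropy")
  expect_equal(sum(sc_ent$weights), 1, tolerance = 1e-12)
  # the two weighting schemes are distinct, never silently mixed
  expect_false(isTRUE(all.equal(unname(sc_ent$weights),
                                unname(sc_ref$weights))))
})
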