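test_that("generators are deterministic under a fixed seed", {
  spec <- synthetic_spec("MVD", seed = 42)
  expect_identical(generate_drying_curve(spec, 50),
                   generate_drying_curve(spec, 50))
  expect_identical(generate_temperature_trace(spec, 50),
                   generate_temperature_trace(spec, 50))
  expect_identical(generate_quality_table(seed = 9),
                   generate_quality_table(seed = 9))
  # a different seed perturbs the noise
  spec2 <- synthetic_spec("MVD", seed = 43)
  expect_false(identical(generate_drying_curve(spec, 50)$moisture_db,
                         generate_drying_curve(spec2, 50)$moisture_db))
})

test_that("noise-free curves are exact Page curves and close the fitting loop", {
  spec <- synthetic_spec("MVD", sigma_mr = 0)
  cv <- generate_drying_curve(spec, 50)
  k <- page_rate_constant(spec, 50)
  tmin <- cv$time_h * 60
  expect_equal(moisture_ratio(cv), exp(-k * tmin^spec$n), tolerance = 1e-12)
  # truncation at the target moisture ratio
  mr <- moisture_ratio(cv)
  expect_lte(mr[length(mr)], spec$target_mr)
  expect_gt(mr[length(mr) - 1L], spec$target_mr)
  f <- fit_page(cv)
  expect_equal(f$k, k, tolerance = 1e-6)
  expect_equal(f$n, spec$n, tolerance = 1e-6)
})

test_that("the full generate -> Page -> Arrhenius chain returns the seeded Ea", {
  for (method in c("MVD", "PVD", "HAD")) {
    spec <- synthetic_spec(method, sigma_mr = 0)
    fits <- lapply(spec$temperatures,
                   function(tt) fit_page(generate_drying_curve(spec, tt)))
    a <- fit_arrhenius(fits, spec$temperatures)
    expect_equal(a$Ea, spec$Ea, tolerance = 1e-6)
  }
})

test_that("activation-energy recovery under noise is unbiased and tight", {
  # 20 seeds through the full generate -> Page -> Arrhenius chain at the
  # default gravimetric sampling (5 min); with 13-24 points per curve the
  # per-curve rate-constant noise propagates to a median Ea error below 8%
  # (denser sampling tightens it further; see the methods vignette)
  errs <- vapply(1:20, function(s) {
    spec <- synthetic_spec("MVD", sigma_mr = 0.01, seed = s)
    fits <- lapply(spec$temperatures,
                   function(tt) fit_page(generate_drying_curve(spec, tt)))
    a <- fit_arrhenius(fits, spec$temperatures)
    (a$Ea - spec$Ea) / spec$Ea
  }, numeric(1L))
  expect_lt(median(abs(errs)), 0.08)
  expect_lt(abs(median(errs)), 0.08)     # centred, not biased
})

test_that("temperature traces follow the first-order lag", {
  spec <- synthetic_spec("MVD", sigma_temp = 0)
  tr <- generate_temperature_trace(spec, 50, times_min = c(0, spec$temp_tau, 1e6))
  expect_equal(tr$temp_C[1], 20)
  expect_equal(tr$temp_C[2], 20 + (1 - exp(-1)) * 30, tolerance = 1e-12)
  expect_equal(tr$temp_C[3], 50, tolerance = 1e-9)
})

test_that("the synthetic quality set has the design structure", {
  q <- generate_quality_table(seed = 4)
  expect_equal(nrow(q$table), 12)
  expect_true(all(c("delta_e", "dehiscence_rate", "volatile_oil", "amide")
                  %in% names(q$table)))
  expect_equal(nrow(q$color_replicates), 12 * 5)
  expect_equal(sum(q$indicator_replicates$method == "MVD"), 4 * 4 * 3)
  # zero replicate scatter collapses replicates onto the reference means
  q0 <- generate_quality_table(seed = 4, sd_scale = 0)
  ref <- zb_reference_quality()$table
  expect_equal(q0$table$delta_e, ref$delta_e, tolerance = 1e-12)
  expect_equal(sum(entropy_weights(score_quality(q0$table)$d)), 1,
               tolerance = 1e-12)
})

test_that("a planted +8 sigma colour outlier is removed by Chauvenet and only it", {
  q <- generate_quality_table(seed = 21, inject_color_outlier = TRUE)
  first <- q$color_replicates[q$color_replicates$method == q$table$method[1] &
                              q$color_replicates$temperature == q$table$temperature[1], ]
  kept <- chauvenet_filter(first$L)
  expect_equal(length(kept), 4L)
  expect_false(first$L[1] %in% kept)
  expect_true(all(first$L[-1] %in% kept))
})
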