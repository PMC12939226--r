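test_that("moisture ratio and drying rate follow their definitions", {
  cv <- drying_curve(c(0, 0.5, 1), c(2.03, 1.53, 1.2))
  mr <- moisture_ratio(cv)
  expect_equal(mr[1], 1)
  expect_equal(moisture_ratio(c(2.03, 0.11))[2], 0.11 / 2.03)
  expect_equal(moisture_ratio(c(2.03, 0.11))[2], 0.0542, tolerance = 1e-3)
  dr <- drying_rate(cv)
  expect_equal(dr$DR[1], 1.00)
  expect_equal(dr$time_h, c(0.25, 0.75))
  flat <- drying_curve(c(0, 1, 2), c(1.5, 1.5, 1.5))
  expect_true(all(drying_rate(flat)$DR == 0))
  expect_true(all(moisture_ratio(flat) == 1))
  dec <- drying_curve(c(0, 1, 2, 3), c(2, 1.5, 1.2, 1.1))
  expect_true(all(drying_rate(dec)$DR >= 0))
})

test_that("drying-rate integral is consistent with the moisture loss", {
  t <- seq(0, 5, by = 0.02)
  m <- 2.03 * exp(-0.9 * t)
  cv <- drying_curve(t, m)
  dr <- drying_rate(cv)
  integral <- sum(dr$DR * diff(t))
  expect_equal(integral, m[1] - m[length(m)], tolerance = 0.01 * m[1])
})

test_that("Page fit recovers generating parameters on noise-free data", {
  t <- seq(0, 300, by = 5)
  # pure exponential special case
  f1 <- fit_page(exp(-0.02 * t), times_min = t)
  expect_equal(f1$k, 0.02, tolerance = 1e-6)
  expect_equal(f1$n, 1, tolerance = 1e-6)
  # forward value and joint round trip at n > 1
  mr <- exp(-0.01 * t^1.2)
  expect_equal(mr[t == 60], 0.2566, tolerance = 1e-3)
  f2 <- fit_page(mr, times_min = t)
  expect_equal(f2$k, 0.01, tolerance = 1e-6)
  expect_equal(f2$n, 1.2, tolerance = 1e-6)
  expect_equal(f2$R2, 1, tolerance = 1e-9)
  expect_lt(f2$RMSE, 1e-8)
})

test_that("Page fit is robust to measurement noise at the stated level", {
  t <- seq(0, 300, length.out = 200)
  mr_true <- exp(-0.01 * t^1.2)
  withr_seed <- function(seed, expr) { set.seed(seed); expr }
  set.seed(42)
  mr <- pmin(1, pmax(1e-6, mr_true + rnorm(200, 0, 0.01)))
  f <- fit_page(mr, times_min = t)
  expect_lt(abs(f$k - 0.01) / 0.01, 0.10)
  expect_lt(abs(f$n - 1.2), 0.05)
})

test_that("Page fit is scale-equivariant in time", {
  t <- seq(0, 200, by = 4)
  mr <- exp(-0.015 * t^1.3)
  f1 <- fit_page(mr, times_min = t)
  c_fac <- 3
  f2 <- fit_page(mr, times_min = t * c_fac)
  expect_equal(f2$n, f1$n, tolerance = 1e-6)
  expect_equal(f2$k, f1$k * c_fac^(-f1$n), tolerance = 1e-6)
})

test_that("Page fit rejects degenerate inputs", {
  expect_error(fit_page(rep(1, 10), times_min = 1:10), "degenerate")
  expect_error(fit_page(c(1, 0.9), times_min = c(0, 10)), "4 points")
})

test_that("Arrhenius fit recovers the generating law", {
  R <- 8.314
  temps <- c(40, 50, 60, 70)
  k <- 100 * exp(-25300 / (R * (temps + 273.15)))
  expect_equal(k[temps == 50], 8.11e-3, tolerance = 5e-3)
  a <- fit_arrhenius(k, temps)
  expect_equal(a$Ea, 25300, tolerance = 1e-6)
  expect_equal(a$k0, 100, tolerance = 1e-6)
  expect_equal(a$R2, 1, tolerance = 1e-9)
  # zero slope -> zero activation energy
  a0 <- fit_arrhenius(rep(0.02, 4), temps)
  expect_equal(a0$Ea, 0, tolerance = 1e-9)
  # closed-form two-point estimate
  a2 <- fit_arrhenius(c(0.01944, 0.0486), c(40, 70))
  Ea2 <- R * log(0.0486 / 0.01944) / (1 / 313.15 - 1 / 343.15)
  expect_equal(a2$Ea, Ea2, tolerance = 1e-9)
  expect_equal(a2$Ea / 1000, 27.28, tolerance = 1e-3)
  expect_error(fit_arrhenius(c(0.01, 0.02), c(50, 50)), "distinct")
})
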