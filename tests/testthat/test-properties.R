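props <- material_properties()

test_that("Antoine saturation pressure matches direct evaluation and is monotone", {
  expect_equal(antoine_saturation_pressure(373.15, props),
               10^(7.8087 - 1007.839 / (373.15 - 166.3583)), tolerance = 1e-12)
  expect_equal(antoine_saturation_pressure(373.15, props), 861.0, tolerance = 1e-3)
  expect_equal(antoine_saturation_pressure(333.15, props), 58.37, tolerance = 1e-3)
  Tgrid <- seq(273, 400, by = 0.5)
  expect_true(all(diff(antoine_saturation_pressure(Tgrid, props)) > 0))
  expect_error(antoine_saturation_pressure(100, props), "Antoine")
})

test_that("moisture diffusivity follows the correlation where positive and is floored elsewhere", {
  # formula value at M = 0.5 (visible with a floor below it)
  p_lowfloor <- material_properties(diffusivity_floor = 1e-12)
  expect_equal(moisture_diffusivity(0.5, 323.15, p_lowfloor),
               1e-9 * (-39.41 * log(0.5) - 8.247) / 323.15, tolerance = 1e-12)
  expect_equal(moisture_diffusivity(0.5, 323.15, p_lowfloor), 5.90e-11,
               tolerance = 1e-3)
  # the correlation is negative at M = 1.5 -> clamped to the floor
  expect_equal(moisture_diffusivity(1.5, 323.15, props), props$diffusivity_floor)
  # exact root of the bracket -> clamped as well
  M_root <- exp(-8.247 / 39.41)
  expect_equal(moisture_diffusivity(M_root, 300, props), props$diffusivity_floor)
  expect_error(moisture_diffusivity(-1, 300, props))
})

test_that("microwave source converts power density and scales with eta", {
  expect_equal(microwave_volumetric_source(material_properties(absorbed_fraction = 1)),
               8.24e6)
  expect_equal(microwave_volumetric_source(material_properties(absorbed_fraction = 0.5)),
               4.12e6)
  # adiabatic heating-rate implication of the full nominal source
  expect_equal(8.24e6 / (1030 * 1569), 5.10, tolerance = 1e-3)
})

test_that("infrared source is Beer-Lambert with conserved flux", {
  p1 <- material_properties(absorbed_fraction = 1)
  expect_equal(infrared_volumetric_source(0, p1), 0.9 * 6540 / 0.002,
               tolerance = 1e-12)
  expect_equal(infrared_volumetric_source(p1$ir_penetration_depth, p1),
               infrared_volumetric_source(0, p1) * exp(-1), tolerance = 1e-12)
  # depth integral equals the absorbed surface flux, for any decay length
  for (delta in c(5e-4, 2e-3, 2e-2)) {
    pd <- material_properties(absorbed_fraction = 1, ir_penetration_depth = delta)
    integral <- stats::integrate(function(z) infrared_volumetric_source(z, pd),
                                 0, Inf, rel.tol = 1e-9)$value
    expect_equal(integral, 0.9 * 6540, tolerance = 1e-6)
  }
})

test_that("chamber pressure honours mode, plateaux, periodicity and smoothness", {
  sched <- pulsation_schedule()
  expect_equal(chamber_pressure(c(0, 1e4), sched, "HAD"), c(101.325, 101.325))
  expect_equal(chamber_pressure(c(0, 1e4), sched, "MVD"), c(10, 10))
  expect_equal(chamber_pressure(450, sched, "PVD"), 10)
  expect_equal(chamber_pressure(1050, sched, "PVD"), 101.325)
  t <- seq(0, 2400, by = 0.5)
  p <- chamber_pressure(t, sched, "PVD")
  expect_equal(p, chamber_pressure(t + 1200, sched, "PVD"), tolerance = 1e-12)
  expect_true(all(p >= 10 - 1e-9) && all(p <= 101.325 + 1e-9))
  # finite slope everywhere (smoothed square wave, no jumps)
  expect_lt(max(abs(diff(p)) / 0.5), (101.325 - 10) / (0.08 * 1200) * 2)
  # C2: second difference stays small relative to a hard switch
  d2 <- diff(p, differences = 2) / 0.5^2
  expect_lt(max(abs(d2)), 1)
})

test_that("property constructors validate their invariants", {
  expect_error(material_properties(density = -1), "positive")
  expect_error(material_properties(absorption_coefficient = 1.2), "0, 1")
  expect_error(pulsation_schedule(vacuum_pressure = 200), "below")
  expect_error(pulsation_schedule(vacuum_duration = -5), "positive")
  expect_silent(material_properties(evaporation_rate_constant = 0))
})
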