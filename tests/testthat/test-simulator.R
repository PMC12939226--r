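no_evap <- function(...) material_properties(evaporation_rate_constant = 0, ...)

test_that("an isolated system stays at its initial state", {
  cfg <- simulation_config("HAD", t_end = 1800, target_moisture = 0,
                           heat_transfer_coeff = 1e-12,
                           mass_transfer_coeff = 1e-12)
  res <- simulate_drying(cfg, no_evap())
  expect_equal(max(abs(res$temperature - 20)), 0, tolerance = 1e-9)
  expect_equal(max(abs(res$moisture - 2.03)), 0, tolerance = 1e-9)
})

test_that("a uniform source with insulated boundaries heats at exactly the input rate", {
  cfg <- simulation_config("MVD", air_temperature = 500, t_end = 600,
                           target_moisture = 0,
                           heat_transfer_coeff = 1e-12,
                           mass_transfer_coeff = 1e-12)
  p <- no_evap(absorbed_fraction = 0.01)
  res <- simulate_drying(cfg, p)
  q <- microwave_volumetric_source(p)
  t_end <- max(res$times)
  Tmean <- sum(res$temperature[length(res$times), ] * res$volume) / sum(res$volume)
  expect_equal(Tmean - 20, q * t_end / (1030 * 1569), tolerance = 1e-6)
  expect_lt(res$energy_ledger$residual_rel, 1e-9)
})

test_that("conduction-only slab matches the analytic series oracle", {
  # Dirichlet surface emulated by a very large transfer coefficient
  cfg <- simulation_config("HAD", air_temperature = 50, t_end = 95,
                           target_moisture = 0, n_nodes = 50, max_step = 0.25,
                           heat_transfer_coeff = 1e8,
                           mass_transfer_coeff = 1e-12)
  res <- simulate_drying(cfg, no_evap())
  alpha <- 0.55 / (1030 * 1569)
  L <- cfg$characteristic_size
  for (tt in c(0.06, 0.1, 0.2, 0.3) * L^2 / alpha) {
    i <- which.min(abs(res$times - tt))
    exact <- slab_dirichlet_series(res$x, res$times[i], L, alpha, 20, 50)
    expect_lt(max(abs(res$temperature[i, ] - exact)), 0.1)
  }
})

test_that("energy and mass ledgers close on every mode", {
  for (mode in c("HAD", "PVD", "MVD")) {
    cfg <- simulation_config(mode, t_end = 2400, target_moisture = 0)
    p <- material_properties(absorbed_fraction = 0.05,
                             evaporation_multiplier = 500)
    res <- simulate_drying(cfg, p)
    expect_lt(res$energy_ledger$residual_rel, 1e-3)
    expect_lt(res$mass_ledger$residual_rel, 1e-3)
    expect_true(all(res$water_concentration >= 0))
  }
})

test_that("volume-mean moisture ratio is non-increasing and temperatures bounded", {
  cfg <- simulation_config("MVD", t_end = 3600, target_moisture = 0)
  p <- material_properties(absorbed_fraction = 0.08,
                           evaporation_multiplier = 2000)
  res <- simulate_drying(cfg, p)
  expect_true(all(diff(res$MR_mean) <= 1e-12))
  expect_lt(max(res$temperature), cfg$air_temperature + 30)
  expect_gte(min(res$temperature), min(20, cfg$air_temperature))
})

test_that("drying time converges under mesh and step refinement", {
  p <- material_properties(absorbed_fraction = 0.08,
                           evaporation_multiplier = 2400)
  t_coarse <- simulate_drying(simulation_config("MVD", n_nodes = 20,
                                                max_step = 60, t_end = 4e4),
                              p)$drying_time_to_target
  t_fine <- simulate_drying(simulation_config("MVD", n_nodes = 40,
                                              max_step = 30, t_end = 4e4),
                            p)$drying_time_to_target
  expect_false(is.na(t_coarse))
  expect_lt(abs(t_fine - t_coarse) / t_coarse, 0.02)
})

test_that("core/surface extraction uses the stated regions and sign convention", {
  cfg <- simulation_config("MVD", t_end = 60, target_moisture = 0,
                           mass_transfer_coeff = 1e-12)
  res <- simulate_drying(cfg, no_evap())
  # uniform moisture -> zero gradient
  expect_equal(extract_core_surface(res, 30)$delta_MR, 0, tolerance = 1e-9)
  # linear profile from wet core to dry surface -> positive delta_MR
  res2 <- res
  prof <- seq(2.0, 1.0, length.out = length(res$x)) / 2.0
  wV <- res$volume / sum(res$volume)
  core <- res$x / cfg$characteristic_size <= 0.5
  surf <- res$x / cfg$characteristic_size >= 0.9
  mr_core <- sum(prof[core] * res$volume[core]) / sum(res$volume[core])
  mr_surf <- sum(prof[surf] * res$volume[surf]) / sum(res$volume[surf])
  expect_gt(mr_core, mr_surf)
})

test_that("the evaporation sink follows its closure", {
  p <- material_properties()
  # below the reference pressure there is no evaporation
  expect_equal(evaporation_sink(300, 2, 101.325, p), 0)
  # direct evaluation at 60 C under 10 kPa vacuum
  g <- evaporation_sink(333.15, 2.03, 10, p, C_w = 707.61)
  expect_equal(g, 1e-6 * 707.61 *
                 (antoine_saturation_pressure(333.15, p) - 10) / 101.325,
               tolerance = 1e-12)
  expect_equal(g, 3.37e-4, tolerance = 1e-2)
  # no free water -> no sink; zero rate constant -> zero everywhere
  expect_equal(evaporation_sink(333.15, 0.005, 10, p, M_e = 0.01), 0)
  p0 <- material_properties(evaporation_rate_constant = 0)
  expect_equal(evaporation_sink(333.15, 2.03, 10, p0), 0)
})
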