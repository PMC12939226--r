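# Shared fixtures: an analytic transient-conduction oracle and cached
# calibrated runs (the calibrations are reused by several acceptance checks).

# Analytic separation-of-variables series for a slab 0..L, insulated at x = 0,
# surface held at T_s (Dirichlet), initial temperature T0.
slab_dirichlet_series <- function(x, t, L, alpha, T0, Ts, n_terms = 60L) {
  lam <- (2 * seq_len(n_terms) - 1) * pi / 2
  vapply(x, function(xx) {
    theta <- sum(2 * (-1)^(seq_len(n_terms) + 1) / lam *
                   cos(lam * xx / L) * exp(-lam^2 * alpha * t / L^2))
    Ts + (T0 - Ts) * theta
  }, numeric(1L))
}

.zb_cache <- new.env(parent = emptyenv())

zb_cached <- function(key, expr) {
  if (!exists(key, envir = .zb_cache)) assign(key, force(expr), envir = .zb_cache)
  get(key, envir = .zb_cache)
}

# Calibrated 50 C MVD run against the noise-free synthetic reference
# (kinetics + temperature trace), shared by the acceptance checks.
zb_mvd_calibration <- function() {
  zb_cached("mvd_cal", {
    spec <- synthetic_spec("MVD", sigma_mr = 0, sigma_temp = 0)
    ref <- generate_drying_curve(spec, 50)
    tr <- generate_temperature_trace(spec, 50)
    cal <- calibrate_source_fraction(simulation_config("MVD"),
                                     material_properties(), ref,
                                     temperature_reference = tr)
    list(cal = cal, ref = ref, trace = tr)
  })
}

zb_had_calibration <- function() {
  zb_cached("had_cal", {
    calibrate_thermal_signature(simulation_config("HAD"),
                                material_properties(),
                                target_gradient = 7, at_time = 1200,
                                parameter = "evap_multiplier")
  })
}

zb_pvd_calibration <- function() {
  zb_cached("pvd_cal", {
    spec <- synthetic_spec("PVD", sigma_mr = 0)
    ref <- generate_drying_curve(spec, 50)
    kin <- calibrate_source_fraction(simulation_config("PVD"),
                                     material_properties(), ref)
    therm <- calibrate_thermal_signature(simulation_config("PVD"), kin$props,
                                         target_gradient = -5, at_time = 1200,
                                         parameter = "ir_penetration_depth")
    list(kin = kin, therm = therm)
  })
}
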