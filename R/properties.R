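# Material properties and closure relations: saturation vapour pressure,
# moisture-dependent diffusivity, volumetric heat sources for the three drying
# modes, and the chamber-pressure pulsation schedule.

#' Material properties of Z. bungeanum pericarp
#'
#' Bundles the physical constants of the homogenised pericarp tissue together
#' with the calibration scalars used by the transport closures. Defaults are
#' the reference operating-parameter set for fresh Sichuan pepper.
#'
#' @param density mass density \eqn{\rho_m}, kg/m^3.
#' @param specific_heat specific heat capacity \eqn{C_p}, J/(kg °C).
#' @param thermal_conductivity thermal conductivity \eqn{k_p}, W/(m °C).
#' @param latent_heat latent heat of evaporation \eqn{L_v}, J/kg.
#' @param liquid_water_concentration initial liquid water concentration
#'   \eqn{C_{w0}}, kg water per m^3 of tissue.
#' @param evaporation_rate_constant dimensionless evaporation rate scalar
#'   \eqn{K_{evap}} multiplying the pressure-deficit sink.
#' @param absorption_coefficient radiative absorption coefficient
#'   \eqn{\kappa \in (0, 1]}.
#' @param radiation_intensity infrared radiant flux \eqn{l_i}, W/m^2.
#' @param microwave_frequency microwave frequency, GHz (metadata; the
#'   dielectric field is never solved).
#' @param dielectric_constant,dielectric_loss relative permittivity
#'   \eqn{\varepsilon'} and loss factor \eqn{\varepsilon''} (metadata).
#' @param antoine_A,antoine_B,antoine_C Antoine constants for
#'   \eqn{\log_{10} p_{sat}(kPa)} with temperature in kelvin.
#' @param diffusivity_scale calibration scalar \eqn{r^2} of the moisture
#'   diffusivity correlation, m^2 K.
#' @param power_density nominal microwave power density for MVD, W per g of
#'   sample.
#' @param absorbed_fraction dimensionless calibration factor \eqn{\eta}
#'   multiplying the nominal source power; refined by
#'   \code{\link{calibrate_source_fraction}}.
#' @param ir_penetration_depth Beer-Lambert decay length \eqn{\delta} of the
#'   infrared absorption, m.
#' @param diffusivity_floor lower bound on the moisture diffusivity, m^2/s,
#'   applied where the empirical correlation is non-positive (it changes sign
#'   at \eqn{M_t \approx 0.81} kg/kg, i.e. over the whole wet regime). The
#'   default is the effective Fickian diffusivity implied by the observed
#'   50 degree MVD drying time for a 2.5 mm berry via the first-term sphere
#'   solution, \eqn{D = -\ln(MR_{target})/t_{dry} \cdot R^2/\pi^2 \approx
#'   2.8 \times 10^{-10}} m^2/s — squarely in the literature range for
#'   high-moisture plant tissue — so internal moisture migration in the wet
#'   regime is self-consistent with the material's own drying kinetics.
#' @param evaporation_multiplier dimensionless multiplier on
#'   \code{evaporation_rate_constant}; unity by default, set by calibration.
#' @return An object of class \code{material_properties} (a validated list).
#' @examples
#' props <- material_properties()
#' antoine_saturation_pressure(373.15, props)
#' @export
material_properties <- function(density = 1030,
                                specific_heat = 1569,
                                thermal_conductivity = 0.55,
                                latent_heat = 2.32e6,
                                liquid_water_concentration = 707.61,
                                evaporation_rate_constant = 1e-6,
                                absorption_coefficient = 0.9,
                                radiation_intensity = 6.54e3,
                                microwave_frequency = 2.45,
                                dielectric_constant = 40,
                                dielectric_loss = 17,
                                antoine_A = 7.8087,
                                antoine_B = 1007.839,
                                antoine_C = -166.3583,
                                diffusivity_scale = 1e-9,
                                power_density = 8,
                                absorbed_fraction = 0.01,
                                ir_penetration_depth = 2e-3,
                                diffusivity_floor = 2.8e-10,
                                evaporation_multiplier = 1) {
  props <- list(
    density = density, specific_heat = specific_heat,
    thermal_conductivity = thermal_conductivity, latent_heat = latent_heat,
    liquid_water_concentration = liquid_water_concentration,
    evaporation_rate_constant = evaporation_rate_constant,
    absorption_coefficient = absorption_coefficient,
    radiation_intensity = radiation_intensity,
    microwave_frequency = microwave_frequency,
    dielectric_constant = dielectric_constant,
    dielectric_loss = dielectric_loss,
    antoine_A = antoine_A, antoine_B = antoine_B, antoine_C = antoine_C,
    diffusivity_scale = diffusivity_scale,
    power_density = power_density,
    absorbed_fraction = absorbed_fraction,
    ir_penetration_depth = ir_penetration_depth,
    diffusivity_floor = diffusivity_floor,
    evaporation_multiplier = evaporation_multiplier
  )
  nonneg <- c("evaporation_rate_constant", "evaporation_multiplier")
  for (nm in setdiff(names(props), "antoine_C")) {
    if (!is.numeric(props[[nm]]) || length(props[[nm]]) != 1L || is.na(props[[nm]]))
      stop_zb("material property '", nm, "' must be a single finite number")
    if (nm %in% nonneg) {
      if (props[[nm]] < 0)
        stop_zb("material property '", nm, "' must be non-negative")
    } else if (props[[nm]] <= 0) {
      stop_zb("material property '", nm, "' must be strictly positive")
    }
  }
  if (absorption_coefficient > 1) stop_zb("absorption_coefficient must lie in (0, 1]")
  if (absorbed_fraction > 1) stop_zb("absorbed_fraction must lie in (0, 1]")
  structure(props, class = "material_properties")
}

#' @export
print.material_properties <- function(x, ...) {
  cat("Material properties (Z. bungeanum pericarp)\n")
  cat(sprintf("  density %.4g kg/m^3, Cp %.4g J/(kg C), k %.3g W/(m C)\n",
              x$density, x$specific_heat, x$thermal_conductivity))
  cat(sprintf("  C_w0 %.5g kg/m^3, Lv %.3g J/kg, K_evap %.3g (x %.3g)\n",
              x$liquid_water_concentration, x$latent_heat,
              x$evaporation_rate_constant, x$evaporation_multiplier))
  cat(sprintf("  eta %.4g, P_mw %.3g W/g, l_i %.4g W/m^2, delta %.3g m\n",
              x$absorbed_fraction, x$power_density, x$radiation_intensity,
              x$ir_penetration_depth))
  invisible(x)
}

#' Vacuum pulsation schedule
#'
#' Periodic pressure programme of the pulsed-vacuum dryer: a vacuum phase
#' followed by an atmospheric phase, repeated, with C2-continuous quintic
#' smoothstep ramps between the two plateaux.
#'
#' @param vacuum_duration duration of the vacuum phase, s.
#' @param atmospheric_duration duration of the atmospheric phase, s.
#' @param vacuum_pressure absolute vacuum-phase pressure, kPa.
#' @param atmospheric_pressure absolute atmospheric-phase pressure, kPa.
#' @param transition_width width of each smoothed transition, as a fraction of
#'   the cycle period.
#' @return An object of class \code{pulsation_schedule}.
#' @examples
#' sched <- pulsation_schedule()
#' chamber_pressure(c(450, 1050), sched, "PVD")
#' @export
pulsation_schedule <- function(vacuum_duration = 900,
                               atmospheric_duration = 300,
                               vacuum_pressure = 10,
                               atmospheric_pressure = 101.325,
                               transition_width = 0.08) {
  if (vacuum_duration <= 0 || atmospheric_duration <= 0)
    stop_zb("phase durations must be positive")
  if (vacuum_pressure >= atmospheric_pressure)
    stop_zb("vacuum_pressure must be below atmospheric_pressure")
  if (transition_width <= 0 || transition_width >= 0.5)
    stop_zb("transition_width must lie in (0, 0.5)")
  structure(list(vacuum_duration = vacuum_duration,
                 atmospheric_duration = atmospheric_duration,
                 vacuum_pressure = vacuum_pressure,
                 atmospheric_pressure = atmospheric_pressure,
                 transition_width = transition_width,
                 period = vacuum_duration + atmospheric_duration),
            class = "pulsation_schedule")
}

#' Saturation vapour pressure (Antoine correlation)
#'
#' \eqn{\log_{10} p = A - B / (C + T)} with \eqn{T} in kelvin and \eqn{p} in
#' kPa. The constant set is the one used throughout the drying model; it is
#' used as given even though it deviates from steam-table values, because the
#' evaporation sink that consumes it is rescaled by the calibrated rate
#' constant anyway.
#'
#' @param T_K absolute temperature, K (vectorised).
#' @param props a \code{\link{material_properties}} object.
#' @return saturation pressure, kPa; strictly increasing in temperature.
#' @export
antoine_saturation_pressure <- function(T_K, props = material_properties()) {
  denom <- props$antoine_C + T_K
  if (any(denom <= 0))
    stop_zb("temperature below the validity of the Antoine correlation (C + T <= 0)")
  10^(props$antoine_A - props$antoine_B / denom)
}

#' Moisture diffusivity of the pericarp
#'
#' Empirical correlation \eqn{D_w = r^2 (-39.41 \ln M_t - 8.247) / T}, floored
#' at \code{props$diffusivity_floor} where the bracket is non-positive (the
#' correlation changes sign at \eqn{M_t = e^{-8.247/39.41} \approx 0.811}
#' kg/kg, i.e. over most of the wet regime). The floor keeps the moisture
#' transport operator parabolic and internal migration alive.
#'
#' @param M_t dry-basis moisture content, kg/kg (vectorised, > 0).
#' @param T_K absolute temperature, K.
#' @param props a \code{\link{material_properties}} object.
#' @return diffusivity, m^2/s.
#' @export
moisture_diffusivity <- function(M_t, T_K, props = material_properties()) {
  if (any(M_t <= 0)) stop_zb("M_t must be strictly positive")
  if (any(T_K <= 0)) stop_zb("T_K must be strictly positive")
  raw <- props$diffusivity_scale * (-39.41 * log(M_t) - 8.247) / T_K
  pmax(props$diffusivity_floor, raw)
}

#' Microwave volumetric heat source (MVD)
#'
#' The absorbed microwave power is modelled as a spatially uniform volumetric
#' source: the nominal power density (W per g of sample) scaled by the
#' calibrated absorbed fraction \eqn{\eta}. The dielectric field expression is
#' deliberately not evaluated: the nominal power density is its macroscopic
#' surrogate and \eqn{\eta} absorbs coupling losses.
#'
#' @param props a \code{\link{material_properties}} object.
#' @return volumetric power, W/m^3.
#' @export
microwave_volumetric_source <- function(props = material_properties()) {
  props$absorbed_fraction * props$power_density * 1000 * props$density
}

#' Infrared volumetric heat source (PVD)
#'
#' Beer-Lambert volumetric deposition of the infrared radiant flux:
#' \eqn{q(z) = \eta \kappa l_i / \delta \; e^{-z/\delta}} at depth \eqn{z}
#' below the irradiated surface. Its depth integral over \eqn{[0, \infty)}
#' equals the absorbed surface flux \eqn{\eta \kappa l_i} (flux conservation).
#'
#' @param z depth below the surface, m (vectorised, >= 0).
#' @param props a \code{\link{material_properties}} object.
#' @return volumetric power, W/m^3.
#' @export
infrared_volumetric_source <- function(z, props = material_properties()) {
  if (any(z < 0)) stop_zb("depth z must be non-negative")
  props$absorbed_fraction * props$absorption_coefficient *
    props$radiation_intensity / props$ir_penetration_depth *
    exp(-z / props$ir_penetration_depth)
}

#' Chamber pressure programme
#'
#' Absolute chamber pressure as a function of time for each drying mode:
#' constant atmospheric for HAD, constant vacuum for MVD, and for PVD a
#' periodic smoothed square wave between the vacuum and atmospheric plateaux
#' with quintic smoothstep ramps (C2 continuity) of width
#' \code{transition_width} x period centred on each phase switch. The cycle
#' starts with the vacuum phase.
#'
#' @param t time since the start of drying, s (vectorised, >= 0).
#' @param schedule a \code{\link{pulsation_schedule}}.
#' @param mode one of \code{"HAD"}, \code{"PVD"}, \code{"MVD"}.
#' @return pressure, kPa.
#' @export
chamber_pressure <- function(t, schedule = pulsation_schedule(),
                             mode = c("PVD", "HAD", "MVD")) {
  mode <- match.arg(mode)
  if (any(t < 0)) stop_zb("t must be non-negative")
  if (mode == "HAD") return(rep(101.325, length(t)))
  if (mode == "MVD") return(rep(schedule$vacuum_pressure, length(t)))
  per <- schedule$period
  w <- schedule$transition_width * per
  half <- w / 2
  phi <- t %% per
  vd <- schedule$vacuum_duration
  # fraction of the way towards the atmospheric plateau
  g <- ifelse(phi < vd - half, 0,
       ifelse(phi < vd + half, smoothstep5((phi - (vd - half)) / w),
       ifelse(phi < per - half, 1,
              1 - smoothstep5((phi - (per - half)) / w))))
  # wrap of the atmospheric -> vacuum ramp into the start of the cycle
  g <- ifelse(phi < half, 1 - smoothstep5((phi + half) / w), g)
  schedule$vacuum_pressure +
    (schedule$atmospheric_pressure - schedule$vacuum_pressure) * g
}

#' Ambient water-vapour partial pressure
#'
#' Partial pressure of water vapour in the drying air, from its absolute
#' humidity, used as the reference pressure of the evaporation sink during
#' hot-air drying (the chamber gas is then mostly dry air, so evaporation is
#' driven by the vapour-pressure deficit, not the total pressure).
#'
#' @param humidity absolute humidity, kg water per kg dry air.
#' @param total_pressure total pressure, kPa.
#' @return vapour partial pressure, kPa.
#' @export
ambient_vapour_pressure <- function(humidity = 0.0098, total_pressure = 101.325) {
  total_pressure * humidity / (0.622 + humidity)
}
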