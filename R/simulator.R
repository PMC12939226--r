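# One-dimensional finite-volume solver for the coupled energy and moisture
# transport equations with mode-specific volumetric heat sources, a
# pressure-deficit evaporation sink and convective boundary conditions.
#
# Discretisation: cell-centred finite volumes on a slab (per unit face area)
# or sphere (full 4*pi solid angle), harmonic-mean interface diffusivities,
# implicit Euler time stepping with Picard iteration on the nonlinear
# closures and adaptive step-size control. The energy and mass ledgers are
# accumulated from the same discrete quantities that enter the linear solves,
# so conservation closes to solver precision by construction.

#' Simulation configuration
#'
#' Drying scenario description for \code{\link{simulate_drying}}.
#'
#' @param mode drying mode: \code{"HAD"} (convective hot air), \code{"PVD"}
#'   (infrared heating under pulsed vacuum) or \code{"MVD"} (microwave
#'   heating under continuous vacuum).
#' @param air_temperature drying set temperature, degrees C (hot-air
#'   temperature for HAD; material set point of the radiant/microwave power
#'   control for PVD/MVD).
#' @param geometry \code{"slab"} (bulk sample layer, symmetric about its
#'   midplane) or \code{"sphere"} (single berry).
#' @param characteristic_size slab half-thickness or sphere radius, m.
#' @param n_nodes number of finite-volume cells (>= 10).
#' @param t_end simulated duration, s.
#' @param max_step maximum time step, s.
#' @param rel_tol,abs_tol relative and absolute tolerances of the implicit
#'   step's successive-substitution convergence test.
#' @param initial_temperature initial temperature, degrees C.
#' @param initial_moisture initial dry-basis moisture content, kg/kg.
#' @param target_moisture volume-mean moisture content at which drying stops,
#'   kg/kg (the safe storage level); set to 0 to disable early termination.
#' @param equilibrium_moisture equilibrium dry-basis moisture content, kg/kg.
#' @param heat_transfer_coeff surface heat-transfer coefficient, W/(m^2 C).
#' @param mass_transfer_coeff surface mass-transfer coefficient, m/s.
#' @param schedule a \code{\link{pulsation_schedule}} (used by PVD; supplies
#'   the vacuum level of MVD).
#' @param wall_temperature effective temperature of the gas/walls the sample
#'   surface exchanges heat with, degrees C. Defaults to
#'   \code{air_temperature} for HAD and MVD and to 25 degrees C for PVD
#'   (the pulsed-vacuum chamber is heated radiatively; its walls sit near
#'   ambient next to the condenser circuit).
#' @param ambient_humidity absolute humidity of the drying air, kg/kg (sets
#'   the vapour-pressure deficit that drives evaporation during HAD).
#' @param condenser_temperature temperature of the condenser/cold trap that
#'   dries the chamber gas of the vacuum modes, degrees C; its saturation
#'   pressure bounds the chamber vapour partial pressure seen by the surface
#'   gas film.
#' @param throttle_band width of the set-point power throttle, degrees C:
#'   volumetric sources ramp smoothly from full power at
#'   \code{air_temperature - throttle_band/2} to zero at
#'   \code{air_temperature + throttle_band/2}, emulating the apparatus'
#'   temperature control.
#' @param seed integer, reserved (the solver is deterministic).
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(mode = c("MVD", "PVD", "HAD"),
                              air_temperature = 50,
                              geometry = c("slab", "sphere"),
                              characteristic_size = if (match.arg(geometry) == "sphere") 2.5e-3 else 1e-2,
                              n_nodes = 30L,
                              t_end = 6 * 3600,
                              max_step = 60,
                              rel_tol = 0.01,
                              abs_tol = 0.001,
                              initial_temperature = 20,
                              initial_moisture = 2.03,
                              target_moisture = 0.11,
                              equilibrium_moisture = 0.01,
                              heat_transfer_coeff = 25,
                              mass_transfer_coeff = 0.025,
                              schedule = pulsation_schedule(),
                              wall_temperature = NULL,
                              ambient_humidity = 0.0098,
                              condenser_temperature = 5,
                              throttle_band = 2,
                              seed = 1L) {
  mode <- match.arg(mode)
  geometry <- match.arg(geometry)
  if (n_nodes < 10L) stop_zb("n_nodes must be at least 10")
  if (t_end <= 0 || max_step <= 0) stop_zb("t_end and max_step must be positive")
  if (target_moisture < 0 || target_moisture >= initial_moisture)
    stop_zb("target_moisture must lie in [0, initial_moisture)")
  if (characteristic_size <= 0) stop_zb("characteristic_size must be positive")
  wall_temperature <- wall_temperature %||%
    (if (mode == "PVD") 25 else air_temperature)
  structure(list(mode = mode, air_temperature = air_temperature,
                 geometry = geometry, characteristic_size = characteristic_size,
                 n_nodes = as.integer(n_nodes), t_end = t_end,
                 max_step = max_step, rel_tol = rel_tol, abs_tol = abs_tol,
                 initial_temperature = initial_temperature,
                 initial_moisture = initial_moisture,
                 target_moisture = target_moisture,
                 equilibrium_moisture = equilibrium_moisture,
                 heat_transfer_coeff = heat_transfer_coeff,
                 mass_transfer_coeff = mass_transfer_coeff,
                 schedule = schedule, wall_temperature = wall_temperature,
                 ambient_humidity = ambient_humidity,
                 condenser_temperature = condenser_temperature,
                 throttle_band = throttle_band, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Volumetric evaporation sink
#'
#' Evaporation rate driven by the deficit between the internal equilibrium
#' vapour pressure and the reference vapour pressure of the surroundings:
#' \eqn{G_{evap} = K_{evap} C_w \max(0, p_{sat}(T) - p_{ref}) / p_{atm}},
#' tapering to zero as the local moisture approaches equilibrium (no free
#' water). The associated volumetric heat sink is \eqn{Q = L_v G_{evap}}.
#'
#' @param T_K local temperature, K (vectorised).
#' @param M local dry-basis moisture content, kg/kg.
#' @param p_ref reference vapour pressure, kPa: the chamber pressure for
#'   vacuum operation, or the ambient vapour partial pressure for hot-air
#'   drying.
#' @param props a \code{\link{material_properties}} object.
#' @param C_w local liquid-water concentration, kg/m^3; computed from M and
#'   the initial state when omitted.
#' @param M_e equilibrium moisture content, kg/kg.
#' @param M0 initial moisture content used to convert M to concentration when
#'   \code{C_w} is omitted.
#' @return volumetric evaporation rate, kg/(m^3 s).
#' @export
evaporation_sink <- function(T_K, M, p_ref, props = material_properties(),
                             C_w = NULL, M_e = 0.01, M0 = 2.03) {
  if (is.null(C_w)) C_w <- M * props$liquid_water_concentration / M0
  drive <- pmax(0, antoine_saturation_pressure(T_K, props) - p_ref) / 101.325
  wet <- pmin(1, pmax(0, (M - M_e) / pmax(M_e, 1e-9)))
  props$evaporation_multiplier * props$evaporation_rate_constant *
    C_w * drive * wet
}

# Mode-resolved reference vapour pressure for the evaporation sink. Under
# vacuum the chamber gas is essentially pure vapour, so the total chamber
# pressure is the reference; in hot air the reference is the vapour partial
# pressure of the drying air.
sink_reference_pressure <- function(t, config) {
  if (config$mode == "HAD") {
    rep(ambient_vapour_pressure(config$ambient_humidity), length(t))
  } else {
    chamber_pressure(t, config$schedule, config$mode)
  }
}

# Set-point power throttle: smooth quintic ramp from full power at
# T_set - band/2 to zero at T_set + band/2, so the controlled plateau sits at
# the set temperature.
source_throttle <- function(T_C, T_set, band) {
  1 - smoothstep5((T_C - T_set) / band + 0.5)
}

#' Simulate a drying run
#'
#' Advances the coupled energy and moisture equations
#' \deqn{\rho_m C_p \partial T/\partial t = \nabla\cdot(k_p \nabla T) + Q_{mode} - L_v G_{evap}}
#' \deqn{\partial C_w/\partial t = \nabla\cdot(D_w \nabla C_w) - G_{evap}}
#' on a 1-D slab or sphere with convective boundary conditions
#' \eqn{-k_p \partial T/\partial n = h_t (T_s - T_a) + L_v J_m} and
#' \eqn{-D_w \partial C_w/\partial n = h_m (C_s - C_e)} (the surface moisture
#' flux \eqn{J_m} carries its latent heat out of the thermal balance).
#' Volumetric sources: none for HAD, Beer-Lambert infrared deposition for
#' PVD, uniform microwave absorption for MVD, both modulated by a smooth
#' set-point throttle. Time integration is implicit Euler with Picard
#' iteration and adaptive step refinement; a step is rejected and retried at
#' half size when the iteration stalls or concentrations turn negative, and
#' the run aborts with a diagnostic state if the step collapses below 1 s.
#' The run stops at \code{t_end} or when the volume-mean moisture reaches
#' \code{target_moisture}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param props a \code{\link{material_properties}} object.
#' @return An object of class \code{simulation_result}: list with the
#'   recorded \code{times} (s), nodal \code{temperature} and
#'   \code{water_concentration} matrices (time x node), node centre
#'   coordinates \code{x} (m), volume weights, summary series
#'   (\code{MR_mean}, \code{T_surface}, \code{T_core}, \code{delta_MR},
#'   \code{chamber_pressure}), \code{drying_time_to_target} (s, NA when the
#'   target is not reached), the cumulative \code{energy_ledger} and
#'   \code{mass_ledger} with closure residuals, and the inputs.
#' @export
simulate_drying <- function(config, props = material_properties()) {
  N <- config$n_nodes
  L <- config$characteristic_size
  xf <- seq(0, L, length.out = N + 1L)
  xc <- (xf[-1L] + xf[-(N + 1L)]) / 2
  if (config$geometry == "sphere") {
    Af <- 4 * pi * xf^2
    V <- 4 * pi / 3 * diff(xf^3)
  } else {
    Af <- rep(1, N + 1L)
    V <- diff(xf)
  }
  dx <- L / N
  A_out <- Af[N + 1L]

  rho_dry <- props$liquid_water_concentration / config$initial_moisture
  Ce <- config$equilibrium_moisture * rho_dry
  kp <- props$thermal_conductivity
  rhoC <- props$density * props$specific_heat
  Lv <- props$latent_heat
  ht <- config$heat_transfer_coeff
  hm <- config$mass_transfer_coeff
  Ta <- config$wall_temperature
  Tset <- config$air_temperature
  Me <- config$equilibrium_moisture

  # nominal (unthrottled) volumetric source profile, W/m^3
  q_nominal <- switch(config$mode,
    HAD = rep(0, N),
    MVD = rep(microwave_volumetric_source(props), N),
    PVD = infrared_volumetric_source(L - xc, props))

  # constant-conductivity heat matrix pieces
  cond_face <- kp * Af[2:N] / dx            # interior face conductances
  kT_surf <- 1 / (dx / (2 * kp) + 1 / ht)   # centre-to-ambient conductance

  T_now <- rep(config$initial_temperature, N)
  C_now <- rep(props$liquid_water_concentration, N)

  cap <- 512L
  times <- numeric(cap)
  Tmat <- matrix(NA_real_, cap, N)
  Cmat <- matrix(NA_real_, cap, N)
  p_series <- numeric(cap)
  n_rec <- 0L
  push <- function(t, Tv, Cv, p) {
    n_rec <<- n_rec + 1L
    if (n_rec > cap) {
      cap <<- cap * 2L
      times <<- c(times, numeric(cap / 2L))
      Tmat <<- rbind(Tmat, matrix(NA_real_, cap / 2L, N))
      Cmat <<- rbind(Cmat, matrix(NA_real_, cap / 2L, N))
      p_series <<- c(p_series, numeric(cap / 2L))
    }
    times[n_rec] <<- t
    Tmat[n_rec, ] <<- Tv
    Cmat[n_rec, ] <<- Cv
    p_series[n_rec] <<- p
  }
  push(0, T_now, C_now, chamber_pressure(0, config$schedule, config$mode))

  E_source <- E_latent <- E_boundary <- 0
  M_evap <- M_boundary <- 0
  E_sens0 <- sum(rhoC * T_now * V)

  t <- 0
  dt <- min(config$max_step, 5)
  maxit <- 40L
  mean_M <- function(Cv) sum(Cv * V) / sum(V) / rho_dry
  target_hit <- config$target_moisture > 0 &&
    mean_M(C_now) <= config$target_moisture
  drying_time <- if (target_hit) 0 else NA_real_

  while (t < config$t_end && is.na(drying_time)) {
    dt <- min(dt, config$t_end - t)
    accepted <- FALSE
    while (!accepted) {
      t_new <- t + dt
      p_ch <- chamber_pressure(t_new, config$schedule, config$mode)
      p_ref <- sink_reference_pressure(t_new, config)

      Tit <- T_now; Cit <- C_now
      Tsol_prev <- T_now; Csol_prev <- C_now
      converged <- FALSE
      rec <- NULL
      for (it in seq_len(maxit)) {
        TK <- Tit + 273.15
        Mit <- pmax(Cit, 1e-9) / rho_dry
        psat <- antoine_saturation_pressure(TK, props)
        drive <- pmax(0, psat - p_ref) / 101.325
        wet <- pmin(1, pmax(0, (Mit - Me) / Me))
        scoef <- props$evaporation_multiplier * props$evaporation_rate_constant *
          drive * wet                              # 1/s, multiplies C_w

        # --- moisture solve (implicit in C) ---
        # The surface flux is the smaller of the liquid-side supply (internal
        # diffusion in series with h_m, Robin form) and the vapour-side
        # carrying capacity h_m (p_atm/p_ch) (rho_sat(T_s) - rho_vapour):
        # the gas film cannot remove more vapour than the saturation deficit
        # admits (this pins a wet surface near its wet-bulb state in hot
        # air), while at low total pressure the film transport is enhanced
        # in proportion to 1/p (vapour diffusivity scaling) and the ambient
        # vapour density is set by the condenser-dried chamber gas.
        D <- moisture_diffusivity(pmax(Mit, 1e-9), TK, props)
        Dface <- 2 * D[1:(N - 1L)] * D[2:N] / (D[1:(N - 1L)] + D[2:N])
        gC <- Dface * Af[2:N] / dx
        kS_surf <- 1 / (dx / (2 * D[N]) + 1 / hm)
        rho_sat_s <- antoine_saturation_pressure(TK[N], props) * 1000 * 0.018 /
          (8.314 * TK[N])
        p_v_amb <- if (config$mode == "HAD") {
          ambient_vapour_pressure(config$ambient_humidity)
        } else {
          min(p_ch, antoine_saturation_pressure(
            config$condenser_temperature + 273.15, props))
        }
        rho_amb <- p_v_amb * 1000 * 0.018 / (8.314 * (Ta + 273.15))
        J_cap <- max(0, hm * (101.325 / p_ch) * (rho_sat_s - rho_amb))
        J_diff_est <- kS_surf * max(Cit[N] - Ce, 0)
        flux_capped <- J_cap < J_diff_est
        lower <- -gC * dt / V[2:N]
        upper <- -gC * dt / V[1:(N - 1L)]
        diagC <- 1 + dt * scoef
        diagC[1:(N - 1L)] <- diagC[1:(N - 1L)] + gC * dt / V[1:(N - 1L)]
        diagC[2:N] <- diagC[2:N] + gC * dt / V[2:N]
        rhsC <- C_now
        if (flux_capped) {
          rhsC[N] <- rhsC[N] - J_cap * A_out * dt / V[N]
        } else {
          diagC[N] <- diagC[N] + kS_surf * A_out * dt / V[N]
          rhsC[N] <- rhsC[N] + kS_surf * A_out * dt / V[N] * Ce
        }
        Csol <- solve_tridiag(lower, diagC, upper, rhsC)

        Jm <- if (flux_capped) J_cap else kS_surf * (Csol[N] - Ce)  # kg/(m^2 s)
        G <- scoef * Csol                          # kg/(m^3 s)

        # --- temperature solve (implicit in T; the throttled source and the
        # saturation-pressure-driven sink are linearised about the current
        # iterate so their stiff temperature feedback lands on the diagonal) ---
        u <- (Tit - Tset) / config$throttle_band + 0.5
        phi <- 1 - smoothstep5(u)
        uc <- pmin(1, pmax(0, u))
        dphi <- -30 * uc^2 * (1 - uc)^2 / config$throttle_band   # d(phi)/dT <= 0
        q0 <- q_nominal * phi
        dq <- q_nominal * dphi
        # d(psat)/dT for the latent-sink linearisation
        dpsat <- psat * log(10) * props$antoine_B / (props$antoine_C + TK)^2
        dsink <- ifelse(drive > 0,
                        Lv * props$evaporation_multiplier *
                          props$evaporation_rate_constant * wet * Csol *
                          dpsat / 101.325, 0)                    # >= 0, W/(m^3 K)
        lowerT <- -cond_face * dt / (rhoC * V[2:N])
        upperT <- -cond_face * dt / (rhoC * V[1:(N - 1L)])
        diagT <- 1 + dt * (dsink - dq) / rhoC
        diagT[1:(N - 1L)] <- diagT[1:(N - 1L)] + cond_face * dt / (rhoC * V[1:(N - 1L)])
        diagT[2:N] <- diagT[2:N] + cond_face * dt / (rhoC * V[2:N])
        diagT[N] <- diagT[N] + kT_surf * A_out * dt / (rhoC * V[N])
        rhsT <- T_now + dt * (q0 - dq * Tit - Lv * G + dsink * Tit) / rhoC
        rhsT[N] <- rhsT[N] + dt * kT_surf * Ta * A_out / (rhoC * V[N])
        Tsol <- solve_tridiag(lowerT, diagT, upperT, rhsT)
        q_eff <- q0 + dq * (Tsol - Tit)
        latent_eff <- Lv * G + dsink * (Tsol - Tit)

        errT <- max(abs(Tsol - Tsol_prev) /
                      (config$rel_tol * pmax(abs(Tsol), 1) + config$abs_tol))
        errC <- max(abs(Csol - Csol_prev) /
                      (config$rel_tol * pmax(abs(Csol), 1) + config$abs_tol))
        Tsol_prev <- Tsol; Csol_prev <- Csol
        if (it >= 2L && max(errT, errC) < 1) {
          rec <- list(q = q_eff, latent = latent_eff, G = G, Jm = Jm,
                      kT = kT_surf, Tsol = Tsol, Csol = Csol, iters = it)
          converged <- TRUE
          break
        }
        om <- if (it <= 4L) 1 else if (it <= 15L) 0.5 else 0.25
        Tit <- Tit + om * (Tsol - Tit)
        Cit <- Cit + om * (Csol - Cit)
      }

      if (!converged || min(Csol_prev) < -1e-9) {
        dt <- dt / 2
        if (dt < 1) {
          stop_zb(sprintf(paste0(
            "implicit step failed to converge at t = %.1f s even at the ",
            "minimum step; diagnostic state: T in [%.2f, %.2f] C, ",
            "C_w in [%.3f, %.3f] kg/m^3"),
            t, min(Tit), max(Tit), min(Cit), max(Cit)))
        }
        next
      }

      # --- accept: ledgers from the same discrete quantities ---
      T_new_v <- rec$Tsol
      C_new_v <- pmax(rec$Csol, 0)
      E_source <- E_source + dt * sum(rec$q * V)
      E_latent <- E_latent + dt * sum(rec$latent * V)
      E_boundary <- E_boundary + dt * rec$kT * (T_new_v[N] - Ta) * A_out
      M_evap <- M_evap + dt * sum(rec$G * V)
      M_boundary <- M_boundary + dt * rec$Jm * A_out

      max_dT <- max(abs(T_new_v - T_now))
      T_now <- T_new_v
      C_now <- C_new_v
      t <- t_new
      push(t, T_now, C_now, p_ch)
      accepted <- TRUE

      if (config$target_moisture > 0 && mean_M(C_now) <= config$target_moisture) {
        m_prev <- mean_M(Cmat[n_rec - 1L, ])
        m_curr <- mean_M(C_now)
        frac <- (m_prev - config$target_moisture) / (m_prev - m_curr)
        drying_time <- times[n_rec - 1L] + frac * dt
      }

      # step-size control: resolve fast transients, grow in quiet phases
      if (max_dT > 2) {
        dt <- max(min(1, config$max_step), dt / 2)
      } else if (rec$iters <= 6L && max_dT < 0.8) {
        dt <- min(config$max_step, dt * 1.5)
      }
    }
  }

  idx <- seq_len(n_rec)
  times <- times[idx]; Tmat <- Tmat[idx, , drop = FALSE]
  Cmat <- Cmat[idx, , drop = FALSE]; p_series <- p_series[idx]

  Mmat <- Cmat / rho_dry
  MR_mat <- Mmat / config$initial_moisture
  wV <- V / sum(V)
  MR_mean <- as.numeric(MR_mat %*% wV)
  # surface temperature extrapolated to the face through the boundary flux
  T_surface <- Tmat[, N] - kT_surf * (Tmat[, N] - Ta) * (dx / 2) / kp
  T_core <- Tmat[, 1L]
  core_mask <- xc / L <= 0.5
  surf_mask <- xc / L >= 0.9
  MR_core <- as.numeric(MR_mat[, core_mask, drop = FALSE] %*%
                          (V[core_mask] / sum(V[core_mask])))
  MR_surface <- as.numeric(MR_mat[, surf_mask, drop = FALSE] %*%
                             (V[surf_mask] / sum(V[surf_mask])))

  sens <- sum(rhoC * T_now * V) - E_sens0
  e_in <- E_source - min(0, E_boundary)   # boundary gain counts as input
  e_resid <- abs(E_source - (sens + E_latent + E_boundary)) /
    max(abs(E_source) + abs(E_boundary), 1e-9)
  water0 <- props$liquid_water_concentration * sum(V)
  water_now <- sum(C_now * V)
  m_resid <- abs((water0 - water_now) - (M_evap + M_boundary)) / water0

  structure(list(
    times = times, temperature = Tmat, water_concentration = Cmat,
    moisture = Mmat, x = xc, volume = V, geometry = config$geometry,
    MR_mean = MR_mean, T_surface = T_surface, T_core = T_core,
    MR_core = MR_core, MR_surface = MR_surface,
    delta_MR = MR_core - MR_surface, chamber_pressure = p_series,
    drying_time_to_target = drying_time,
    energy_ledger = list(source_in = E_source, sensible = sens,
                         latent = E_latent, boundary_loss = E_boundary,
                         residual_rel = e_resid, reference_in = e_in),
    mass_ledger = list(initial_water = water0, remaining_water = water_now,
                       evaporated = M_evap, boundary_flux = M_boundary,
                       residual_rel = m_resid),
    config = config, props = props),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Drying simulation: %s, %s, %d nodes, %.0f s simulated (%d records)\n",
              x$config$mode, x$config$geometry, x$config$n_nodes,
              max(x$times), length(x$times)))
  cat(sprintf("  final mean MR %.4f; drying time to target: %s\n",
              x$MR_mean[length(x$MR_mean)],
              if (is.na(x$drying_time_to_target)) "not reached"
              else sprintf("%.0f s (%.1f min)", x$drying_time_to_target,
                           x$drying_time_to_target / 60)))
  cat(sprintf("  ledger residuals: energy %.2e, mass %.2e (relative)\n",
              x$energy_ledger$residual_rel, x$mass_ledger$residual_rel))
  invisible(x)
}

#' Core and surface moisture-ratio summaries
#'
#' Volume-weighted mean moisture ratio over the core region (normalised
#' coordinate <= 0.5) and the surface shell (>= 0.9), and their difference
#' \eqn{\Delta MR = MR_{core} - MR_{surface}}, the internal moisture-gradient
#' measure. When a time is given the series are linearly interpolated there.
#'
#' @param result a \code{\link{simulate_drying}} result.
#' @param time_s optional time, s; when NULL the full series are returned.
#' @return list with \code{MR_core}, \code{MR_surface}, \code{delta_MR}
#'   (scalars at \code{time_s}, else series).
#' @export
extract_core_surface <- function(result, time_s = NULL) {
  if (is.null(time_s)) {
    return(list(MR_core = result$MR_core, MR_surface = result$MR_surface,
                delta_MR = result$delta_MR))
  }
  f <- function(y) stats::approx(result$times, y, xout = time_s, rule = 2)$y
  list(MR_core = f(result$MR_core), MR_surface = f(result$MR_surface),
       delta_MR = f(result$delta_MR))
}

#' Interpolate summary series of a simulation
#'
#' @param result a \code{\link{simulate_drying}} result.
#' @param time_s times, s.
#' @param what one of \code{"MR_mean"}, \code{"T_surface"}, \code{"T_core"},
#'   \code{"delta_MR"}.
#' @return interpolated values (constant extrapolation beyond the run).
#' @export
interp_series <- function(result, time_s,
                          what = c("MR_mean", "T_surface", "T_core", "delta_MR")) {
  what <- match.arg(what)
  stats::approx(result$times, result[[what]], xout = time_s, rule = 2)$y
}
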