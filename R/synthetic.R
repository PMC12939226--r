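# Deterministic synthetic-data generators that emulate the measurement
# structure of the drying experiments: Page-form drying curves with additive
# Gaussian noise, first-order-lag surface-temperature traces, and the
# 3-method x 4-temperature quality table with replicate scatter.

# Per-method study conditions: apparent activation energy (J/mol), Page
# exponent, and the printed drying-time endpoints (min) at 40 and 70 C from
# which the 50 C anchor time is log-interpolated.
.zb_method_defaults <- list(
  MVD = list(Ea = 25300, n = 1.1, t40 = 150, t70 = 60,  tau = 1.5),
  PVD = list(Ea = 32100, n = 1.2, t40 = 640, t70 = 260, tau = 8),
  HAD = list(Ea = 38700, n = 1.0, t40 = 480, t70 = 75,  tau = 6)
)

#' Synthetic-measurement specification
#'
#' Describes the statistical structure of one method's synthetic data set:
#' Page-model ground truth whose rate constant follows an Arrhenius law across
#' the four drying temperatures, additive Gaussian noise on the moisture
#' ratio, a first-order-lag surface-temperature trace, and replicate counts
#' for the quality table. The per-method defaults anchor the Arrhenius
#' pre-exponential factor so that the 50 degree drying time matches a
#' log-interpolation of the reported drying-time range of that method.
#'
#' @param method one of \code{"MVD"}, \code{"PVD"}, \code{"HAD"}.
#' @param temperatures drying temperatures, degrees C (distinct).
#' @param Ea apparent activation energy of the rate constant, J/mol.
#' @param n Page exponent (dimensionless).
#' @param t50 drying time to the safe moisture level at 50 degrees C, min;
#'   anchors the pre-exponential factor.
#' @param k0 pre-exponential factor, 1/min; computed from \code{Ea} and
#'   \code{t50} when NULL.
#' @param sampling_interval gravimetric sampling interval, min.
#' @param sigma_mr standard deviation of the additive noise on MR.
#' @param sigma_temp standard deviation of the temperature-trace noise, C.
#' @param temp_tau first-order-lag time constant of the heating transient, min.
#' @param initial_temperature,initial_moisture initial state (degrees C,
#'   kg/kg dry basis).
#' @param target_mr moisture ratio at which drying stops (safe moisture level
#'   0.11 kg/kg over initial 2.03 kg/kg).
#' @param replicates_indicator,replicates_color replicate counts for quality
#'   indicators and colour readings.
#' @param seed integer seed; a fixed seed makes every generator output
#'   byte-identical.
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(method = c("MVD", "PVD", "HAD"),
                           temperatures = c(40, 50, 60, 70),
                           Ea = NULL, n = NULL, t50 = NULL, k0 = NULL,
                           sampling_interval = 5,
                           sigma_mr = 0.01,
                           sigma_temp = 0.5,
                           temp_tau = NULL,
                           initial_temperature = 20,
                           initial_moisture = 2.03,
                           target_mr = 0.11 / 2.03,
                           replicates_indicator = 3L,
                           replicates_color = 5L,
                           seed = 1L) {
  method <- match.arg(method)
  def <- .zb_method_defaults[[method]]
  Ea <- Ea %||% def$Ea
  n <- n %||% def$n
  t50 <- t50 %||% (def$t40 * (def$t70 / def$t40)^(1 / 3))
  temp_tau <- temp_tau %||% def$tau
  if (anyDuplicated(temperatures)) stop_zb("temperatures must be distinct")
  if (sigma_mr < 0 || sigma_temp < 0) stop_zb("noise SDs must be non-negative")
  if (is.null(k0)) {
    k50 <- -log(target_mr) / t50^n
    k0 <- k50 * exp(Ea / (8.314 * (50 + 273.15)))
  }
  structure(list(method = method, temperatures = temperatures, Ea = Ea, n = n,
                 k0 = k0, t50 = t50, sampling_interval = sampling_interval,
                 sigma_mr = sigma_mr, sigma_temp = sigma_temp,
                 temp_tau = temp_tau,
                 initial_temperature = initial_temperature,
                 initial_moisture = initial_moisture, target_mr = target_mr,
                 replicates_indicator = as.integer(replicates_indicator),
                 replicates_color = as.integer(replicates_color),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Arrhenius rate constant of a synthetic specification
#'
#' \eqn{k(T) = k_0 \exp(-E_a / (R T))} with T absolute.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param temperature_C drying temperature, degrees C.
#' @return Page rate constant, 1/min.
#' @export
page_rate_constant <- function(spec, temperature_C) {
  spec$k0 * exp(-spec$Ea / (8.314 * (temperature_C + 273.15)))
}

#' Generate a synthetic drying curve
#'
#' Page-model ground truth \eqn{MR = \exp(-k t^n)} sampled on the spec's
#' gravimetric grid, truncated at the first sample where the noise-free curve
#' reaches the target moisture ratio, with additive Gaussian noise clipped to
#' (0, 1]. The initial observation is noise-free (the initial moisture content
#' defines the MR normalisation). Deterministic under the spec's seed.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param temperature drying temperature, degrees C.
#' @return a \code{\link{drying_curve}} (times in hours, dry-basis moisture).
#' @export
generate_drying_curve <- function(spec, temperature) {
  k <- page_rate_constant(spec, temperature)
  t_end <- (-log(spec$target_mr) / k)^(1 / spec$n)
  tmin <- seq(0, t_end + spec$sampling_interval, by = spec$sampling_interval)
  mr_clean <- exp(-k * tmin^spec$n)
  cut <- which(mr_clean <= spec$target_mr)[1L]
  if (!is.na(cut)) {
    tmin <- tmin[seq_len(cut)]
    mr_clean <- mr_clean[seq_len(cut)]
  }
  mr <- with_seed(spec$seed * 1000L + round(temperature), {
    noise <- stats::rnorm(length(tmin), 0, spec$sigma_mr)
    noise[1L] <- 0
    pmin(1, pmax(1e-6, mr_clean + noise))
  })
  drying_curve(times_h = tmin / 60,
               moisture = mr * spec$initial_moisture,
               method = spec$method, temperature = temperature)
}

#' Generate a synthetic surface-temperature trace
#'
#' First-order lag towards the set temperature,
#' \eqn{T(t) = T_{set} - (T_{set} - T_0) e^{-t/\tau}}, with additive Gaussian
#' sensor noise (the initial reading is noise-free), sampled on the same grid
#' as the drying curve. Emulates the rapid initial heating and subsequent
#' plateau of a monitored drying run.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param temperature set temperature, degrees C.
#' @param times_min optional sampling grid, min; defaults to the grid of the
#'   corresponding drying curve.
#' @return data frame of class \code{temperature_trace} with columns
#'   \code{time_min} and \code{temp_C}.
#' @export
generate_temperature_trace <- function(spec, temperature, times_min = NULL) {
  if (is.null(times_min)) {
    times_min <- generate_drying_curve(spec, temperature)$time_h * 60
  }
  clean <- temperature - (temperature - spec$initial_temperature) *
    exp(-times_min / spec$temp_tau)
  temp <- with_seed(spec$seed * 1000L + round(temperature) + 500L, {
    noise <- stats::rnorm(length(times_min), 0, spec$sigma_temp)
    noise[1L] <- 0
    clean + noise
  })
  structure(data.frame(time_min = times_min, temp_C = temp),
            method = spec$method, temperature = temperature,
            class = c("temperature_trace", "data.frame"))
}

#' Reference quality-indicator summary
#'
#' The bundled treatment-level quality summary (mean and SD of replicate
#' assays) for Z. bungeanum dried by MVD, PVD and HAD at 40-70 degrees C:
#' CIELAB colour coordinates, colour difference against the fresh sample,
#' dehiscence rate, volatile-oil content and amide content. Serves as the
#' mean-response profile of the synthetic quality generator and as a worked
#' input for the scoring chain.
#'
#' @return list with \code{fresh} (the fresh-sample CIELAB reference) and
#'   \code{table} (12 treatment rows of means and SDs).
#' @export
zb_reference_quality <- function() {
  tab <- data.frame(
    method = rep(c("MVD", "PVD", "HAD"), each = 4L),
    temperature = rep(c(40, 50, 60, 70), times = 3L),
    L = c(25.94, 28.91, 29.42, 28.74, 30.23, 30.06, 28.19, 29.48,
          28.94, 26.38, 31.35, 26.58),
    a = c(-17.68, -18.24, -17.17, -16.49, -17.72, -18.27, -18.65, -16.63,
          -20.11, -19.30, -16.43, -16.20),
    b = c(16.35, 17.39, 18.07, 16.17, 16.22, 18.41, 16.86, 15.46,
          17.80, 17.48, 14.99, 13.58),
    delta_e = c(6.73, 3.75, 3.81, 5.59, 4.40, 2.52, 4.37, 5.70,
                3.07, 5.44, 5.86, 8.68),
    dehiscence_rate = c(97.87, 98.09, 99.10, 99.31, 91.46, 97.19, 98.20, 98.31,
                        97.10, 98.20, 98.43, 99.77),
    volatile_oil = c(0.90, 1.00, 1.50, 1.00, 0.70, 0.75, 0.75, 0.70,
                     0.80, 0.95, 1.00, 0.90),
    amide = c(25.39, 24.84, 28.63, 23.09, 24.83, 26.28, 28.65, 25.94,
              24.31, 25.48, 27.60, 26.49),
    L_sd = c(0.26, 0.26, 0.35, 0.30, 0.22, 0.06, 0.10, 0.10,
             0.21, 0.22, 0.40, 0.94),
    a_sd = c(0.31, 0.32, 0.09, 0.35, 0.24, 0.18, 0.19, 0.40,
             0.29, 0.15, 0.35, 0.40),
    b_sd = c(0.34, 0.17, 0.21, 0.09, 0.02, 0.37, 0.09, 0.37,
             0.16, 0.19, 0.12, 0.38),
    delta_e_sd = c(0.18, 0.24, 0.16, 0.24, 0.20, 0.20, 0.07, 0.29,
                   0.21, 0.29, 0.34, 1.22),
    dehiscence_rate_sd = c(0.63, 0.36, 0.76, 0.58, 0.73, 0.34, 0.52, 0.24,
                           0.26, 0.59, 0.78, 0.16),
    volatile_oil_sd = c(0.14, 0.06, 0.09, 0.02, 0.04, 0.05, 0.04, 0.05,
                        0.04, 0.06, 0.07, 0.03),
    amide_sd = c(0.33, 0.28, 0.22, 0.36, 0.19, 0.20, 0.56, 0.41,
                 0.31, 0.29, 0.43, 0.44),
    stringsAsFactors = FALSE
  )
  list(fresh = c(L = 31.82, a = -21.23, b = 19.51), table = tab)
}

#' Generate a synthetic quality data set
#'
#' Draws replicate-level quality measurements around the reference
#' mean-response profile (convex colour-difference response in temperature,
#' monotone dehiscence, oil/amide peaking at 60 degrees C) with Gaussian
#' replicate scatter at the reference SD magnitudes: triplicate indicator
#' assays and quintuplicate CIELAB readings per treatment. Optionally injects
#' a single gross colour outlier for testing outlier rejection. Deterministic
#' under the seed.
#'
#' @param seed integer seed.
#' @param sd_scale multiplier on all replicate SDs (0 gives replicates equal
#'   to the means).
#' @param inject_color_outlier if TRUE, the first colour replicate of the
#'   first treatment has its L* reading displaced by
#'   \code{outlier_sd} x its SD.
#' @param outlier_sd displacement of the injected outlier, in SD units.
#' @param replicates_indicator,replicates_color replicate counts.
#' @return list with \code{table} (a \code{\link{quality_table}} of replicate
#'   means with SD columns), \code{indicator_replicates} and
#'   \code{color_replicates} (long data frames), and \code{fresh}.
#' @export
generate_quality_table <- function(seed = 1L, sd_scale = 1,
                                   inject_color_outlier = FALSE,
                                   outlier_sd = 8,
                                   replicates_indicator = 3L,
                                   replicates_color = 5L) {
  ref <- zb_reference_quality()
  tab <- ref$table
  indicators <- c("delta_e", "dehiscence_rate", "volatile_oil", "amide")
  with_seed(seed, {
    ind_rep <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      do.call(rbind, lapply(indicators, function(col) {
        vals <- stats::rnorm(replicates_indicator, tab[[col]][i],
                             sd_scale * tab[[paste0(col, "_sd")]][i])
        data.frame(method = tab$method[i], temperature = tab$temperature[i],
                   indicator = col, replicate = seq_len(replicates_indicator),
                   value = pmax(vals, 0))
      }))
    }))
    col_rep <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      data.frame(method = tab$method[i], temperature = tab$temperature[i],
                 replicate = seq_len(replicates_color),
                 L = stats::rnorm(replicates_color, tab$L[i], sd_scale * tab$L_sd[i]),
                 a = stats::rnorm(replicates_color, tab$a[i], sd_scale * tab$a_sd[i]),
                 b = stats::rnorm(replicates_color, tab$b[i], sd_scale * tab$b_sd[i]))
    }))
    if (inject_color_outlier) {
      sd1 <- max(sd_scale * tab$L_sd[1L], 0.1)
      col_rep$L[1L] <- tab$L[1L] + outlier_sd * sd1
    }
    means <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      sub <- ind_rep[ind_rep$method == tab$method[i] &
                     ind_rep$temperature == tab$temperature[i], ]
      row <- data.frame(method = tab$method[i], temperature = tab$temperature[i])
      for (col in indicators) {
        v <- sub$value[sub$indicator == col]
        row[[col]] <- mean(v)
        row[[paste0(col, "_sd")]] <- stats::sd(v)
      }
      row
    }))
    list(table = quality_table(means), indicator_replicates = ind_rep,
         color_replicates = col_rep, fresh = ref$fresh)
  })
}
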