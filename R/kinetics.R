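# Thin-layer drying kinetics: moisture-ratio and drying-rate transforms,
# Page-model fitting and Arrhenius activation-energy estimation.

#' Drying curve container
#'
#' A time series of dry-basis moisture content (and optionally surface
#' temperature) for one drying run. Times are stored in hours with the first
#' observation at t = 0.
#'
#' @param times_h observation times, h; strictly increasing, first element 0.
#' @param moisture dry-basis moisture content, kg/kg; all non-negative,
#'   first element positive.
#' @param surface_temperature optional surface temperature, degrees C.
#' @param method drying-method label (e.g. "MVD").
#' @param temperature drying-temperature label, degrees C.
#' @return A data frame of class \code{drying_curve} with columns
#'   \code{time_h}, \code{moisture_db} and optionally \code{temp_C}, and
#'   attributes \code{method} and \code{temperature}.
#' @export
drying_curve <- function(times_h, moisture, surface_temperature = NULL,
                         method = NA_character_, temperature = NA_real_) {
  if (length(times_h) != length(moisture))
    stop_zb("times and moisture must have equal length")
  if (length(times_h) < 2L) stop_zb("a drying curve needs at least two points")
  if (times_h[1L] != 0) stop_zb("the first observation must be at time 0")
  if (any(diff(times_h) <= 0)) stop_zb("times must be strictly increasing")
  if (moisture[1L] <= 0) stop_zb("initial moisture must be positive")
  if (any(moisture < 0)) stop_zb("moisture must be non-negative")
  df <- data.frame(time_h = times_h, moisture_db = moisture)
  if (!is.null(surface_temperature)) {
    if (length(surface_temperature) != length(times_h))
      stop_zb("surface_temperature must match the time grid")
    df$temp_C <- surface_temperature
  }
  structure(df, method = method, temperature = temperature,
            class = c("drying_curve", "data.frame"))
}

#' @export
print.drying_curve <- function(x, ...) {
  cat(sprintf("Drying curve: %s at %s C, %d points over %.2f h, M0 = %.3f kg/kg\n",
              attr(x, "method"), format(attr(x, "temperature")), nrow(x),
              max(x$time_h), x$moisture_db[1L]))
  invisible(x)
}

#' Moisture ratio
#'
#' Dimensionless drying progress \eqn{MR_t = M_t / M_0}; equals 1 at t = 0.
#'
#' @param curve a \code{\link{drying_curve}}, or a numeric vector of dry-basis
#'   moisture contents whose first element is the initial moisture.
#' @return numeric vector of moisture ratios.
#' @export
moisture_ratio <- function(curve) {
  m <- if (inherits(curve, "drying_curve")) curve$moisture_db else as.numeric(curve)
  if (m[1L] <= 0) stop_zb("initial moisture must be positive")
  m / m[1L]
}

#' Drying rate
#'
#' Finite-difference drying rate over each consecutive interval,
#' \eqn{DR = (M_{t_1} - M_{t_2}) / (t_2 - t_1)}, reported at interval
#' midpoints.
#'
#' @param curve a \code{\link{drying_curve}}.
#' @return data frame with columns \code{time_h} (interval midpoint) and
#'   \code{DR} (kg/kg per h).
#' @export
drying_rate <- function(curve) {
  t <- curve$time_h
  m <- curve$moisture_db
  if (any(diff(t) == 0)) stop_zb("repeated time stamps")
  data.frame(time_h = (t[-1L] + t[-length(t)]) / 2,
             DR = -diff(m) / diff(t))
}

#' Fit the Page thin-layer model
#'
#' Nonlinear least squares of \eqn{MR = \exp(-k t^n)} with \eqn{t} in minutes.
#' Starting values come from the log-log linearisation
#' \eqn{\ln(-\ln MR) = \ln k + n \ln t} over interior points (MR values >= 1,
#' which can occur under measurement noise, are clipped to 1 - 1e-9 for the
#' initialiser only, never for the objective).
#'
#' @param curve a \code{\link{drying_curve}} (times converted from hours to
#'   minutes internally) or a numeric vector of moisture ratios.
#' @param times_min observation times in minutes; required when \code{curve}
#'   is a plain MR vector, ignored otherwise.
#' @return An object of class \code{page_fit}: list with rate constant
#'   \code{k} (1/min), exponent \code{n}, \code{R2} and \code{RMSE}.
#' @export
fit_page <- function(curve, times_min = NULL) {
  if (inherits(curve, "drying_curve")) {
    mr <- moisture_ratio(curve)
    times_min <- curve$time_h * 60
  } else {
    mr <- as.numeric(curve)
    if (is.null(times_min)) stop_zb("times_min is required for a plain MR vector")
  }
  keep <- is.finite(mr) & is.finite(times_min) & mr > 0
  mr <- mr[keep]; tmin <- times_min[keep]
  if (length(mr) < 4L) stop_zb("at least 4 points with MR in (0, 1] are required")
  if (all(mr >= 1)) stop_zb("degenerate fit: no drying in the data (all MR >= 1)")

  interior <- tmin > 0 & mr < 1 & mr > 0
  mr_init <- pmin(mr, 1 - 1e-9)
  ll <- stats::lm(log(-log(mr_init[interior])) ~ log(tmin[interior]))
  n0 <- min(4, max(0.2, stats::coef(ll)[[2L]]))
  k0 <- exp(stats::coef(ll)[[1L]])

  dat <- data.frame(mr = mr, t = tmin)
  fit <- minpack.lm::nlsLM(mr ~ exp(-k * t^n), data = dat,
                           start = list(k = k0, n = n0),
                           lower = c(k = 1e-10, n = 0.2),
                           upper = c(k = 1e3, n = 4),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  pred <- stats::predict(fit)
  res <- mr - pred
  r2 <- 1 - sum(res^2) / sum((mr - mean(mr))^2)
  structure(list(k = stats::coef(fit)[["k"]], n = stats::coef(fit)[["n"]],
                 R2 = r2, RMSE = sqrt(mean(res^2)), n_points = length(mr)),
            class = "page_fit")
}

#' @export
print.page_fit <- function(x, ...) {
  cat(sprintf("Page fit: k = %.5g 1/min, n = %.4f (R2 = %.4f, RMSE = %.4g, %d points)\n",
              x$k, x$n, x$R2, x$RMSE, x$n_points))
  invisible(x)
}

#' Arrhenius fit of Page rate constants
#'
#' Ordinary least squares of \eqn{\ln k} on \eqn{1/T} (T absolute): the
#' apparent activation energy is \eqn{E_a = -\mathrm{slope} \cdot R} with
#' \eqn{R = 8.314} J/(mol K), and the pre-exponential factor is
#' \eqn{k_0 = e^{\mathrm{intercept}}}.
#'
#' @param fits a list of \code{page_fit} objects, or a numeric vector of rate
#'   constants (1/min).
#' @param temperatures_C drying temperatures, degrees C (same length, at least
#'   two distinct values).
#' @return An object of class \code{arrhenius_fit}: list with \code{k0}
#'   (1/min), \code{Ea} (J/mol) and \code{R2}.
#' @export
fit_arrhenius <- function(fits, temperatures_C) {
  k <- if (is.list(fits)) vapply(fits, function(f) f$k, numeric(1L)) else as.numeric(fits)
  if (length(k) != length(temperatures_C))
    stop_zb("rate constants and temperatures must have equal length")
  if (length(unique(temperatures_C)) < 2L)
    stop_zb("at least two distinct temperatures are required")
  if (any(k <= 0)) stop_zb("all rate constants must be positive")
  R <- 8.314
  invT <- 1 / (temperatures_C + 273.15)
  fit <- stats::lm(log(k) ~ invT)
  slope <- stats::coef(fit)[[2L]]
  res <- stats::residuals(fit)
  ss_tot <- sum((log(k) - mean(log(k)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  structure(list(k0 = exp(stats::coef(fit)[[1L]]), Ea = -slope * R, R2 = r2),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit: Ea = %.4g kJ/mol, k0 = %.5g 1/min (R2 = %.4f)\n",
              x$Ea / 1000, x$k0, x$R2))
  invisible(x)
}
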