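# Goodness-of-fit metrics for simulation-vs-reference comparison and the
# Pearson correlation matrix of quality indicators.

#' Goodness of fit between observed and predicted series
#'
#' Coefficient of determination \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, root mean
#' square error, and the maximum relative deviation (in percent) over points
#' whose observed magnitude exceeds \code{eps}.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @param label optional series label carried into the report.
#' @param eps magnitude guard for the relative deviation.
#' @return list of class \code{fit_report} with \code{R2}, \code{RMSE},
#'   \code{max_rel_dev_pct}, \code{n} and \code{label}. A constant observed
#'   series has no defined R2 (returned as NaN with a warning).
#' @export
r2_rmse <- function(observed, predicted, label = NA_character_, eps = 1e-8) {
  if (length(observed) != length(predicted))
    stop_zb("observed and predicted must have equal length")
  if (length(observed) < 2L) stop_zb("at least 2 points are required")
  res <- observed - predicted
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("constant observed series: R2 is undefined")
    r2 <- NaN
  } else {
    r2 <- 1 - sum(res^2) / ss_tot
  }
  big <- abs(observed) > eps
  mrd <- if (any(big)) 100 * max(abs(res[big]) / abs(observed[big])) else NA_real_
  structure(list(label = label, R2 = r2, RMSE = sqrt(mean(res^2)),
                 max_rel_dev_pct = mrd, n = length(observed)),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("Fit report%s: R2 = %.4f, RMSE = %.4g, max rel dev = %.2f%% (n = %d)\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$R2, x$RMSE, x$max_rel_dev_pct, x$n))
  invisible(x)
}

#' Pearson correlation matrix with significance flags
#'
#' Pairwise Pearson correlations between numeric columns, with two-sided
#' p-values from the t transform \eqn{t = r \sqrt{(n-2)/(1-r^2)}} and
#' significance flags at the 0.05 and 0.01 levels. No multiplicity correction
#' is applied. Zero-variance columns yield NaN correlations for their pairs.
#'
#' @param data data frame (or matrix) of treatment-level values; non-numeric
#'   columns are dropped. At least 3 rows.
#' @return list of class \code{pearson_matrix} with matrices \code{r},
#'   \code{p}, \code{sig05}, \code{sig01} and the sample size \code{n}.
#' @export
pearson_matrix <- function(data) {
  num <- as.data.frame(data)[vapply(as.data.frame(data), is.numeric, logical(1L))]
  n <- nrow(num)
  if (n < 3L) stop_zb("at least 3 rows are required")
  m <- as.matrix(num)
  sds <- apply(m, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  r[, sds == 0] <- NaN
  r[sds == 0, ] <- NaN
  diag(r)[sds > 0] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  structure(list(r = r, p = p, sig05 = p < 0.05, sig01 = p < 0.01, n = n),
            class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, ...) {
  cat(sprintf("Pearson correlations over %d treatments ('*' p<0.05, '**' p<0.01):\n", x$n))
  stars <- ifelse(x$sig01, "**", ifelse(x$sig05, "*", ""))
  out <- matrix(paste0(formatC(x$r, digits = 3, format = "f"), stars),
                nrow = nrow(x$r), dimnames = dimnames(x$r))
  print(out, quote = FALSE)
  invisible(x)
}
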