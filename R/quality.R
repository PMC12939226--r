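# Quality indicators and the multi-criteria comprehensive score:
# CIELAB colour difference, Chauvenet outlier rejection, dehiscence rate,
# amide content, min-max normalisation, entropy weighting and the F index.

#' CIELAB colour difference
#'
#' Euclidean distance in (L*, a*, b*) space between a dried sample and the
#' fresh-sample reference.
#'
#' @param sample,reference numeric vectors \code{c(L, a, b)} (names optional).
#' @return \eqn{\Delta E}, dimensionless.
#' @examples
#' delta_e(c(29.42, -17.17, 18.07), c(31.82, -21.23, 19.51))
#' @export
delta_e <- function(sample, reference) {
  s <- as.numeric(sample); r <- as.numeric(reference)
  if (length(s) != 3L || length(r) != 3L)
    stop_zb("sample and reference must be (L, a, b) triples")
  sqrt(sum((s - r)^2))
}

#' Chauvenet outlier rejection
#'
#' Single-pass Chauvenet criterion: a replicate x is rejected when
#' \eqn{n \, \mathrm{erfc}(|x - \bar{x}| / (\sigma \sqrt{2})) < 0.5}, i.e.
#' when fewer than half an observation is expected that far from the mean
#' under normality. The criterion is not re-iterated after rejection and at
#' least two values are always retained.
#'
#' @param values numeric vector of replicate measurements (>= 3 for the
#'   criterion to apply; shorter inputs are returned unchanged with a
#'   warning).
#' @return the retained values, in their original order.
#' @export
chauvenet_filter <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) {
    warning("fewer than 3 values: Chauvenet criterion not applied")
    return(values)
  }
  s <- stats::sd(values)
  if (s == 0) return(values)
  z <- abs(values - mean(values)) / s
  keep <- n * erfc(z / sqrt(2)) >= 0.5
  if (sum(keep) < 2L) {
    keep <- rank(z, ties.method = "first") <= 2L
  }
  values[keep]
}

#' Dehiscence rate
#'
#' Percentage of pericarps that have split open after drying,
#' \eqn{\mu = 100 N_0 / N_t}.
#'
#' @param n_dehiscent number of dehiscent units \eqn{N_0}.
#' @param n_total total number of counted specimens \eqn{N_t} (> 0).
#' @return percentage in [0, 100].
#' @export
dehiscence_rate <- function(n_dehiscent, n_total) {
  if (any(n_total <= 0)) stop_zb("n_total must be positive")
  if (any(n_dehiscent < 0) || any(n_dehiscent > n_total))
    stop_zb("n_dehiscent must lie in [0, n_total]")
  100 * n_dehiscent / n_total
}

#' Amide content from UV absorbance
#'
#' \eqn{X = A K V / (m E)}: absorbance of the diluted methanol extract, scaled
#' by the dilution factor and extract volume and normalised by sample mass and
#' the molar absorptivity of the target amides.
#'
#' @param A absorbance of the diluted extract (270 nm).
#' @param K supernatant dilution factor.
#' @param V extract volume, mL.
#' @param m sample mass, g (> 0).
#' @param E molar absorptivity, L/(g cm) (> 0).
#' @return amide content, mg/g.
#' @export
amide_content <- function(A, K, V, m, E) {
  if (any(m <= 0)) stop_zb("sample mass m must be positive")
  if (any(E <= 0)) stop_zb("absorptivity E must be positive")
  A * K * V / (m * E)
}

#' Min-max normalisation of a quality indicator
#'
#' Cost indicators (lower is better, e.g. colour difference) use
#' \eqn{d_i = (X_{max} - X_i) / (X_{max} - X_{min})}; benefit indicators use
#' \eqn{d_i = (X_i - X_{min}) / (X_{max} - X_{min})}. Either way the best
#' treatment maps to 1 and the worst to 0.
#'
#' @param x numeric vector of indicator values across treatments.
#' @param direction \code{"cost"} or \code{"benefit"}.
#' @return normalised values in [0, 1]; a constant column is degenerate and
#'   returns 0.5 everywhere with a warning.
#' @export
normalize_indicator <- function(x, direction = c("cost", "benefit")) {
  direction <- match.arg(direction)
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    warning("constant indicator column: normalisation is degenerate, returning 0.5")
    return(rep(0.5, length(x)))
  }
  if (direction == "cost") (rng[2L] - x) / diff(rng) else (x - rng[1L]) / diff(rng)
}

#' Entropy weights
#'
#' Objective indicator weights from the information entropy of the normalised
#' matrix: \eqn{p_{ij} = d_{ij} / \sum_i d_{ij}},
#' \eqn{E_j = -(\ln m)^{-1} \sum_i p_{ij} \ln p_{ij}} (with
#' \eqn{0 \ln 0 := 0}), and \eqn{W_j = (1 - E_j) / \sum_j (1 - E_j)}. A
#' uniform column has maximal entropy and receives zero weight; an all-zero
#' column is treated as maximally entropic (zero weight) as well.
#'
#' @param d numeric matrix of normalised indicators, treatments in rows.
#' @return named numeric vector of weights summing to 1.
#' @export
entropy_weights <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) stop_zb("at least 2 treatment rows are required")
  if (any(d < 0)) stop_zb("normalised values must be non-negative")
  m <- nrow(d)
  E <- apply(d, 2L, function(col) {
    s <- sum(col)
    if (s <= 0) return(1)           # degenerate: no information
    p <- col / s
    plogp <- ifelse(p > 0, p * log(p), 0)
    -sum(plogp) / log(m)
  })
  one_minus <- 1 - E
  one_minus[one_minus < 1e-12] <- 0
  if (sum(one_minus) <= 0) {
    warning("all columns are maximally entropic; returning equal weights")
    w <- rep(1 / ncol(d), ncol(d))
  } else {
    w <- one_minus / sum(one_minus)
  }
  stats::setNames(w, colnames(d))
}

#' Comprehensive quality score (F index)
#'
#' Weighted sum of the normalised indicators, \eqn{F = \sum_j d_j W_j},
#' reported both raw (in [0, 1] when the weights sum to 1) and on the 0-10
#' display scale on which published comprehensive scores are quoted.
#'
#' @param d numeric vector (one treatment) or matrix (treatments in rows) of
#'   normalised indicators.
#' @param W weight vector; must match the number of indicators and sum to 1
#'   (tolerance 1e-6).
#' @return data frame with columns \code{F_raw} and \code{F} (display scale,
#'   = 10 x raw).
#' @export
comprehensive_score <- function(d, W) {
  d <- if (is.matrix(d) || is.data.frame(d)) as.matrix(d) else matrix(d, nrow = 1L)
  if (ncol(d) != length(W)) stop_zb("d and W must have the same number of indicators")
  if (abs(sum(W) - 1) > 1e-6) stop_zb("weights must sum to 1")
  raw <- as.numeric(d %*% W)
  data.frame(F_raw = raw, F = 10 * raw)
}

#' Published indicator weights
#'
#' The reference weighting coefficients for colour difference, dehiscence
#' rate, volatile-oil content and amide content used for comprehensive
#' scoring. Shipped as constants for reproducible ranking;
#' \code{\link{entropy_weights}} computes self-derived weights instead and the
#' two are never mixed.
#'
#' @return named numeric vector summing to 1.
#' @export
zb_reference_weights <- function() {
  c(delta_e = 0.21, dehiscence_rate = 0.18, volatile_oil = 0.22, amide = 0.39)
}

#' Quality table container
#'
#' Per-treatment quality indicators with a direction flag per indicator
#' column. Colour difference is a cost indicator (lower is better); dehiscence
#' rate, volatile-oil content and amide content are benefit indicators.
#'
#' @param df data frame with columns \code{method}, \code{temperature} and the
#'   indicator columns.
#' @param directions named character vector mapping indicator columns to
#'   \code{"cost"} or \code{"benefit"}.
#' @return a \code{quality_table} (data frame with a \code{directions}
#'   attribute).
#' @export
quality_table <- function(df,
                          directions = c(delta_e = "cost",
                                         dehiscence_rate = "benefit",
                                         volatile_oil = "benefit",
                                         amide = "benefit")) {
  if (nrow(df) < 2L) stop_zb("a quality table needs at least 2 treatment rows")
  missing_cols <- setdiff(names(directions), names(df))
  if (length(missing_cols))
    stop_zb("missing indicator columns: ", paste(missing_cols, collapse = ", "))
  if (!all(directions %in% c("cost", "benefit")))
    stop_zb("directions must be 'cost' or 'benefit'")
  structure(df, directions = directions,
            class = c("quality_table", "data.frame"))
}

#' Score a quality table
#'
#' Runs the full scoring chain: per-indicator min-max normalisation (with the
#' table's direction flags), indicator weights (either the published reference
#' set or entropy weights computed from the normalised matrix), and the F
#' index per treatment.
#'
#' @param table a \code{\link{quality_table}}.
#' @param weights \code{"reference"} for the published constants,
#'   \code{"entropy"} for self-computed entropy weights, or a named numeric
#'   vector summing to 1.
#' @return list of class \code{score_result} with the normalised matrix
#'   \code{d}, the \code{weights} used, per-column entropy (when computed) and
#'   a \code{scores} data frame (method, temperature, F_raw, F) sorted as the
#'   input.
#' @export
score_quality <- function(table, weights = c("reference", "entropy")) {
  dirs <- attr(table, "directions")
  if (is.null(dirs)) stop_zb("table must be a quality_table with direction flags")
  d <- vapply(names(dirs),
              function(nm) normalize_indicator(table[[nm]], dirs[[nm]]),
              numeric(nrow(table)))
  d <- matrix(d, nrow = nrow(table), dimnames = list(NULL, names(dirs)))
  entropy <- NULL
  if (is.character(weights)) {
    weights <- match.arg(weights)
    if (weights == "reference") {
      W <- zb_reference_weights()
      if (!all(names(dirs) %in% names(W)))
        stop_zb("reference weights are only defined for the standard indicator set")
      W <- W[names(dirs)]
    } else {
      W <- entropy_weights(d)
    }
  } else {
    W <- weights[names(dirs)]
    if (anyNA(W)) stop_zb("custom weights must name every indicator column")
  }
  sc <- comprehensive_score(d, W)
  scores <- cbind(table[, intersect(c("method", "temperature"), names(table)),
                        drop = FALSE], sc)
  structure(list(d = d, weights = W, entropy = entropy, scores = scores),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat("Comprehensive quality scores (F, 0-10 scale):\n")
  print(x$scores, row.names = FALSE)
  cat("weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                        collapse = ", "), "\n")
  invisible(x)
}
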