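# Internal numerical helpers shared across modules.

#' Quintic smoothstep
#'
#' C2-continuous ramp used for the pulsation-schedule pressure transitions and
#' the set-point power throttle. Returns 0 for u <= 0, 1 for u >= 1 and
#' 6u^5 - 15u^4 + 10u^3 in between (first and second derivatives vanish at both
#' ends).
#'
#' @param u numeric vector.
#' @return numeric vector in [0, 1].
#' @keywords internal
smoothstep5 <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * u * (u * (u * 6 - 15) + 10)
}

# Thomas algorithm for tridiagonal systems. `lower` and `upper` have length
# n - 1 (sub/super diagonal), `diag` and `rhs` length n. Returns the solution.
solve_tridiag <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  if (n == 1L) return(rhs / diag)
  cp <- numeric(n - 1L)
  dp <- numeric(n)
  cp[1L] <- upper[1L] / diag[1L]
  dp[1L] <- rhs[1L] / diag[1L]
  if (n > 2L) {
    for (i in 2:(n - 1L)) {
      denom <- diag[i] - lower[i - 1L] * cp[i - 1L]
      cp[i] <- upper[i] / denom
      dp[i] <- (rhs[i] - lower[i - 1L] * dp[i - 1L]) / denom
    }
  }
  denom <- diag[n] - lower[n - 1L] * cp[n - 1L]
  dp[n] <- (rhs[n] - lower[n - 1L] * dp[n - 1L]) / denom
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Complementary error function (base R has none).
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_zb <- function(...) stop(..., call. = FALSE)
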