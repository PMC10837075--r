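# Internal numeric helpers shared across modules.

#' Derive a child RNG seed from a master seed and stream labels
#'
#' All randomness in the simulator flows from one master integer seed.
#' Child seeds for speckle realizations, per-loop noise and per-day
#' acquisitions are derived deterministically with a multiplicative
#' congruential mix modulo 2^31 - 1, so identical (inputs, seed) give
#' bit-identical output while distinct streams decorrelate.
#'
#' @param seed master seed (integer-valued scalar).
#' @param ... integer stream labels (e.g. loop index, day).
#' @return an integer seed in [1, 2^31 - 2].
#' @keywords internal
deriveSeed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

#' Round half away from zero
#'
#' Commercial rounding used for reported fold changes: ties go away from
#' zero (2.5 -> 3), unlike base round()'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @keywords internal
roundHalfAway <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Wrap angles into (-pi, pi]
#' @param x numeric vector of angles in radians.
#' @keywords internal
wrapToPi <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

# stop() with call.=FALSE everywhere; small wrapper for consistency
.err <- function(...) stop(sprintf(...), call. = FALSE)

.assertScalarNum <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .err("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0) .err("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) .err("'%s' must be >= 0 (got %g)", name, x)
  invisible(TRUE)
}
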