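# Reconstruction: per-pixel temporal phase unwrapping, single-bin
# quadrature demodulation at the drive frequency, amplitude maps and
# magnet-on minus magnet-off difference images, and motion-based loop
# rejection.

#' Temporally unwrap the per-pixel phase of an I/Q ensemble
#'
#' Computes r(x,z,n) = arg(R_I + j R_Q) for every pixel and frame and
#' unwraps it along the frame axis: 2*pi multiples are added so that
#' consecutive differences lie in (-pi, pi], with the first frame's phase
#' kept in (-pi, pi]. Unwrapping is purely temporal; no spatial coupling.
#'
#' Zero-magnitude I/Q samples have undefined phase; for those frames the
#' previous frame's phase is carried forward and the pixel is counted in
#' \code{flaggedPixels}.
#'
#' @param stack an \linkS4class{IQStack} (N >= 2 frames).
#' @return a \linkS4class{PhaseStack}.
#' @export
unwrapPhase <- function(stack) {
  stopifnot(is(stack, "IQStack"))
  d <- dim(stack@iq)
  npix <- d[1L] * d[2L]
  N <- d[3L]
  P <- matrix(Arg(stack@iq), npix, N)
  Z <- matrix(Mod(stack@iq) == 0, npix, N)
  flagged <- sum(rowSums(Z) > 0L)
  if (flagged > 0L) {
    # undefined phase: carry the last valid raw phase forward before
    # differencing, so later increments are taken against it
    for (n in 2:N) {
      z <- Z[, n]
      if (any(z)) P[z, n] <- P[z, n - 1L]
    }
  }
  D <- wrapToPi(P[, -1L, drop = FALSE] - P[, -N, drop = FALSE])
  U <- cbind(P[, 1L], D)
  U <- t(apply(U, 1L, cumsum))
  phase <- array(U, dim = d)
  new("PhaseStack", phase = phase, frameRate = stack@frameRate,
      magState = stack@magState, flaggedPixels = as.integer(flagged),
      meta = stack@meta)
}

# longest frame prefix covering an integer number of f0 cycles
.integerCyclePrefix <- function(N, frameRate, f0) {
  n <- seq_len(N)
  cyc <- n * f0 / frameRate
  ok <- abs(cyc - round(cyc)) < 1e-9 & round(cyc) >= 1
  if (!any(ok)) return(0L)
  max(n[ok])
}

.metaF0 <- function(x) {
  f0 <- x@meta$f0
  if (is.null(f0)) .err("f0 not given and absent from stack metadata")
  f0
}

.trimFrames <- function(x, slotName, f0) {
  a <- slot(x, slotName)
  N <- dim(a)[3L]
  keep <- .integerCyclePrefix(N, x@frameRate, f0)
  if (keep == 0L)
    .err("ensemble covers less than one full drive cycle (%d frames at %g Hz, f0 = %g Hz)",
         N, x@frameRate, f0)
  if (keep < N) {
    warning(sprintf("trimmed %d of %d frames to cover %d whole drive cycles",
                    N - keep, N, as.integer(round(keep * f0 / x@frameRate))),
            call. = FALSE)
    slot(x, slotName) <- a[, , seq_len(keep), drop = FALSE]
  }
  x
}

#' @rdname trimToIntegerCycles
setMethod("trimToIntegerCycles", "IQStack", function(x, f0) {
  if (missing(f0)) f0 <- .metaF0(x)
  .trimFrames(x, "iq", f0)
})

#' @rdname trimToIntegerCycles
setMethod("trimToIntegerCycles", "PhaseStack", function(x, f0) {
  if (missing(f0)) f0 <- .metaF0(x)
  .trimFrames(x, "phase", f0)
})

.demodPhase <- function(phase, frameRate, f0) {
  if (f0 >= frameRate / 2)
    .err("f0 = %g Hz is at or above Nyquist for a %g Hz frame rate", f0,
         frameRate)
  d <- dim(phase)
  N <- d[3L]
  cyc <- N * f0 / frameRate
  if (abs(cyc - round(cyc)) > 1e-9)
    warning(sprintf(
      "ensemble covers %.4g (non-integer) drive cycles; call trimToIntegerCycles() for exact averaging",
      cyc), call. = FALSE)
  n <- 0:(N - 1L)
  e <- exp(1i * 2 * pi * f0 * n / frameRate)
  Rbar <- matrix(phase, d[1L] * d[2L], N) %*% e / N
  Rbar <- matrix(Rbar, d[1L], d[2L])
  new("DemodResult", complexMean = Rbar, amplitude = 2 * Mod(Rbar), f0 = f0)
}

#' Quadrature demodulation at the magnetic drive frequency
#'
#' Multiplies the unwrapped phase sequence of every pixel by
#' exp(j*2*pi*f0*n*dt) (n = 0..N-1) and averages over frames — a
#' single-bin discrete Fourier (lock-in) detector. The mean, not a
#' low-pass filter, gives the complex amplitude; over an integer number
#' of drive cycles the DC term and every other integer-cycle frequency
#' average to exactly zero. The oscillation amplitude at f0 is
#' A = 2*|Rbar| = 2*sqrt(I^2 + Q^2), in radians of phase modulation.
#'
#' Applied to an \linkS4class{IQStack}, the stack is unwrapped first
#' (\code{\link{unwrapPhase}}).
#'
#' @param x a \linkS4class{PhaseStack} or \linkS4class{IQStack}.
#' @param f0 demodulation (drive) frequency, Hz; defaults to the stack's
#'   metadata. Must be below the frame-rate Nyquist limit.
#' @param ... unused.
#' @return a \linkS4class{DemodResult}.
#' @examples
#' # 0.2 rad sinusoid on a 0.3 rad DC offset: A recovers 0.2 exactly
#' fr <- 500; N <- 500; t <- (0:(N - 1)) / fr
#' ph <- array(rep(0.3 + 0.2 * sin(2 * pi * 5 * t), each = 1), c(1, 1, N))
#' ps <- new("PhaseStack", phase = ph, frameRate = fr, magState = "ON",
#'           flaggedPixels = 0L, meta = list(f0 = 5))
#' amplitude(demodulate(ps, 5))
#' @export
setMethod("demodulate", "PhaseStack", function(x, f0, ...) {
  if (missing(f0)) f0 <- .metaF0(x)
  .demodPhase(x@phase, x@frameRate, f0)
})

#' @rdname demodulate
setMethod("demodulate", "IQStack", function(x, f0, ...) {
  if (missing(f0)) f0 <- .metaF0(x)
  demodulate(unwrapPhase(x), f0)
})

#' Amplitude map of a demodulation result
#'
#' @param demod a \linkS4class{DemodResult}.
#' @return an \linkS4class{AmplitudeMap} of kind "SINGLE".
#' @export
amplitudeMap <- function(demod) {
  stopifnot(is(demod, "DemodResult"))
  new("AmplitudeMap", values = demod@amplitude, kind = "SINGLE")
}

#' Average amplitude maps across loops
#'
#' The per-loop amplitude maps of one set are averaged pixelwise into the
#' set's amplitude map before any magnet-on/off subtraction.
#'
#' @param maps list of \linkS4class{AmplitudeMap} (or
#'   \linkS4class{DemodResult}) sharing one shape and kind.
#' @return an \linkS4class{AmplitudeMap}.
#' @export
averageAmplitudeMaps <- function(maps) {
  if (length(maps) == 0L) .err("no maps to average")
  vals <- lapply(maps, function(m) {
    if (is(m, "DemodResult")) m <- amplitudeMap(m)
    stopifnot(is(m, "AmplitudeMap"))
    m@values
  })
  d <- dim(vals[[1L]])
  if (!all(vapply(vals, function(v) identical(dim(v), d), logical(1L))))
    .err("maps differ in shape")
  new("AmplitudeMap", values = Reduce(`+`, vals) / length(vals),
      kind = "SINGLE")
}

#' Magnet-on minus magnet-off difference image
#'
#' Subtracts the magnet-off (baseline) amplitude map from the magnet-on
#' (contrast-bearing) map pixelwise; negative differences are clamped to
#' zero. The same operation forms post- minus pre-injection difference
#' images in vivo.
#'
#' @param on,off \linkS4class{AmplitudeMap}s of identical shape
#'   (contrast-bearing and baseline, respectively).
#' @return an \linkS4class{AmplitudeMap} of kind "DELTA".
#' @export
deltaMap <- function(on, off) {
  stopifnot(is(on, "AmplitudeMap"), is(off, "AmplitudeMap"))
  if (!identical(dim(on@values), dim(off@values)))
    .err("amplitude maps differ in shape")
  new("AmplitudeMap", values = pmax(on@values - off@values, 0),
      kind = "DELTA")
}

#' Bulk-motion metric of one loop
#'
#' Quantifies common-mode (bulk) tissue motion, e.g. breathing, as the
#' root-mean-square over frames of the spatial median of the phase
#' excursion relative to the first frame. A bulk drift moves every
#' pixel's phase coherently and survives the spatial median, whereas
#' independent speckle phase noise is suppressed by ~1/sqrt(npix) and
#' localized magnetomotive signal barely moves the median as long as the
#' moving region is a minority of the field of view. The metric therefore
#' separates motion-corrupted loops from clean ones even when per-pixel
#' phase noise exceeds the per-frame drift increment.
#'
#' @param x a \linkS4class{PhaseStack} (or \linkS4class{IQStack}, which is
#'   unwrapped first).
#' @return non-negative scalar, rad.
#' @export
loopMotionMetric <- function(x) {
  if (is(x, "IQStack")) x <- unwrapPhase(x)
  stopifnot(is(x, "PhaseStack"))
  d <- dim(x@phase)
  P <- matrix(x@phase, d[1L] * d[2L], d[3L])
  b <- apply(P - P[, 1L], 2L, stats::median)
  sqrt(mean(b^2))
}

#' Reject motion-corrupted loops
#'
#' Scores every loop with \code{\link{loopMotionMetric}} and removes loops
#' whose metric exceeds \code{threshold}. The default threshold is 3 times
#' the lower quartile of the loop metrics: the lower quartile tracks the
#' clean-loop noise level even when up to half the loops in a set are
#' corrupted, where a median-based cut would fail.
#'
#' @param loopList non-empty list of \linkS4class{PhaseStack} (or
#'   \linkS4class{IQStack}) objects.
#' @param threshold rejection threshold, rad; \code{NULL} for the
#'   default rule.
#' @return list with elements \code{kept} (the retained loops),
#'   \code{rejected} (integer indices of removed loops), \code{metrics}
#'   and \code{threshold}.
#' @export
rejectLoops <- function(loopList, threshold = NULL) {
  if (length(loopList) == 0L) .err("at least one loop is required")
  metrics <- vapply(loopList, loopMotionMetric, numeric(1L))
  if (is.null(threshold))
    threshold <- 3 * stats::quantile(metrics, 0.25, names = FALSE)
  rejected <- which(metrics > threshold)
  if (length(rejected) == length(loopList))
    .err("all %d loops exceed the motion threshold %.3g; review the threshold or the acquisition",
         length(loopList), threshold)
  list(kept = if (length(rejected)) loopList[-rejected] else loopList,
       rejected = rejected, metrics = metrics, threshold = threshold)
}

#' Reconstruct the amplitude map of one set of loops
#'
#' Full reconstruction of one magnet state: trim each loop to whole drive
#' cycles, unwrap, optionally reject motion-corrupted loops, demodulate
#' each retained loop at f0 and average the per-loop amplitude maps.
#'
#' @param x an \linkS4class{MMUSAcquisition} or a list of
#'   \linkS4class{IQStack} loops.
#' @param f0 drive frequency, Hz (defaults to stack metadata).
#' @param reject logical, apply \code{\link{rejectLoops}}?
#' @param threshold motion threshold passed to \code{\link{rejectLoops}}.
#' @return list with \code{map} (the loop-averaged
#'   \linkS4class{AmplitudeMap}), \code{rejected} (loop indices),
#'   \code{metrics}, and \code{framesTrimmed} per loop.
#' @export
reconstructAmplitude <- function(x, f0, reject = FALSE, threshold = NULL) {
  loopList <- if (is(x, "MMUSAcquisition")) x@loops else x
  if (length(loopList) == 0L) .err("no loops to reconstruct")
  if (missing(f0)) f0 <- .metaF0(loopList[[1L]])
  nIn <- vapply(loopList, nFrames, numeric(1L))
  phases <- lapply(loopList, function(lp)
    unwrapPhase(suppressWarnings(trimToIntegerCycles(lp, f0))))
  framesTrimmed <- nIn - vapply(phases, nFrames, numeric(1L))
  rejected <- integer()
  metrics <- NULL
  if (reject) {
    rj <- rejectLoops(phases, threshold)
    phases <- rj$kept
    rejected <- rj$rejected
    metrics <- rj$metrics
  }
  maps <- lapply(phases, function(p) amplitudeMap(demodulate(p, f0)))
  list(map = averageAmplitudeMaps(maps), rejected = rejected,
       metrics = metrics, framesTrimmed = framesTrimmed)
}
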