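# Stiffness calibration: power-law fit of signal against elastic modulus,
# modulus inversion, limit of detection and detectable stiffness range.

#' Fit a power-law signal-stiffness calibration
#'
#' Least-squares line on (log E, log signal):
#' log signal = log(alpha) - beta * log(E), i.e. signal = alpha * E^(-beta).
#' The power law is the simplest monotone family consistent with the
#' inverse signal-stiffness relation; beta is estimated, not fixed to 1.
#'
#' @param modulus elastic moduli, Pa (> 0; at least 3 distinct values).
#' @param signal matching signals (e.g. delta-SBR), all > 0.
#' @param concentration,fieldStrength optional stratum metadata (nM, mT);
#'   calibrations are per (concentration, field) stratum.
#' @return a \linkS4class{CalibrationFit}.
#' @examples
#' f <- fitPowerLaw(c(63, 74, 564, 5828), 1000 / c(63, 74, 564, 5828))
#' coef(f)  # alpha = 1000, beta = 1
#' @export
fitPowerLaw <- function(modulus, signal, concentration = NA_real_,
                        fieldStrength = NA_real_) {
  if (length(modulus) != length(signal))
    .err("modulus and signal must have equal length")
  if (any(!is.finite(modulus)) || any(modulus <= 0))
    .err("all moduli must be positive and finite")
  if (any(!is.finite(signal)) || any(signal <= 0))
    .err("all signals must be positive (log-log fit)")
  if (length(unique(modulus)) < 3L)
    .err("at least 3 distinct moduli are required (got %d)",
         length(unique(modulus)))
  fit <- stats::lm(log(signal) ~ log(modulus))
  beta <- -unname(stats::coef(fit)[2L])
  alpha <- exp(unname(stats::coef(fit)[1L]))
  if (!is.finite(beta) || beta <= 0)
    .err("fitted exponent is not positive (beta = %.3g): data show no inverse signal-stiffness relation",
         beta)
  new("CalibrationFit", alpha = alpha, beta = beta,
      concentration = as.numeric(concentration),
      fieldStrength = as.numeric(fieldStrength),
      residualSd = sqrt(sum(stats::residuals(fit)^2) /
                          max(1L, length(signal) - 2L)),
      nPoints = length(signal))
}

#' Predicted signal at a given modulus
#'
#' @param fit a \linkS4class{CalibrationFit}.
#' @param modulus elastic modulus, Pa (> 0).
#' @return predicted signal alpha * E^(-beta).
#' @export
predictSignal <- function(fit, modulus) {
  stopifnot(is(fit, "CalibrationFit"))
  if (any(modulus <= 0)) .err("modulus must be > 0")
  fit@alpha * modulus^(-fit@beta)
}

#' Invert a calibration: estimate the elastic modulus from a signal
#'
#' Algebraic inverse of the power law: E = (alpha/signal)^(1/beta).
#' Strictly decreasing in the signal.
#'
#' @param signal measured signal (> 0).
#' @param fit a \linkS4class{CalibrationFit}.
#' @return estimated elastic modulus, Pa.
#' @examples
#' f <- fitPowerLaw(c(63, 74, 564, 5828), 1000 / c(63, 74, 564, 5828))
#' estimateModulus(10, f)  # 100 Pa
#' @export
estimateModulus <- function(signal, fit) {
  stopifnot(is(fit, "CalibrationFit"))
  if (any(!is.finite(signal)) || any(signal <= 0))
    .err("signal must be > 0")
  (fit@alpha / signal)^(1 / fit@beta)
}

#' Limit of detection over a concentration series
#'
#' Detection rule: a concentration is detected when its replicate mean
#' exceeds mean(background) + k * sd(background) (k = 3 by default, the
#' conventional three-sigma criterion). The LOD is the smallest tested
#' concentration that is detected and whose larger tested concentrations
#' are all detected too; if none qualifies the result is flagged
#' not-detected.
#'
#' @param table data.frame with numeric columns \code{concentration} (nM)
#'   and \code{value} (replicate signals, e.g. delta-SBR).
#' @param background numeric vector of background (agent-free) replicate
#'   signals, length >= 2.
#' @param k threshold multiplier on the background sd.
#' @return an \linkS4class{LODResult}.
#' @export
estimateLOD <- function(table, background, k = 3) {
  if (!is.data.frame(table) || nrow(table) == 0L ||
      !all(c("concentration", "value") %in% names(table)))
    .err("table must be a non-empty data.frame(concentration, value)")
  if (length(background) < 2L)
    .err("at least 2 background replicates are required")
  thr <- mean(background) + k * stats::sd(background)
  means <- tapply(table$value, table$concentration, mean)
  conc <- as.numeric(names(means))
  o <- order(conc)
  conc <- conc[o]; means <- as.numeric(means)[o]
  det <- means > thr
  # smallest concentration detected with all larger ones detected too
  lodIdx <- NA_integer_
  for (i in rev(seq_along(conc))) {
    if (!det[i]) break
    lodIdx <- i
  }
  if (is.na(lodIdx))
    new("LODResult", lod = NA_real_, detected = FALSE, threshold = thr,
        replicates = length(background))
  else
    new("LODResult", lod = conc[lodIdx], detected = TRUE, threshold = thr,
        replicates = length(background))
}

#' Stiffest modulus still detectable at a signal threshold
#'
#' Upper end of the detectable stiffness (dynamic) range for a given
#' calibration: E_max = (alpha/threshold)^(1/beta), the stiffest modulus
#' whose predicted signal still exceeds \code{threshold}. Because the
#' signal scales with agent concentration through alpha, higher
#' concentrations broaden the range.
#'
#' @param fit a \linkS4class{CalibrationFit}.
#' @param threshold detection threshold on the signal scale (> 0).
#' @return E_max, Pa.
#' @export
detectableModulusRange <- function(fit, threshold) {
  stopifnot(is(fit, "CalibrationFit"))
  .assertScalarNum(threshold, "threshold", positive = TRUE)
  (fit@alpha / threshold)^(1 / fit@beta)
}

#' Plot a signal-stiffness calibration (log-log)
#'
#' Draws the calibration points and fitted power law on log-log axes,
#' optionally to a PNG file.
#'
#' @param fit a \linkS4class{CalibrationFit}.
#' @param modulus,signal the calibration points.
#' @param file optional PNG path; plots to the active device when NULL.
#' @return the file path (or NULL), invisibly.
#' @export
plotCalibration <- function(fit, modulus, signal, file = NULL) {
  stopifnot(is(fit, "CalibrationFit"))
  if (!is.null(file)) grDevices::png(file, width = 600, height = 480)
  graphics::plot(modulus, signal, log = "xy", pch = 19,
                 xlab = "Elastic modulus (Pa)", ylab = "Signal (delta-SBR)",
                 main = sprintf("signal = %.3g E^-%.3g", fit@alpha, fit@beta))
  eg <- exp(seq(log(min(modulus)), log(max(modulus)), length.out = 100))
  graphics::lines(eg, predictSignal(fit, eg), col = "red3", lwd = 2)
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}
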