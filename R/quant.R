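# ROI quantification: SBR, delta-SBR, fold changes, softness index and
# longitudinal normalization.

#' Construct a rectangular ROI
#'
#' Pixel indices are 0-based and half-open: the ROI covers map elements
#' with x in [x0, x1) and z in [z0, z1).
#'
#' @param x0,z0,x1,z1 integer pixel bounds (x1 > x0, z1 > z0).
#' @param label text label.
#' @return an \linkS4class{ROI}.
#' @examples
#' roi(0, 0, 4, 4, "background")  # the 4 x 4 corner block
#' @export
roi <- function(x0, z0, x1, z1, label = "") {
  new("ROI", x0 = as.integer(x0), z0 = as.integer(z0), x1 = as.integer(x1),
      z1 = as.integer(z1), label = as.character(label))
}

.roiValues <- function(map, r) {
  v <- if (is(map, "AmplitudeMap")) map@values else map
  stopifnot(is.matrix(v))
  if (r@x1 > nrow(v) || r@z1 > ncol(v))
    .err("ROI '%s' [%d, %d) x [%d, %d) exceeds the %d x %d map", r@label,
         r@x0, r@x1, r@z0, r@z1, nrow(v), ncol(v))
  v[(r@x0 + 1L):r@x1, (r@z0 + 1L):r@z1, drop = FALSE]
}

#' Mean pixel intensity over an ROI
#'
#' @param map an \linkS4class{AmplitudeMap} or numeric matrix.
#' @param r an \linkS4class{ROI} within the map bounds.
#' @return arithmetic mean of the ROI pixels.
#' @export
roiMean <- function(map, r) {
  stopifnot(is(r, "ROI"))
  mean(.roiValues(map, r))
}

#' Signal-to-background ratio of two ROIs
#'
#' SBR = mean pixel intensity of the sample ROI divided by that of the
#' background ROI (a linear ratio, not dB). Computed on a "DELTA" map
#' this is the magnetic-field-dependent signal change (delta-SBR).
#'
#' @param map an \linkS4class{AmplitudeMap} or numeric matrix.
#' @param sample,background \linkS4class{ROI}s.
#' @return dimensionless SBR >= 0.
#' @export
sbr <- function(map, sample, background) {
  b <- roiMean(map, background)
  if (b <= 0)
    .err("background ROI '%s' has non-positive mean (%g); SBR undefined",
         background@label, b)
  roiMean(map, sample) / b
}

#' SBR difference between magnet-on and magnet-off maps
#'
#' Secondary summary \code{sbr(on) - sbr(off)}, distinct from the primary
#' delta-SBR (SBR evaluated on the clamped difference image); exposed
#' under its own name to keep the two definitions from being conflated.
#'
#' @param on,off \linkS4class{AmplitudeMap}s.
#' @inheritParams sbr
#' @return dimensionless difference (may be negative).
#' @export
sbrDifference <- function(on, off, sample, background) {
  sbr(on, sample, background) - sbr(off, sample, background)
}

#' Fold change between two group means
#'
#' Ratio numerator/denominator rounded half away from zero to
#' \code{decimals} places, the convention used for reported
#' "x-fold" comparisons.
#'
#' @param numerator,denominator group means (denominator > 0).
#' @param decimals decimal places kept.
#' @return rounded fold change.
#' @examples
#' foldChange(110.1, 9.1, 0)  # 12
#' foldChange(37.1, 4.0, 1)   # 9.3
#' @export
foldChange <- function(numerator, denominator, decimals = 1) {
  .assertScalarNum(numerator, "numerator")
  .assertScalarNum(denominator, "denominator", positive = TRUE)
  roundHalfAway(numerator / denominator, decimals)
}

#' Softness index
#'
#' Ratio of the magnetomotive (MMUS) SBR to the contrast-mode (AM) SBR.
#' Dividing by the AM signal normalizes the motion signal by the local
#' agent abundance, so the index tracks how freely the agent moves —
#' higher means softer tissue.
#'
#' @param mmusSbr MMUS SBR (>= 0).
#' @param amSbr AM-mode SBR (> 0).
#' @return dimensionless softness index.
#' @export
softnessIndex <- function(mmusSbr, amSbr) {
  .assertScalarNum(mmusSbr, "mmusSbr", nonneg = TRUE)
  .assertScalarNum(amSbr, "amSbr", positive = TRUE)
  mmusSbr / amSbr
}

#' Normalize a longitudinal series to its baseline day
#'
#' Divides every value by the value at \code{baselineDay} (e.g. relative
#' SBR normalized to the first imaging day), making the baseline entry
#' exactly 1. Idempotent.
#'
#' @param series data.frame with numeric columns \code{day} (strictly
#'   increasing) and \code{value}.
#' @param baselineDay day to normalize to; defaults to the first day.
#' @return the series with \code{value} replaced by value/baseline.
#' @examples
#' normalizeSeries(data.frame(day = c(5, 7, 9), value = c(4, 2, 1)))
#' @export
normalizeSeries <- function(series, baselineDay = NULL) {
  if (!is.data.frame(series) || !all(c("day", "value") %in% names(series)))
    .err("series must be a data.frame(day, value)")
  if (nrow(series) == 0L) .err("series is empty")
  if (any(diff(series$day) <= 0)) .err("days must be strictly increasing")
  if (is.null(baselineDay)) baselineDay <- series$day[1L]
  i <- which(series$day == baselineDay)
  if (length(i) != 1L) .err("baseline day %g not present in the series",
                            baselineDay)
  b <- series$value[i]
  if (!is.finite(b) || b <= 0)
    .err("baseline value must be > 0 (got %g)", b)
  series$value <- series$value / b
  series
}
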