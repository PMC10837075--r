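# Accessor and show methods.

#' @rdname IQStack-class
setMethod("iqData", "IQStack", function(object) object@iq)

#' @rdname PhaseStack-class
setMethod("phaseData", "PhaseStack", function(object) object@phase)

#' @rdname IQStack-class
setMethod("frameRate", "IQStack", function(object) object@frameRate)
#' @rdname PhaseStack-class
setMethod("frameRate", "PhaseStack", function(object) object@frameRate)

#' @rdname IQStack-class
setMethod("nFrames", "IQStack", function(object) dim(object@iq)[3L])
#' @rdname PhaseStack-class
setMethod("nFrames", "PhaseStack", function(object) dim(object@phase)[3L])

#' @rdname IQStack-class
setMethod("frameInterval", "IQStack", function(object) 1 / object@frameRate)
#' @rdname PhaseStack-class
setMethod("frameInterval", "PhaseStack", function(object) 1 / object@frameRate)

#' @rdname IQStack-class
setMethod("magState", "IQStack", function(object) object@magState)
#' @rdname PhaseStack-class
setMethod("magState", "PhaseStack", function(object) object@magState)
#' @rdname MMUSAcquisition-class
setMethod("magState", "MMUSAcquisition", function(object) object@magState)

#' @rdname DemodResult-class
setMethod("amplitude", "DemodResult", function(object) object@amplitude)
#' @rdname AmplitudeMap-class
setMethod("amplitude", "AmplitudeMap", function(object) object@values)

#' @rdname DemodResult-class
setMethod("complexMean", "DemodResult", function(object) object@complexMean)

#' @rdname AmplitudeMap-class
setMethod("mapKind", "AmplitudeMap", function(object) object@kind)

#' @rdname PhantomSpec-class
setMethod("gridShape", "PhantomSpec", function(object) object@gridShape)

#' @rdname PhantomSpec-class
setMethod("wells", "PhantomSpec", function(object) object@wells)

#' @rdname MMUSAcquisition-class
setMethod("loops", "MMUSAcquisition", function(object) object@loops)

#' @rdname MMUSAcquisition-class
setMethod("groundTruth", "MMUSAcquisition", function(object) object@truth)

#' @rdname MMUSAcquisition-class
setMethod("acqParams", "MMUSAcquisition", function(object) object@params)

#' @rdname AcquisitionPair-class
setMethod("magOff", "AcquisitionPair", function(object) object@off)

#' @rdname AcquisitionPair-class
setMethod("magOn", "AcquisitionPair", function(object) object@on)

#' @rdname CalibrationFit-class
#' @param object a \code{CalibrationFit}.
setMethod("calibrationStratum", "CalibrationFit", function(object)
  c(concentration_nM = object@concentration,
    field_mT = object@fieldStrength))

#' @describeIn CalibrationFit-class fitted parameters
#'   \code{c(alpha, beta)} of signal = alpha * E^(-beta).
#' @param ... ignored.
#' @export
setMethod("coef", "CalibrationFit", function(object, ...)
  c(alpha = object@alpha, beta = object@beta))

# ---- show methods -----------------------------------------------------------

setMethod("show", "IQStack", function(object) {
  d <- dim(object@iq)
  cat(sprintf("IQStack: %d x %d pixels, %d frames @ %g Hz (mag %s)\n",
              d[1L], d[2L], d[3L], object@frameRate, object@magState))
})

setMethod("show", "PhaseStack", function(object) {
  d <- dim(object@phase)
  cat(sprintf(
    "PhaseStack: %d x %d pixels, %d frames @ %g Hz (mag %s, %d flagged px)\n",
    d[1L], d[2L], d[3L], object@frameRate, object@magState,
    object@flaggedPixels))
})

setMethod("show", "DemodResult", function(object) {
  d <- dim(object@amplitude)
  cat(sprintf("DemodResult @ f0 = %g Hz: %d x %d, A in [%.3g, %.3g] rad\n",
              object@f0, d[1L], d[2L], min(object@amplitude),
              max(object@amplitude)))
})

setMethod("show", "AmplitudeMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("AmplitudeMap (%s): %d x %d, values in [%.3g, %.3g] rad\n",
              object@kind, d[1L], d[2L], min(object@values),
              max(object@values)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d px @ %g mm, %d wells, background %.3g\n",
              object@gridShape[1L], object@gridShape[2L], object@pixelPitch,
              length(object@wells), object@backgroundEchogenicity))
  for (w in object@wells)
    cat(sprintf("  %s well at (%d, %d) +/- (%d, %d): E = %g Pa, c = %g nM\n",
                w@agent, w@center[1L], w@center[2L], w@halfSize[1L],
                w@halfSize[2L], w@elasticModulus, w@concentration))
})

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf(
    "AcquisitionParams: %d frames @ %g Hz, drive %g Hz / %g mT, %d loops\n",
    object@nFrames, object@frameRate, object@f0, object@fieldStrength,
    object@nLoops))
  cat(sprintf("  fc = %g MHz, c = %g m/s, noise sd %g, kappa %g, seed %d\n",
              object@centerFreq, object@soundSpeed, object@noiseSd,
              object@couplingKappa, object@seed))
})

setMethod("show", "MMUSAcquisition", function(object) {
  cat(sprintf("MMUSAcquisition (mag %s): %d loops\n", object@magState,
              length(object@loops)))
  show(object@params)
})

setMethod("show", "AcquisitionPair", function(object) {
  cat("AcquisitionPair (matched speckle):\n  OFF: ")
  show(object@off@loops[[1L]])
  cat("  ON:  ")
  show(object@on@loops[[1L]])
})

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI '%s': [%d, %d) x [%d, %d) (0-based, half-open)\n",
              object@label, object@x0, object@x1, object@z0, object@z1))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf(
    "CalibrationFit: signal = %.4g * E^-%.4g (n = %d, log-sd %.3g)\n",
    object@alpha, object@beta, object@nPoints, object@residualSd))
  if (is.finite(object@concentration) || is.finite(object@fieldStrength))
    cat(sprintf("  stratum: %g nM, %g mT\n", object@concentration,
                object@fieldStrength))
})

setMethod("show", "LODResult", function(object) {
  if (object@detected)
    cat(sprintf("LODResult: LOD = %g nM (threshold %.4g, %d background reps)\n",
                object@lod, object@threshold, object@replicates))
  else
    cat(sprintf("LODResult: NOT DETECTED (threshold %.4g, %d background reps)\n",
                object@threshold, object@replicates))
})
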