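#' @import methods
NULL

# ---- simulation-side value classes -----------------------------------------

#' WellSpec: one inclusion (well) of a simulated phantom
#'
#' A rectangular well centred at \code{center} (1-based pixel coordinates,
#' (x, z)) extending \code{halfSize} pixels either side, filled with an
#' imaging agent at a given molar concentration and embedded in a medium of
#' the stated elastic modulus. Agents differ in their acoustic and magnetic
#' behaviour: \code{"MGV"} (magneto-gas vesicle) is both echogenic and
#' magnetically actuatable, \code{"GV"} is echogenic only (zero
#' magnetomotive displacement), \code{"MNP"} moves magnetically but is
#' weakly echogenic.
#'
#' @slot center integer(2), well centre in pixels (x, z), 1-based.
#' @slot halfSize integer(2), half extent in pixels along (x, z).
#' @slot elasticModulus numeric, Pa (> 0).
#' @slot concentration numeric, nM (>= 0).
#' @slot agent character, one of "MGV", "GV", "MNP".
#' @exportClass WellSpec
setClass("WellSpec",
  representation(center = "integer", halfSize = "integer",
                 elasticModulus = "numeric", concentration = "numeric",
                 agent = "character"))

setValidity("WellSpec", function(object) {
  msg <- character()
  if (length(object@center) != 2L) msg <- c(msg, "center must have length 2")
  if (length(object@halfSize) != 2L || any(object@halfSize < 0L))
    msg <- c(msg, "halfSize must be two non-negative integers")
  if (length(object@elasticModulus) != 1L || !is.finite(object@elasticModulus) ||
      object@elasticModulus <= 0)
    msg <- c(msg, "elasticModulus must be a positive scalar (Pa)")
  if (length(object@concentration) != 1L || !is.finite(object@concentration) ||
      object@concentration < 0)
    msg <- c(msg, "concentration must be a non-negative scalar (nM)")
  if (!object@agent %in% c("MGV", "GV", "MNP"))
    msg <- c(msg, "agent must be one of 'MGV', 'GV', 'MNP'")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: geometry and contents of a simulated imaging phantom
#'
#' @slot gridShape integer(2), image grid (nx, nz) in pixels.
#' @slot pixelPitch numeric, pixel pitch in mm.
#' @slot wells list of \linkS4class{WellSpec}; must lie within the grid and
#'   not overlap.
#' @slot backgroundEchogenicity numeric >= 0, mean speckle brightness of the
#'   agent-free background (dimensionless).
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(gridShape = "integer", pixelPitch = "numeric",
                 wells = "list", backgroundEchogenicity = "numeric"))

.wellBox <- function(w) {
  # inclusive pixel bounds (x0, x1, z0, z1), 1-based
  c(w@center[1L] - w@halfSize[1L], w@center[1L] + w@halfSize[1L],
    w@center[2L] - w@halfSize[2L], w@center[2L] + w@halfSize[2L])
}

setValidity("PhantomSpec", function(object) {
  msg <- character()
  gs <- object@gridShape
  if (length(gs) != 2L || any(gs < 1L))
    msg <- c(msg, "gridShape must be two positive integers (nx, nz)")
  if (length(object@pixelPitch) != 1L || object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be a positive scalar (mm)")
  if (length(object@backgroundEchogenicity) != 1L ||
      object@backgroundEchogenicity < 0)
    msg <- c(msg, "backgroundEchogenicity must be >= 0")
  for (w in object@wells) {
    if (!is(w, "WellSpec")) { msg <- c(msg, "wells must be WellSpec objects"); next }
    v <- validObject(w, test = TRUE)
    if (is.character(v)) { msg <- c(msg, v); next }
    b <- .wellBox(w)
    if (b[1L] < 1L || b[3L] < 1L || b[2L] > gs[1L] || b[4L] > gs[2L])
      msg <- c(msg, sprintf("well at (%d, %d) extends outside the grid",
                            w@center[1L], w@center[2L]))
  }
  ws <- object@wells
  if (length(ws) > 1L) {
    for (i in seq_len(length(ws) - 1L)) for (j in seq(i + 1L, length(ws))) {
      if (!is(ws[[i]], "WellSpec") || !is(ws[[j]], "WellSpec")) next
      a <- .wellBox(ws[[i]]); b <- .wellBox(ws[[j]])
      if (a[1L] <= b[2L] && b[1L] <= a[2L] && a[3L] <= b[4L] && b[3L] <= a[4L])
        msg <- c(msg, sprintf("wells %d and %d overlap", i, j))
    }
  }
  if (length(msg)) msg else TRUE
})

#' AcquisitionParams: acquisition and actuation settings for one session
#'
#' Defaults reproduce the in vitro acquisition conditions modelled by the
#' simulator: 500-frame ensembles at 500 Hz, a 5 Hz sinusoidal magnetic
#' drive at 30 mT, a 15.6 MHz linear-array centre frequency, 1540 m/s
#' sound speed and 20 loops per set.
#'
#' @slot frameRate numeric, Hz; must exceed twice the drive frequency.
#' @slot nFrames integer, frames per loop (ensemble); at least one drive
#'   cycle.
#' @slot f0 numeric, magnetic drive frequency, Hz.
#' @slot fieldStrength numeric, peak magnetic field, mT.
#' @slot centerFreq numeric, transducer centre frequency, MHz.
#' @slot soundSpeed numeric, m/s.
#' @slot nLoops integer, independent ensembles per set.
#' @slot noiseSd numeric >= 0, additive complex-noise sd relative to the
#'   background echogenicity.
#' @slot couplingKappa numeric > 0, magneto-elastic coupling constant in
#'   um*Pa/(nM*mT^2); see \code{\link{displacementAmplitude}}.
#' @slot seed integer master seed; all randomness derives from it.
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
  representation(frameRate = "numeric", nFrames = "integer", f0 = "numeric",
                 fieldStrength = "numeric", centerFreq = "numeric",
                 soundSpeed = "numeric", nLoops = "integer",
                 noiseSd = "numeric", couplingKappa = "numeric",
                 seed = "integer"))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  pos <- c(frameRate = object@frameRate, f0 = object@f0,
           fieldStrength = object@fieldStrength, centerFreq = object@centerFreq,
           soundSpeed = object@soundSpeed, couplingKappa = object@couplingKappa)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) msg <- c(msg, paste0(bad, " must be > 0"))
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@nLoops < 1L) msg <- c(msg, "nLoops must be >= 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) return(msg)
  if (object@frameRate <= 2 * object@f0)
    msg <- c(msg, "frameRate must exceed 2*f0 (drive above Nyquist)")
  if (object@nFrames < object@frameRate / object@f0)
    msg <- c(msg, "nFrames must cover at least one drive cycle (frameRate/f0)")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: known per-pixel truth backing a simulated acquisition
#'
#' @slot displacementAmp matrix, peak magnetically induced axial
#'   displacement per pixel, um.
#' @slot phaseAmp matrix, corresponding pulse-echo phase amplitude, rad
#'   (4*pi*d/lambda).
#' @slot modulusMap matrix, elastic modulus per pixel, Pa (Inf outside
#'   wells: the rigid background does not move).
#' @slot echogenicityMap matrix, expected (pre-speckle) echogenicity.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(displacementAmp = "matrix", phaseAmp = "matrix",
                 modulusMap = "matrix", echogenicityMap = "matrix"))

setValidity("GroundTruth", function(object) {
  d <- dim(object@displacementAmp)
  if (!identical(d, dim(object@phaseAmp)) ||
      !identical(d, dim(object@modulusMap)) ||
      !identical(d, dim(object@echogenicityMap)))
    return("all ground-truth maps must share one grid shape")
  if (any(object@displacementAmp < 0) || any(object@phaseAmp < 0))
    return("displacement and phase amplitudes must be >= 0")
  TRUE
})

# ---- reconstruction-side data classes --------------------------------------

#' IQStack: one complex I/Q frame ensemble (loop)
#'
#' Beamformed in-phase/quadrature data R_I + j R_Q as a complex array of
#' dimension (nx, nz, N): N frames of an (nx, nz) image sampled at
#' \code{frameRate}. The frame interval is 1/frameRate. \code{meta} carries
#' acquisition metadata (at least f0, fieldStrength, centerFreq,
#' soundSpeed, seed for persisted stacks).
#'
#' @slot iq complex 3-d array (nx, nz, N), N >= 2.
#' @slot frameRate numeric, Hz.
#' @slot magState character, "OFF" or "ON".
#' @slot meta list of acquisition metadata.
#' @exportClass IQStack
setClass("IQStack",
  representation(iq = "array", frameRate = "numeric", magState = "character",
                 meta = "list"))

setValidity("IQStack", function(object) {
  msg <- character()
  if (!is.complex(object@iq) || length(dim(object@iq)) != 3L)
    msg <- c(msg, "iq must be a complex 3-d array (nx, nz, N)")
  else if (dim(object@iq)[3L] < 2L)
    msg <- c(msg, "at least 2 frames are required")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a positive scalar (Hz)")
  if (!object@magState %in% c("OFF", "ON"))
    msg <- c(msg, "magState must be 'OFF' or 'ON'")
  if (length(msg)) msg else TRUE
})

#' PhaseStack: temporally unwrapped per-pixel phase of an I/Q ensemble
#'
#' @slot phase numeric 3-d array (nx, nz, N), radians; per pixel the frame
#'   sequence is arg(R_I + j R_Q) adjusted by 2*pi multiples so consecutive
#'   differences lie in (-pi, pi].
#' @slot frameRate numeric, Hz.
#' @slot magState character, "OFF" or "ON".
#' @slot flaggedPixels integer, pixels that contained zero-magnitude
#'   (undefined-phase) samples; their phase was carried forward.
#' @slot meta list, inherited acquisition metadata.
#' @exportClass PhaseStack
setClass("PhaseStack",
  representation(phase = "array", frameRate = "numeric", magState = "character",
                 flaggedPixels = "integer", meta = "list"))

setValidity("PhaseStack", function(object) {
  if (!is.numeric(object@phase) || length(dim(object@phase)) != 3L)
    return("phase must be a numeric 3-d array (nx, nz, N)")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    return("frameRate must be a positive scalar (Hz)")
  TRUE
})

#' DemodResult: single-frequency quadrature demodulation of a phase stack
#'
#' Holds the per-pixel complex mean Rbar(x,z) of the quadrature-detected
#' sequence r_unwrapped(x,z,n) * exp(j*2*pi*f0*n*dt) and the derived
#' oscillation-amplitude map A = 2*|Rbar| = 2*sqrt(I^2 + Q^2) (radians of
#' phase modulation at f0).
#'
#' @slot complexMean complex matrix (nx, nz).
#' @slot amplitude numeric matrix (nx, nz), >= 0, rad.
#' @slot f0 numeric, demodulation frequency, Hz.
#' @exportClass DemodResult
setClass("DemodResult",
  representation(complexMean = "matrix", amplitude = "matrix", f0 = "numeric"))

setValidity("DemodResult", function(object) {
  if (!identical(dim(object@complexMean), dim(object@amplitude)))
    return("complexMean and amplitude must share a shape")
  if (any(object@amplitude < 0)) return("amplitude must be >= 0")
  a <- 2 * Mod(object@complexMean)
  if (max(abs(a - object@amplitude)) > 1e-8 * (1 + max(a)))
    return("amplitude must equal 2*|complexMean| elementwise")
  TRUE
})

#' AmplitudeMap: a reconstructed oscillation-amplitude image
#'
#' \code{kind} is "SINGLE" for the amplitude of one (possibly
#' loop-averaged) set and "DELTA" for a magnet-on minus magnet-off (or
#' post- minus pre-injection) difference image, clamped at zero.
#'
#' @slot values numeric matrix (nx, nz), >= 0, rad.
#' @slot kind character, "SINGLE" or "DELTA".
#' @exportClass AmplitudeMap
setClass("AmplitudeMap",
  representation(values = "matrix", kind = "character"))

setValidity("AmplitudeMap", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (any(object@values < 0)) return("values must be >= 0 (DELTA maps are clamped)")
  if (!object@kind %in% c("SINGLE", "DELTA"))
    return("kind must be 'SINGLE' or 'DELTA'")
  TRUE
})

# ---- acquisition containers -------------------------------------------------

#' MMUSAcquisition: one simulated set (loops + ground truth)
#'
#' @slot loops list of \linkS4class{IQStack}, one per loop.
#' @slot truth \linkS4class{GroundTruth}.
#' @slot phantom \linkS4class{PhantomSpec}.
#' @slot params \linkS4class{AcquisitionParams}.
#' @slot magState character, "OFF" or "ON".
#' @exportClass MMUSAcquisition
setClass("MMUSAcquisition",
  representation(loops = "list", truth = "GroundTruth", phantom = "PhantomSpec",
                 params = "AcquisitionParams", magState = "character"))

#' AcquisitionPair: matched magnet-off / magnet-on sets from one session
#'
#' Both members share one speckle realization (identical static scatterer
#' field) and differ in magnetomotive modulation and independent noise.
#'
#' @slot off,on \linkS4class{MMUSAcquisition}.
#' @exportClass AcquisitionPair
setClass("AcquisitionPair",
  representation(off = "MMUSAcquisition", on = "MMUSAcquisition"))

setValidity("AcquisitionPair", function(object) {
  if (object@off@magState != "OFF" || object@on@magState != "ON")
    return("off/on members must carry magState 'OFF'/'ON'")
  TRUE
})

# ---- quantification / calibration ------------------------------------------

#' ROI: rectangular region of interest
#'
#' Pixel indices are 0-based and half-open: the ROI covers columns
#' [x0, x1) and rows [z0, z1) of the amplitude map, matching array
#' conventions of imaging tool chains.
#'
#' @slot x0,z0,x1,z1 integer pixel bounds, x1 > x0, z1 > z0.
#' @slot label character.
#' @exportClass ROI
setClass("ROI",
  representation(x0 = "integer", z0 = "integer", x1 = "integer",
                 z1 = "integer", label = "character"))

setValidity("ROI", function(object) {
  if (object@x0 < 0L || object@z0 < 0L) return("ROI origin must be >= 0")
  if (object@x1 <= object@x0 || object@z1 <= object@z0)
    return("ROI must satisfy x1 > x0 and z1 > z0 (half-open rectangle)")
  TRUE
})

#' CalibrationFit: power-law calibration of signal against elastic modulus
#'
#' Parameterizes signal = alpha * E^(-beta): a least-squares line on
#' (log E, log signal). \code{beta > 0} encodes the inverse
#' signal-stiffness relation.
#'
#' @slot alpha numeric > 0, signal at E = 1 Pa (model units).
#' @slot beta numeric > 0, power-law exponent.
#' @slot concentration numeric, nM (NA when unstratified).
#' @slot fieldStrength numeric, mT (NA when unstratified).
#' @slot residualSd numeric, residual sd on the log scale.
#' @slot nPoints integer, calibration points used (>= 3 distinct moduli).
#' @exportClass CalibrationFit
setClass("CalibrationFit",
  representation(alpha = "numeric", beta = "numeric", concentration = "numeric",
                 fieldStrength = "numeric", residualSd = "numeric",
                 nPoints = "integer"))

setValidity("CalibrationFit", function(object) {
  if (!is.finite(object@alpha) || object@alpha <= 0) return("alpha must be > 0")
  if (!is.finite(object@beta) || object@beta <= 0)
    return("beta must be > 0 (inverse signal-stiffness relation)")
  if (object@nPoints < 3L) return("at least 3 calibration points are required")
  TRUE
})

#' LODResult: limit-of-detection estimate
#'
#' @slot lod numeric, lowest reliably detected concentration in nM;
#'   \code{NA} when no tested concentration is detected.
#' @slot detected logical, whether any concentration met the criterion.
#' @slot threshold numeric, detection threshold on the signal scale
#'   (background mean + k * sd).
#' @slot replicates integer, background replicates used.
#' @exportClass LODResult
setClass("LODResult",
  representation(lod = "numeric", detected = "logical", threshold = "numeric",
                 replicates = "integer"))
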