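# Generics and accessors. Slot access from user code should go through
# these; the slot layout is not part of the API.

#' @rdname IQStack-class
#' @param object,x an object.
#' @export
setGeneric("iqData", function(object) standardGeneric("iqData"))

#' @rdname PhaseStack-class
#' @export
setGeneric("phaseData", function(object) standardGeneric("phaseData"))

#' @rdname IQStack-class
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname IQStack-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname IQStack-class
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname IQStack-class
#' @export
setGeneric("magState", function(object) standardGeneric("magState"))

#' @rdname DemodResult-class
#' @export
setGeneric("amplitude", function(object) standardGeneric("amplitude"))

#' @rdname DemodResult-class
#' @export
setGeneric("complexMean", function(object) standardGeneric("complexMean"))

#' @rdname AmplitudeMap-class
#' @export
setGeneric("mapKind", function(object) standardGeneric("mapKind"))

#' @rdname PhantomSpec-class
#' @export
setGeneric("gridShape", function(object) standardGeneric("gridShape"))

#' @rdname PhantomSpec-class
#' @export
setGeneric("wells", function(object) standardGeneric("wells"))

#' @rdname MMUSAcquisition-class
#' @export
setGeneric("loops", function(object) standardGeneric("loops"))

#' @rdname MMUSAcquisition-class
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname MMUSAcquisition-class
#' @export
setGeneric("acqParams", function(object) standardGeneric("acqParams"))

#' @rdname AcquisitionPair-class
#' @export
setGeneric("magOff", function(object) standardGeneric("magOff"))

#' @rdname AcquisitionPair-class
#' @export
setGeneric("magOn", function(object) standardGeneric("magOn"))

#' Trim an ensemble to a whole number of drive cycles
#'
#' Returns the longest frame prefix whose duration is an exact integer
#' number of cycles of the drive frequency \code{f0}, which makes the
#' single-bin demodulation mean exact (the DC term and any other
#' integer-cycle frequency average to exactly zero). A warning reports how
#' many frames were dropped.
#'
#' @param x an \linkS4class{IQStack} or \linkS4class{PhaseStack}.
#' @param f0 drive frequency, Hz; defaults to the stack's metadata.
#' @return an object of the same class, possibly with fewer frames.
#' @examples
#' iq <- array(exp(1i * 0.1 * (0:499)), c(1, 1, 500))
#' st <- new("IQStack", iq = iq, frameRate = 350, magState = "ON",
#'           meta = list(f0 = 5))
#' # 500 frames at 350 Hz cover 50/7 cycles; keep 490 frames (7 cycles)
#' nFrames(suppressWarnings(trimToIntegerCycles(st, f0 = 5)))
#' @export
setGeneric("trimToIntegerCycles",
           function(x, f0) standardGeneric("trimToIntegerCycles"))

#' Inject a bulk breathing-motion phase drift into simulated loops
#'
#' Adds a common (bulk) phase drift \code{amplitude * sin(2*pi*freq*n*dt)}
#' to every pixel of the affected loops, emulating respiratory tissue
#' motion in vivo. The drift frequency must differ from the magnetic drive
#' frequency, which would alias directly into the signal band.
#'
#' @param x an \linkS4class{IQStack} or \linkS4class{MMUSAcquisition}.
#' @param amplitude drift amplitude, rad (>= 0).
#' @param freq drift frequency, Hz.
#' @param affectedLoops integer indices of the loops to corrupt (for
#'   \code{MMUSAcquisition}).
#' @return the corrupted object, same class as \code{x}.
#' @export
setGeneric("injectBreathing",
           function(x, amplitude, freq, affectedLoops)
             standardGeneric("injectBreathing"))

#' @rdname demodulate
#' @export
setGeneric("demodulate", function(x, f0, ...) standardGeneric("demodulate"))

#' @rdname CalibrationFit-class
#' @export
setGeneric("calibrationStratum",
           function(object) standardGeneric("calibrationStratum"))
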