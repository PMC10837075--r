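# Synthetic MMUS acquisition simulator with known ground truth.
#
# Signal model, per pixel p and frame n (t_n = n/frameRate, n = 0..N-1):
#   IQ(p, n) = e(p) * exp(j * (phi(p) + a(p) * sin(2*pi*f0*t_n))) + w(p, n)
# where e(p) is Rayleigh speckle echogenicity, phi(p) a static uniform
# speckle phase, a(p) the magnetomotive phase amplitude (zero when the
# magnet is off) and w complex white noise. The phase amplitude derives
# from the magneto-elastic displacement d0 = kappa*c*B^2/E through the
# pulse-echo relation a = 4*pi*d0/lambda.

# per-nM echogenicity added by each agent relative to background 1;
# MNPs scatter ~10x less than the gas-vesicle-based agents
.AGENT_ECHO <- c(MGV = 5, GV = 5, MNP = 0.5)

#' Construct a WellSpec
#'
#' @param center integer(2), well centre (x, z) in 1-based pixels.
#' @param halfSize integer(2) (or scalar), half extent in pixels.
#' @param elasticModulus elastic modulus of the embedding medium, Pa.
#' @param concentration agent concentration, nM.
#' @param agent "MGV", "GV" or "MNP".
#' @return a \linkS4class{WellSpec}.
#' @examples
#' wellSpec(c(16, 16), 5, elasticModulus = 74, concentration = 0.4)
#' @export
wellSpec <- function(center, halfSize, elasticModulus, concentration,
                     agent = "MGV") {
  if (length(halfSize) == 1L) halfSize <- rep(halfSize, 2L)
  new("WellSpec", center = as.integer(center), halfSize = as.integer(halfSize),
      elasticModulus = as.numeric(elasticModulus),
      concentration = as.numeric(concentration), agent = agent)
}

#' Construct a PhantomSpec
#'
#' @param gridShape integer(2), image grid (nx, nz) in pixels.
#' @param pixelPitch pixel pitch, mm (0.1 mm matches a 128-element
#'   high-frequency linear array).
#' @param wells list of \linkS4class{WellSpec}.
#' @param backgroundEchogenicity mean background speckle brightness.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridShape = c(48L, 48L), pixelPitch = 0.1,
                        wells = list(), backgroundEchogenicity = 1) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      pixelPitch = as.numeric(pixelPitch), wells = wells,
      backgroundEchogenicity = as.numeric(backgroundEchogenicity))
}

#' Construct AcquisitionParams
#'
#' Defaults are the modelled in vitro acquisition conditions: 500-frame
#' ensembles at 500 Hz, 5 Hz sinusoidal drive at 30 mT, 15.6 MHz centre
#' frequency, 1540 m/s sound speed, 20 loops per set.
#'
#' @param frameRate frame rate, Hz.
#' @param nFrames frames per loop.
#' @param f0 magnetic drive frequency, Hz.
#' @param fieldStrength peak field, mT.
#' @param centerFreq transducer centre frequency, MHz.
#' @param soundSpeed speed of sound, m/s.
#' @param nLoops loops (independent ensembles) per set.
#' @param noiseSd complex-noise sd relative to background echogenicity.
#' @param couplingKappa magneto-elastic coupling, um*Pa/(nM*mT^2).
#' @param seed master integer seed.
#' @return an \linkS4class{AcquisitionParams}.
#' @export
acquisitionParams <- function(frameRate = 500, nFrames = 500L, f0 = 5,
                              fieldStrength = 30, centerFreq = 15.6,
                              soundSpeed = 1540, nLoops = 20L,
                              noiseSd = 0.05, couplingKappa = 1,
                              seed = 1L) {
  new("AcquisitionParams", frameRate = as.numeric(frameRate),
      nFrames = as.integer(nFrames), f0 = as.numeric(f0),
      fieldStrength = as.numeric(fieldStrength),
      centerFreq = as.numeric(centerFreq), soundSpeed = as.numeric(soundSpeed),
      nLoops = as.integer(nLoops), noiseSd = as.numeric(noiseSd),
      couplingKappa = as.numeric(couplingKappa), seed = as.integer(seed))
}

#' Magnetically induced displacement amplitude
#'
#' Magneto-elastic model d0 = kappa * c * B^2 / E: the magnetic gradient
#' force on unsaturated superparamagnetic particles scales with B^2, the
#' quasi-static Hookean response of the embedding medium with 1/E, and the
#' particle load linearly with concentration. \code{kappa} collects the
#' geometry- and material-dependent coupling into one constant.
#'
#' @param fieldStrength peak magnetic field B, mT.
#' @param elasticModulus elastic modulus E of the medium, Pa (> 0).
#' @param concentration agent concentration c, nM.
#' @param couplingKappa coupling constant kappa, um*Pa/(nM*mT^2).
#' @return displacement amplitude d0, um. Zero when concentration is 0.
#' @examples
#' displacementAmplitude(30, 74, 0.4)  # ~4.86 um at kappa = 1
#' @export
displacementAmplitude <- function(fieldStrength, elasticModulus,
                                  concentration, couplingKappa = 1) {
  if (any(!is.finite(elasticModulus)) || any(elasticModulus <= 0))
    .err("elasticModulus must be > 0")
  if (any(fieldStrength < 0) || any(concentration < 0) ||
      any(couplingKappa < 0))
    .err("fieldStrength, concentration and couplingKappa must be >= 0")
  couplingKappa * concentration * fieldStrength^2 / elasticModulus
}

#' Pulse-echo phase amplitude of an axial displacement
#'
#' An axial scatterer displacement d changes the round-trip echo path by
#' 2d, i.e. the received phase by delta-phi = 4*pi*d/lambda with
#' lambda = soundSpeed/centerFreq (um when m/s and MHz are used).
#'
#' @param displacement axial displacement, um (>= 0).
#' @param centerFreq transducer centre frequency, MHz.
#' @param soundSpeed speed of sound, m/s.
#' @return phase amplitude, rad.
#' @examples
#' phaseAmplitude(1, 15.6, 1540)  # lambda = 98.72 um -> 0.1273 rad
#' @export
phaseAmplitude <- function(displacement, centerFreq = 15.6,
                           soundSpeed = 1540) {
  if (any(displacement < 0)) .err("displacement must be >= 0")
  .assertScalarNum(centerFreq, "centerFreq", positive = TRUE)
  .assertScalarNum(soundSpeed, "soundSpeed", positive = TRUE)
  lambda <- soundSpeed / centerFreq  # um
  4 * pi * displacement / lambda
}

# Per-pixel ground-truth maps implied by a phantom + params.
.makeGroundTruth <- function(phantom, params) {
  gs <- phantom@gridShape
  disp <- matrix(0, gs[1L], gs[2L])
  modulus <- matrix(Inf, gs[1L], gs[2L])
  echo <- matrix(phantom@backgroundEchogenicity, gs[1L], gs[2L])
  for (w in phantom@wells) {
    b <- .wellBox(w)
    xs <- b[1L]:b[2L]; zs <- b[3L]:b[4L]
    modulus[xs, zs] <- w@elasticModulus
    echo[xs, zs] <- phantom@backgroundEchogenicity +
      .AGENT_ECHO[[w@agent]] * w@concentration
    d <- if (w@agent == "GV") 0 else
      displacementAmplitude(params@fieldStrength, w@elasticModulus,
                            w@concentration, params@couplingKappa)
    disp[xs, zs] <- d
  }
  phase <- phaseAmplitude(disp, params@centerFreq, params@soundSpeed)
  new("GroundTruth", displacementAmp = disp, phaseAmp = phase,
      modulusMap = modulus, echogenicityMap = echo)
}

# Speckle realization (static phase + Rayleigh echogenicity), shared
# between the OFF and ON members of a pair: depends only on (phantom,
# params@seed), not on the magnet state.
.makeSpeckle <- function(truth, seed) {
  npix <- length(truth@echogenicityMap)
  set.seed(deriveSeed(seed, 101L))
  phiStatic <- runif(npix, -pi, pi)
  # Rayleigh with unit mean (sigma = sqrt(2/pi)), floored at 0.25: deep
  # speckle nulls are cut off by the finite system point-spread function,
  # and an unfloored Rayleigh makes the per-pixel phase-noise floor
  # (~ noise/echo) infinite-variance, so background ROI means would not
  # concentrate
  ray <- pmax(sqrt(2 / pi) * sqrt(-2 * log(runif(npix))), 0.25)
  list(phiStatic = phiStatic,
       echo = ray * as.vector(truth@echogenicityMap))
}

.simulateLoop <- function(speckle, truth, params, magOn, loopSeed,
                          drivePhase = 0, bgEcho = 1) {
  gs <- dim(truth@phaseAmp)
  N <- params@nFrames
  tn <- (0:(N - 1L)) / params@frameRate
  a <- if (magOn) as.vector(truth@phaseAmp) else 0
  drive <- sin(2 * pi * params@f0 * tn + drivePhase)
  phase <- speckle$phiStatic + outer(if (magOn) a else rep(0, length(speckle$phiStatic)),
                                     drive)
  iq <- speckle$echo * exp(1i * phase)
  if (params@noiseSd > 0) {
    set.seed(loopSeed)
    sd1 <- params@noiseSd * bgEcho / sqrt(2)
    n <- length(iq)
    iq <- iq + complex(real = rnorm(n, 0, sd1), imaginary = rnorm(n, 0, sd1))
  }
  dim(iq) <- c(gs[1L], gs[2L], N)
  new("IQStack", iq = iq, frameRate = params@frameRate,
      magState = if (magOn) "ON" else "OFF",
      meta = list(f0 = params@f0, fieldStrength = params@fieldStrength,
                  centerFreq = params@centerFreq,
                  soundSpeed = params@soundSpeed, seed = params@seed))
}

#' Simulate one MMUS acquisition set
#'
#' Generates \code{nLoops} independent I/Q ensembles of a speckle phantom
#' whose agent-bearing wells oscillate axially at the magnetic drive
#' frequency (when \code{magOn}), together with the per-pixel ground
#' truth. The speckle realization depends only on the phantom and the
#' master seed, so magnet-off and magnet-on sets simulated with the same
#' parameters share their static scatterer field; frame noise is
#' independent per loop and per magnet state. Identical inputs give
#' bit-identical output.
#'
#' @param phantom a \linkS4class{PhantomSpec}.
#' @param params an \linkS4class{AcquisitionParams}.
#' @param magOn logical, magnetic drive on?
#' @param drivePhase phase offset of the drive sinusoid, rad.
#' @return an \linkS4class{MMUSAcquisition}.
#' @examples
#' ph <- phantomSpec(c(24L, 24L), wells = list(
#'   wellSpec(c(12, 12), 4, elasticModulus = 74, concentration = 0.4)))
#' acq <- simulateAcquisition(ph, acquisitionParams(nLoops = 2L, seed = 7L))
#' acq
#' @export
simulateAcquisition <- function(phantom, params, magOn = TRUE,
                                drivePhase = 0) {
  validObject(phantom); validObject(params)
  truth <- .makeGroundTruth(phantom, params)
  speckle <- .makeSpeckle(truth, params@seed)
  stateTag <- if (magOn) 1L else 0L
  loops <- lapply(seq_len(params@nLoops), function(l)
    .simulateLoop(speckle, truth, params, magOn,
                  deriveSeed(params@seed, 202L, stateTag, l), drivePhase,
                  bgEcho = phantom@backgroundEchogenicity))
  new("MMUSAcquisition", loops = loops, truth = truth, phantom = phantom,
      params = params, magState = if (magOn) "ON" else "OFF")
}

#' Simulate a matched magnet-off / magnet-on pair
#'
#' Both members share one speckle realization (same static scatterer
#' field and echogenicity draw) and differ only in the magnetomotive
#' modulation and in independent frame noise, mirroring paired
#' magnet-off/magnet-on sets acquired back to back in one session.
#'
#' @inheritParams simulateAcquisition
#' @return an \linkS4class{AcquisitionPair}.
#' @export
simulatePair <- function(phantom, params) {
  new("AcquisitionPair",
      off = simulateAcquisition(phantom, params, magOn = FALSE),
      on = simulateAcquisition(phantom, params, magOn = TRUE))
}

.injectBreathingStack <- function(stack, amplitude, freq) {
  if (amplitude < 0) .err("breathing amplitude must be >= 0")
  f0 <- stack@meta$f0
  if (!is.null(f0) && isTRUE(all.equal(as.numeric(freq), as.numeric(f0))))
    .err("breathing frequency equals the drive frequency f0 = %g Hz; such a drift would alias into the signal band", f0)
  if (amplitude == 0) return(stack)
  N <- dim(stack@iq)[3L]
  tn <- (0:(N - 1L)) / stack@frameRate
  drift <- exp(1i * amplitude * sin(2 * pi * freq * tn))
  iq <- stack@iq * rep(drift, each = prod(dim(stack@iq)[1:2]))
  initialize(stack, iq = iq)
}

#' @rdname injectBreathing
setMethod("injectBreathing", "IQStack",
  function(x, amplitude, freq, affectedLoops) {
    if (!missing(affectedLoops))
      .err("affectedLoops applies to MMUSAcquisition objects")
    .injectBreathingStack(x, amplitude, freq)
  })

#' @rdname injectBreathing
setMethod("injectBreathing", "MMUSAcquisition",
  function(x, amplitude, freq, affectedLoops) {
    affectedLoops <- as.integer(affectedLoops)
    if (any(affectedLoops < 1L) || any(affectedLoops > length(x@loops)))
      .err("affectedLoops out of range")
    for (l in affectedLoops)
      x@loops[[l]] <- .injectBreathingStack(x@loops[[l]], amplitude, freq)
    x
  })

#' Simulate a longitudinal stiffness time course
#'
#' One matched pair per scheduled day, with the scheduled elastic modulus
#' substituted into every well of the phantom template (emulating, e.g.,
#' progressive fibrosis stiffening monitored over days). Per-day seeds are
#' derived deterministically from the master seed and the day number.
#'
#' @param schedule data.frame with numeric columns \code{day} (strictly
#'   increasing) and \code{modulus} (Pa, > 0).
#' @param phantomTemplate a \linkS4class{PhantomSpec}.
#' @param params an \linkS4class{AcquisitionParams}.
#' @return a list with one element per day:
#'   \code{list(day, pair, truth)} where \code{pair} is an
#'   \linkS4class{AcquisitionPair} and \code{truth} its magnet-on ground
#'   truth.
#' @export
simulateTimecourse <- function(schedule, phantomTemplate, params) {
  if (!is.data.frame(schedule) || nrow(schedule) == 0L)
    .err("schedule must be a non-empty data.frame(day, modulus)")
  if (!all(c("day", "modulus") %in% names(schedule)))
    .err("schedule needs columns 'day' and 'modulus'")
  if (any(diff(schedule$day) <= 0))
    .err("schedule days must be strictly increasing")
  if (any(schedule$modulus <= 0)) .err("schedule moduli must be > 0")
  lapply(seq_len(nrow(schedule)), function(i) {
    day <- schedule$day[i]
    ph <- phantomTemplate
    ph@wells <- lapply(ph@wells, function(w) {
      w@elasticModulus <- schedule$modulus[i]
      w
    })
    p <- params
    p@seed <- deriveSeed(params@seed, 303L, as.integer(round(day)))
    pair <- simulatePair(ph, p)
    list(day = day, pair = pair, truth = groundTruth(magOn(pair)))
  })
}
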