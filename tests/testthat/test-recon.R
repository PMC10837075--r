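# Reconstruction: temporal phase unwrapping, integer-cycle trimming,
# single-bin quadrature demodulation, difference images and loop
# rejection.

test_that("unwrapping restores continuous phase from wrapped I/Q", {
  # constant phase: unchanged
  N <- 64L
  const <- iqStackFromPhase(array(1.2, c(2, 2, N)), 500)
  expect_equal(phaseData(unwrapPhase(const)), array(1.2, c(2, 2, N)))
  # wrapped linear ramp 0.1*n crosses pi at n = 32 and must come back
  # continuous
  n <- 0:199
  ramp <- iqStackFromPhase(array(0.1 * n, c(1, 1, 200)), 500)
  expect_equal(as.vector(phaseData(unwrapPhase(ramp))), 0.1 * n,
               tolerance = 1e-12)
  # random-walk phase with |steps| < pi: recovered up to a global 2*pi
  set.seed(42)
  for (rep in 1:5) {
    steps <- runif(149, -3, 3)
    orig <- cumsum(c(runif(1, -10, 10), steps))
    st <- iqStackFromPhase(array(orig, c(1, 1, 150)), 500)
    rec <- as.vector(phaseData(unwrapPhase(st)))
    k <- (rec[1] - orig[1]) / (2 * pi)
    expect_equal(k, round(k), tolerance = 1e-9)
    expect_equal(rec - 2 * pi * k, orig, tolerance = 1e-9)
  }
})

test_that("zero-magnitude samples carry the previous phase forward", {
  ph <- array(0.1 * (0:49), c(1, 1, 50))
  iq <- exp(1i * ph)
  iq[1, 1, 10] <- 0 + 0i
  st <- new("IQStack", iq = iq, frameRate = 500, magState = "ON",
            meta = list())
  up <- unwrapPhase(st)
  expect_identical(up@flaggedPixels, 1L)
  v <- as.vector(phaseData(up))
  expect_equal(v[10], v[9])       # held
  expect_equal(v[11], 0.1 * 10)   # resumes the true trace
})

test_that("trimming keeps the longest whole-cycle prefix", {
  mk <- function(N, fr) iqStackFromPhase(array(0, c(1, 1, N)), fr,
                                         meta = list(f0 = 5))
  # 500 frames at 500 Hz = 5 whole cycles: untouched, no warning
  expect_silent(tr <- trimToIntegerCycles(mk(500L, 500), 5))
  expect_identical(nFrames(tr), 500L)
  # 500 frames at 350 Hz: 7 cycles of 70 frames -> 490
  expect_warning(tr <- trimToIntegerCycles(mk(500L, 350), 5), "trimmed 10")
  expect_identical(nFrames(tr), 490L)
  # under one cycle: error
  expect_error(trimToIntegerCycles(mk(60L, 500), 5), "less than one")
  # works identically on phase stacks
  ps <- phaseStackFromTrace(rep(0, 500), 350, f0 = 5)
  expect_warning(tp <- trimToIntegerCycles(ps, 5), "trimmed 10")
  expect_identical(nFrames(tp), 490L)
})

test_that("demodulation recovers sinusoid amplitude and rejects DC and off-band", {
  fr <- 500; N <- 500L; t <- (0:(N - 1)) / fr
  # DC + 0.2 rad sinusoid: amplitude exactly 0.2 (factor 2 restores the
  # half-amplitude of the complex mean)
  A <- amplitude(demodulate(
    phaseStackFromTrace(0.3 + 0.2 * sin(2 * pi * 5 * t), fr), 5))
  expect_lt(abs(A[1, 1] - 0.2), 1e-12)
  # constant phase: exactly zero over whole cycles
  A0 <- amplitude(demodulate(phaseStackFromTrace(rep(0.7, N), fr), 5))
  expect_lt(A0[1, 1], 1e-12)
  # off-frequency integer-cycle sinusoid (7 Hz vs 5 Hz bin): exact zero
  A7 <- amplitude(demodulate(
    phaseStackFromTrace(0.5 * sin(2 * pi * 7 * t), fr), 5))
  expect_lt(A7[1, 1], 1e-12)
  # drive at/above Nyquist rejected
  expect_error(demodulate(phaseStackFromTrace(rep(0, N), fr), 250),
               "Nyquist")
  # non-integer cycles warn
  expect_warning(demodulate(phaseStackFromTrace(rep(0, 480L), 350), 5),
                 "non-integer")
})

test_that("amplitude recovery holds for any amplitude, phase and DC offset", {
  fr <- 500; N <- 500L; t <- (0:(N - 1)) / fr
  set.seed(7)
  for (rep in 1:20) {
    a <- runif(1, 0.01, pi - 0.01)
    theta <- runif(1, 0, 2 * pi)
    dc <- runif(1, -5, 5)
    A <- amplitude(demodulate(
      phaseStackFromTrace(dc + a * sin(2 * pi * 5 * t + theta), fr), 5))
    expect_lt(abs(A[1, 1] - a), 1e-9)
  }
})

test_that("demodulation is linear and matches the brute-force Fourier oracle", {
  set.seed(99)
  for (rep in 1:5) {
    ph <- array(rnorm(6 * 5 * 100), c(6, 5, 100))
    ps <- new("PhaseStack", phase = ph, frameRate = 100, magState = "ON",
              flaggedPixels = 0L, meta = list())
    A <- amplitude(demodulate(ps, 5))
    expect_lt(max(abs(A - bruteForceAmplitude(ph, 100, 5))), 1e-10)
    # scaling the phase stack by s scales A by |s| exactly
    ps3 <- new("PhaseStack", phase = -3 * ph, frameRate = 100,
               magState = "ON", flaggedPixels = 0L, meta = list())
    expect_equal(amplitude(demodulate(ps3, 5)), 3 * A, tolerance = 1e-12)
  }
})

test_that("difference images subtract baselines and clamp at zero", {
  m <- function(v, kind = "SINGLE") new("AmplitudeMap",
                                        values = matrix(v, 2, 2), kind = kind)
  on <- m(c(1, 2, 3, 4)); off <- m(c(0.5, 3, 1, 4))
  d <- deltaMap(on, off)
  expect_identical(mapKind(d), "DELTA")
  expect_equal(amplitude(d), matrix(c(0.5, 0, 2, 0), 2, 2))
  # identical maps -> zero; zero baseline -> unchanged
  expect_true(all(amplitude(deltaMap(on, on)) == 0))
  expect_equal(amplitude(deltaMap(on, m(0))), amplitude(on))
  # translation consistency: delta(x + c, x) = c
  onc <- m(c(1, 2, 3, 4) + 0.7)
  expect_equal(amplitude(deltaMap(onc, on)), matrix(0.7, 2, 2))
  expect_error(deltaMap(on, new("AmplitudeMap", values = matrix(0, 3, 3),
                                kind = "SINGLE")), "shape")
})

test_that("loop rejection keeps clean loops and errors when all fail", {
  acq <- simulateAcquisition(smallPhantom(16L), fastParams(81L, nLoops = 6L))
  phases <- lapply(loops(acq), unwrapPhase)
  # infinite threshold: everything kept
  expect_length(rejectLoops(phases, threshold = Inf)$kept, 6L)
  # clean loops at the default threshold: all kept
  rj <- rejectLoops(phases)
  expect_identical(rj$rejected, integer(0))
  expect_length(rj$kept, 6L)
  # all loops over threshold: informative error
  expect_error(rejectLoops(phases, threshold = 0), "review the threshold")
})

test_that("corrupted loops separate cleanly from clean loops", {
  acq <- simulateAcquisition(smallPhantom(20L), fastParams(91L, nLoops = 10L))
  corr <- injectBreathing(acq, 1, 1, affectedLoops = 1:5)
  rj <- rejectLoops(lapply(loops(corr), unwrapPhase))
  expect_identical(rj$rejected, 1:5)
  expect_length(rj$kept, 5L)
})
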