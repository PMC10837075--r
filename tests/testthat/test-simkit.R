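# Synthetic acquisition generator: magneto-elastic displacement law,
# pulse-echo phase conversion, speckle/noise model, determinism and
# artefact injection.

test_that("displacement follows the magneto-elastic law kappa*c*B^2/E", {
  d <- displacementAmplitude(30, 74, 0.4, couplingKappa = 1)
  expect_equal(d, 0.4 * 900 / 74, tolerance = 1e-12)
  # halving with stiffness, quadratic in field, linear in concentration
  expect_equal(displacementAmplitude(30, 148, 0.4), d / 2)
  expect_equal(displacementAmplitude(60, 74, 0.4), 4 * d)
  expect_equal(displacementAmplitude(30, 74, 0.8), 2 * d)
  expect_identical(displacementAmplitude(30, 74, 0), 0)
  expect_error(displacementAmplitude(30, 0, 0.4), "elasticModulus")
  expect_error(displacementAmplitude(30, -5, 0.4), "elasticModulus")
})

test_that("pulse-echo phase amplitude is 4*pi*d/lambda", {
  # quarter-wavelength displacement -> pi radians
  lambda <- 1540 / 15.6
  expect_equal(phaseAmplitude(lambda / 4), pi, tolerance = 1e-12)
  expect_identical(phaseAmplitude(0), 0)
  expect_equal(phaseAmplitude(1, 15.6, 1540), 0.12729, tolerance = 1e-4)
  expect_error(phaseAmplitude(1, centerFreq = 0), "centerFreq")
  expect_error(phaseAmplitude(-1), ">= 0")
})

test_that("phantom validity rejects out-of-bounds and overlapping wells", {
  expect_error(validObject(
    phantomSpec(c(16L, 16L),
                wells = list(wellSpec(c(2, 8), 4, 74, 0.4)))),
    "outside the grid")
  expect_error(validObject(
    phantomSpec(c(32L, 32L), wells = list(
      wellSpec(c(10, 10), 4, 74, 0.4),
      wellSpec(c(14, 14), 4, 564, 0.4)))),
    "overlap")
  expect_error(wellSpec(c(8, 8), 2, elasticModulus = -1,
                        concentration = 0.4), "positive")
})

test_that("acquisition parameter invariants are enforced", {
  expect_error(acquisitionParams(frameRate = 8, f0 = 5), "Nyquist")
  expect_error(acquisitionParams(nFrames = 50L, frameRate = 500, f0 = 5),
               "one drive cycle")
  expect_s4_class(acquisitionParams(), "AcquisitionParams")
})

test_that("ground truth encodes agent physics and geometry", {
  ph <- phantomSpec(c(32L, 32L), wells = list(
    wellSpec(c(8, 8), 3, 74, 0.4, agent = "MGV"),
    wellSpec(c(24, 8), 3, 74, 0.4, agent = "GV"),
    wellSpec(c(16, 24), 3, 74, 0.4, agent = "MNP")))
  p <- fastParams(1L)
  tr <- groundTruth(simulateAcquisition(ph, p, magOn = TRUE))
  # MGV well moves; GV well is echogenic but static; MNP moves, dim echo
  expect_gt(tr@displacementAmp[8, 8], 0)
  expect_identical(tr@displacementAmp[24, 8], 0)
  expect_gt(tr@displacementAmp[16, 24], 0)
  expect_gt(tr@echogenicityMap[24, 8], tr@echogenicityMap[16, 24])
  # phase amplitude consistent with the pulse-echo relation
  expect_equal(tr@phaseAmp, phaseAmplitude(tr@displacementAmp,
                                           p@centerFreq, p@soundSpeed))
  # background: rigid, background echogenicity, no motion
  expect_identical(tr@displacementAmp[1, 1], 0)
  expect_identical(tr@modulusMap[1, 1], Inf)
})

test_that("same seed gives bit-identical stacks; magnet states share speckle", {
  ph <- smallPhantom(16L)
  p <- fastParams(11L, nLoops = 2L)
  a1 <- simulateAcquisition(ph, p, magOn = TRUE)
  a2 <- simulateAcquisition(ph, p, magOn = TRUE)
  expect_identical(iqData(loops(a1)[[1L]]), iqData(loops(a2)[[1L]]))
  expect_identical(iqData(loops(a1)[[2L]]), iqData(loops(a2)[[2L]]))
  # loops are independent realizations
  expect_false(identical(iqData(loops(a1)[[1L]]), iqData(loops(a1)[[2L]])))
  # paired OFF/ON share the static scatterer field: mean |IQ| maps agree
  pr <- simulatePair(ph, p)
  mOff <- apply(Mod(iqData(loops(magOff(pr))[[1L]])), 1:2, mean)
  mOn <- apply(Mod(iqData(loops(magOn(pr))[[1L]])), 1:2, mean)
  expect_lt(max(abs(mOff - mOn)), 5 * p@noiseSd)
})

test_that("agent-free phantoms show no magnet-on/off contrast", {
  ph <- smallPhantom(16L, conc = 0)
  sbrs <- vapply(1:10, function(s) {
    pr <- simulatePair(ph, fastParams(400L + s, nLoops = 2L))
    pairDeltaSBR(pr, centreWellROI(16L), roi(0, 0, 5, 5, "bg"))
  }, numeric(1L))
  expect_true(all(sbrs >= 0.5 & sbrs <= 2))
})

test_that("magnet-off sets sit at the agent-free noise floor", {
  phAgent <- smallPhantom(16L, conc = 0.4)
  phFree <- smallPhantom(16L, conc = 0)
  p <- fastParams(21L, nLoops = 2L)
  offA <- amplitude(reconstructAmplitude(
    simulateAcquisition(phAgent, p, magOn = FALSE))$map)
  freeA <- amplitude(reconstructAmplitude(
    simulateAcquisition(phFree, p, magOn = TRUE))$map)
  expect_lt(max(offA), 3 * max(freeA))
})

test_that("noiseless magnet-on wells reconstruct the true phase amplitude", {
  ph <- smallPhantom(16L)
  p <- fastParams(31L, nLoops = 1L, noiseSd = 0)
  acq <- simulateAcquisition(ph, p, magOn = TRUE)
  tr <- groundTruth(acq)
  A <- amplitude(reconstructAmplitude(acq)$map)
  wellpx <- tr@phaseAmp > 0
  expect_lt(max(abs(A[wellpx] - tr@phaseAmp[wellpx])), 1e-6)
})

test_that("well amplitudes at noiseSd = 0.01 are within 10% of truth", {
  ph <- smallPhantom(16L)
  p <- fastParams(41L, nLoops = 2L, noiseSd = 0.01)
  pr <- simulatePair(ph, p)
  tr <- groundTruth(magOn(pr))
  A <- amplitude(reconstructAmplitude(magOn(pr))$map)
  wellpx <- tr@phaseAmp > 0
  expect_lt(max(abs(A[wellpx] - tr@phaseAmp[wellpx]) / tr@phaseAmp[wellpx]),
            0.1)
})

test_that("breathing injection is a pure bulk phase drift", {
  ph <- smallPhantom(16L)
  acq <- simulateAcquisition(ph, fastParams(51L, nLoops = 4L))
  # amplitude zero: unchanged
  same <- injectBreathing(acq, 0, 1, affectedLoops = 1:2)
  expect_identical(iqData(loops(same)[[1L]]), iqData(loops(acq)[[1L]]))
  # drive-frequency drift is rejected (would alias into the signal band)
  expect_error(injectBreathing(acq, 1, 5, affectedLoops = 1L), "alias")
  # motion metric strictly increases on every affected loop
  corr <- injectBreathing(acq, 1, 1, affectedLoops = c(1L, 3L))
  m0 <- vapply(loops(acq), loopMotionMetric, numeric(1L))
  m1 <- vapply(loops(corr), loopMotionMetric, numeric(1L))
  expect_true(all(m1[c(1L, 3L)] > m0[c(1L, 3L)]))
  expect_equal(m1[c(2L, 4L)], m0[c(2L, 4L)])
  # magnitudes untouched: the artefact only rotates phases
  expect_equal(Mod(iqData(loops(corr)[[1L]])), Mod(iqData(loops(acq)[[1L]])))
})

test_that("injected loops are exactly those flagged at the default threshold", {
  ph <- smallPhantom(16L)
  acq <- simulateAcquisition(ph, fastParams(61L, nLoops = 8L))
  corr <- injectBreathing(acq, 1, 1, affectedLoops = c(2L, 5L, 7L))
  rj <- rejectLoops(lapply(loops(corr), unwrapPhase))
  expect_identical(rj$rejected, c(2L, 5L, 7L))
})

test_that("timecourse schedules substitute moduli and derive per-day seeds", {
  ph <- smallPhantom(16L)
  p <- fastParams(71L, nLoops = 1L)
  expect_error(simulateTimecourse(data.frame(), ph, p), "non-empty")
  expect_error(simulateTimecourse(data.frame(day = c(5, 5),
                                             modulus = c(74, 74)), ph, p),
               "strictly increasing")
  one <- simulateTimecourse(data.frame(day = 5, modulus = 74), ph, p)
  expect_length(one, 1L)
  tc <- simulateTimecourse(data.frame(day = c(5, 9), modulus = c(74, 564)),
                           ph, p)
  w1 <- wells(magOn(tc[[1L]]$pair)@phantom)[[1L]]
  w2 <- wells(magOn(tc[[2L]]$pair)@phantom)[[1L]]
  expect_equal(c(w1@elasticModulus, w2@elasticModulus), c(74, 564))
  # deterministic: rebuilding the course reproduces it exactly
  tc2 <- simulateTimecourse(data.frame(day = c(5, 9), modulus = c(74, 564)),
                            ph, p)
  expect_identical(iqData(loops(magOn(tc[[2L]]$pair))[[1L]]),
                   iqData(loops(magOn(tc2[[2L]]$pair))[[1L]]))
})

test_that("stiffening schedules depress the delta-SBR series", {
  ph <- smallPhantom(16L)
  sched <- data.frame(day = c(5, 9, 13), modulus = c(74, 300, 1200))
  rs <- centreWellROI(16L); rb <- roi(0, 0, 5, 5, "bg")
  series <- sapply(1:4, function(s) {
    tc <- simulateTimecourse(sched, ph, fastParams(600L + s, nLoops = 2L))
    vapply(tc, function(d) pairDeltaSBR(d$pair, rs, rb), numeric(1L))
  })
  expect_true(all(diff(rowMeans(series)) < 0))
  # constant schedule: relative series flat within sampling error
  flat <- data.frame(day = c(5, 9, 13), modulus = c(74, 74, 74))
  rel <- sapply(1:6, function(s) {
    tc <- simulateTimecourse(flat, ph, fastParams(700L + s, nLoops = 2L))
    v <- vapply(tc, function(d) pairDeltaSBR(d$pair, rs, rb), numeric(1L))
    v / v[1L]
  })
  expect_true(all(abs(rowMeans(rel) - 1) < 0.15))
})
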