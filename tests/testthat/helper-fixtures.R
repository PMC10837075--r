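# Fixtures built in code: phase/IQ stacks with known content and small
# phantoms reused across tests.

# PhaseStack holding one pixel trace replicated over a tiny grid
phaseStackFromTrace <- function(trace, frameRate, nx = 1L, nz = 1L, f0 = NULL) {
  N <- length(trace)
  ph <- array(rep(trace, each = nx * nz), c(nx, nz, N))
  new("PhaseStack", phase = ph, frameRate = frameRate, magState = "ON",
      flaggedPixels = 0L, meta = if (is.null(f0)) list() else list(f0 = f0))
}

# IQStack with per-pixel phase array and unit magnitude
iqStackFromPhase <- function(phaseArr, frameRate, magState = "ON",
                             meta = list()) {
  new("IQStack", iq = exp(1i * phaseArr), frameRate = frameRate,
      magState = magState, meta = meta)
}

# single-well MGV phantom on a small grid
smallPhantom <- function(grid = 24L, modulus = 74, conc = 0.4,
                         agent = "MGV", half = 4L) {
  c0 <- as.integer(grid / 2)
  phantomSpec(c(grid, grid), wells = list(
    wellSpec(c(c0, c0), half, elasticModulus = modulus,
             concentration = conc, agent = agent)))
}

# fast acquisition settings for unit tests (integer drive cycles)
fastParams <- function(seed, nLoops = 2L, noiseSd = 0.05, frameRate = 200,
                       nFrames = 200L, fieldStrength = 30, ...) {
  acquisitionParams(frameRate = frameRate, nFrames = nFrames, f0 = 5,
                    fieldStrength = fieldStrength, nLoops = nLoops,
                    noiseSd = noiseSd, seed = seed, ...)
}

# centre-well sample ROI (0-based half-open) for smallPhantom(grid)
centreWellROI <- function(grid = 24L, half = 4L) {
  c0 <- as.integer(grid / 2)
  roi(c0 - half - 1L, c0 - half - 1L, c0 + half, c0 + half, "well")
}

cornerBgROI <- function(size = 6L) roi(0L, 0L, size, size, "background")

# independent brute-force single-bin Fourier amplitude (the oracle):
# elementwise per-pixel loop, no shared code with demodulate()
bruteForceAmplitude <- function(phaseArr, frameRate, f0) {
  d <- dim(phaseArr)
  N <- d[3L]
  A <- matrix(NA_real_, d[1L], d[2L])
  for (ix in seq_len(d[1L])) {
    for (iz in seq_len(d[2L])) {
      acc <- 0 + 0i
      for (n in seq_len(N)) {
        acc <- acc + phaseArr[ix, iz, n] *
          exp(1i * 2 * pi * f0 * (n - 1) / frameRate)
      }
      A[ix, iz] <- 2 * Mod(acc / N)
    }
  }
  A
}

# delta-SBR of one simulated pair via the full pipeline
pairDeltaSBR <- function(pair, sampleROI, bgROI, reject = FALSE) {
  recOn <- reconstructAmplitude(magOn(pair), reject = reject)
  recOff <- reconstructAmplitude(magOff(pair), reject = reject)
  sbr(deltaMap(recOn$map, recOff$map), sampleROI, bgROI)
}
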