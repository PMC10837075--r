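---
title: "Magnetomotive ultrasound stiffness imaging with mmus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetomotive ultrasound stiffness imaging with mmus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmus)
```

## The measurement

Magnetomotive ultrasound (MMUS) images tissue stiffness indirectly: an
oscillating magnetic field exerts a gradient force on superparamagnetic
contrast agents — here magneto-gas vesicles (MGVs), gas-vesicle protein
nanostructures conjugated with superparamagnetic iron-oxide nanoparticles —
and the resulting micrometre-scale axial motion of the surrounding medium
is read out through the phase of beamformed ultrasound I/Q data. Softer
media let the agents move more; stiffer media restrict them. The motion
amplitude at the drive frequency is therefore a stiffness probe, and
because gas vesicles also scatter sound strongly, the same agent provides
an independent echogenicity channel that reports where the agent is.

`mmus` implements the full analysis chain — reconstruction of motion
amplitude maps from I/Q ensembles, magnet-on/magnet-off difference
imaging, ROI quantification, and stiffness calibration — together with a
synthetic acquisition generator that provides ground truth for validating
every stage.

## Reconstruction model

An acquisition is a stack of `N` complex frames
$R_I(x,z,n) + jR_Q(x,z,n)$ sampled at frame rate $1/\delta t$. The
per-pixel phase

$$r(x,z,n) = \arg\!\big(R_I + jR_Q\big)$$

tracks axial scatterer displacement $d$ through the pulse-echo relation
$\Delta\varphi = 4\pi d/\lambda$ with $\lambda = c/f_c$ (the factor two
relative to the one-way path because the echo travels there and back).
`unwrapPhase()` unwraps this sequence *temporally, per pixel* — the
quantity of interest oscillates along the frame axis; nothing in the
model couples neighbouring pixels, so no spatial unwrapping is performed.
Consecutive differences are mapped into $(-\pi, \pi]$ and re-accumulated;
zero-magnitude samples, whose phase is undefined, inherit the previous
frame's phase, and affected pixels are counted in `flaggedPixels`.

`demodulate()` is a single-bin discrete Fourier (lock-in) detector at the
magnetic drive frequency $f_0$:

$$\bar R(x,z) = \frac{1}{N}\sum_{n=0}^{N-1} r(x,z,n)\,
  e^{\,j2\pi f_0 n \delta t}, \qquad
  A(x,z) = 2\,\lvert\bar R\rvert = 2\sqrt{I^2 + Q^2}.$$

The plain mean — not a low-pass filter — is used deliberately: over an
integer number of drive cycles the mean annihilates the DC term and
*every* other integer-cycle frequency exactly, so for a noiseless phase
sinusoid of amplitude $a$ the estimate satisfies $A = a$ to machine
precision (the factor 2 restores the half amplitude carried by the
single-sided complex mean). This exactness is the reason for
`trimToIntegerCycles()`: ensembles whose duration is not a whole number
of cycles (e.g. 500 frames at 350 Hz with a 5 Hz drive) are trimmed to
the longest whole-cycle prefix (490 frames, 7 cycles) with a warning
recording the frames dropped; trimming is preferred to windowing because
it preserves the exact-orthogonality property instead of trading it for
side-lobe suppression. Frames are indexed $n = 0..N-1$ and the exponent
sign is $+j$; both conventions only rotate $\bar R$ and leave $A$
unchanged.

Each loop (ensemble) of a set is reconstructed independently and the
per-loop amplitude maps are averaged. The alternative — averaging the
complex $\bar R$ across loops, which is equivalent to concatenating
frames — was evaluated and rejected: amplitude is phase-invariant, so
incoherent averaging of $A$ maps is robust to any loop-to-loop drift of
the drive phase, and it makes the background noise floor of a set scale
predictably with the number of loops averaged.

The difference image is `deltaMap(on, off)`: the baseline (magnet-off, or
pre-injection) amplitude map subtracted pixelwise from the
contrast-bearing map, with negative values clamped at zero. Clamping
reflects the one-sided physical expectation (turning the magnet on adds
motion); its statistical side effect is that the background of a
difference image has a small positive mean proportional to the noise
level of the two maps — see *Limitations*.

## Quantification

`sbr()` is the linear (not dB) ratio of the mean pixel intensity of a
sample ROI to that of a background ROI. ROIs are 0-based, half-open
rectangles, the convention of array-oriented imaging tool chains. The
primary stiffness readout is the *delta-SBR*: the SBR evaluated on the
difference image. A secondary summary, `sbrDifference()` =
SBR(on) − SBR(off), is exposed under its own name so the two definitions
cannot be conflated. Whether a background-subtracted variant
(mean~s~ − mean~b~)/mean~b~ is preferable is a live question; the pure
ratio was chosen and is flagged here rather than silently assumed.

`softnessIndex()` divides the MMUS SBR by the SBR of the
amplitude-modulation (AM) contrast channel. The AM signal scales with
local agent abundance but not with motion, so the ratio normalizes motion
per unit agent — higher means softer. `normalizeSeries()` rescales a
longitudinal series to its baseline day (the baseline entry becomes 1),
and `foldChange()` rounds group-mean ratios half away from zero with a
configurable number of decimals, matching the usual reporting convention
for "x-fold" comparisons.

## Calibration

The signal–stiffness relation is modelled as a power law
$s = \alpha E^{-\beta}$, fitted by least squares on
$(\log E, \log s)$ — the simplest monotone family consistent with an
inverse relation; $\beta$ is estimated, not fixed at 1. Fits are per
(concentration, field) stratum. `estimateModulus()` inverts the fitted
law, $E = (\alpha/s)^{1/\beta}$, and `detectableModulusRange()` returns
the stiffest modulus whose predicted signal clears a threshold,
$E_{\max} = (\alpha/\mathrm{thr})^{1/\beta}$; because concentration
enters $\alpha$ roughly linearly, higher agent concentrations broaden the
detectable range.

`estimateLOD()` uses the conventional three-sigma rule: a concentration
is detected when its replicate mean exceeds the background mean plus
$k\,\mathrm{sd}$ ($k = 3$ by default), and the limit of detection is the
smallest tested concentration that is detected *with all larger tested
concentrations also detected* — an isolated exceedance below a gap does
not count. When nothing qualifies the result is explicitly flagged
not-detected rather than extrapolated.

## The synthetic acquisition generator

`simulateAcquisition()` emulates one imaging session on a speckle
phantom. Per pixel $p$ and frame $n$:

$$IQ(p,n) = e(p)\,
  \exp\!\big(j\,[\varphi(p) + a(p)\sin(2\pi f_0 t_n)]\big) + w(p,n)$$

* **Speckle.** $\varphi(p) \sim U[-\pi,\pi)$ is a static scatterer
  phase; $e(p)$ is Rayleigh-distributed echogenicity with unit mean,
  scaled by the background brightness plus a concentration-proportional
  agent term. The Rayleigh draw is floored at 0.25 of its mean: perfect
  interference nulls are cut off in practice by the finite point-spread
  function, and an unfloored Rayleigh makes the per-pixel phase-noise
  floor ($\propto 1/e$) a heavy-tailed quantity whose ROI means do not
  concentrate — background statistics would then be dominated by a few
  dark pixels.
* **Magnetomotion.** The displacement amplitude follows the
  magneto-elastic law $d_0 = \kappa c B^2 / E$: gradient force on
  unsaturated superparamagnets $\propto B^2$, quasi-static Hookean
  response $\propto 1/E$, particle load linear in concentration $c$. All
  geometry and material coupling is collected in the single constant
  $\kappa$ (µm·Pa/(nM·mT²)), a free parameter of the model; the default
  $\kappa = 1$ gives sub-wavelength axial displacements (≈ 4.9 µm at
  0.4 nM, 30 mT, 74 Pa against $\lambda \approx 99$ µm) consistent with
  magnetomotive practice. Absolute amplitudes are therefore in model
  units; only ratios (SBR, fold changes) are comparable across settings.
  Agent physics: MGVs are echogenic *and* magnetically actuatable, plain
  gas vesicles are echogenic but contribute zero displacement, bare
  nanoparticles move but scatter ten times less (configurable).
* **Noise.** Additive circular complex Gaussian noise with total sd
  `noiseSd` relative to the background echogenicity, independent per
  frame, pixel and loop.
* **Pairs and loops.** A set is `nLoops` independent ensembles;
  `simulatePair()` generates matched magnet-off/magnet-on sets sharing
  one speckle realization (same static scatterer field) with independent
  noise, as in back-to-back acquisition. All randomness derives from one
  master seed through documented per-stream derivations (speckle, per
  loop × magnet state, per day), so identical inputs give bit-identical
  stacks.

Defaults are the modelled acquisition conditions: 500-frame ensembles at
500 Hz, a 5 Hz sinusoidal drive at 30 mT, 15.6 MHz centre frequency,
1540 m/s sound speed, 20 loops per set; the in vivo-like variant runs at
350 Hz, where ensembles no longer cover whole drive cycles and trimming
becomes active.

`injectBreathing()` models respiratory motion as a *bulk* phase drift
$A_b \sin(2\pi f_b t)$ added to every pixel of the affected loops. Two
properties of this model matter. First, over an ensemble covering whole
cycles of both frequencies the drift is exactly orthogonal to the drive
bin and cannot bias the demodulated amplitude; it is at the in vivo
frame rate, where the trimmed ensemble spans a non-integer number of
drift cycles, that the drift leaks into the signal band and corrupts the
difference image. Second, a drift injected identically into both members
of a pair leaks identically into both amplitude maps and cancels in the
subtraction; the artefact experiments therefore corrupt the
contrast-bearing set, which is also the physically interesting case
(the baseline can be acquired when the animal is still).

```{r breathing-example}
ph <- phantomSpec(c(24L, 24L), wells = list(
  wellSpec(c(12L, 12L), 4L, elasticModulus = 74, concentration = 0.4)))
p <- acquisitionParams(frameRate = 350, nFrames = 250L, nLoops = 4L,
                       noiseSd = 0.05, seed = 1L)
acq <- injectBreathing(simulateAcquisition(ph, p), amplitude = 1,
                       freq = 1, affectedLoops = 1:2)
round(vapply(loops(acq), loopMotionMetric, numeric(1)), 4)
```

## Loop rejection

Motion-corrupted loops are scored by `loopMotionMetric()`: the RMS over
frames of the *spatial median* of the phase excursion relative to the
first frame. Bulk motion moves every pixel coherently and passes the
spatial median undamped, while independent speckle phase noise is
suppressed by roughly $1/\sqrt{n_\mathrm{pix}}$ and a localized
magnetomotive signal barely shifts the median as long as the moving
region is a minority of the field of view. A per-pixel metric (e.g. the
mean absolute frame-to-frame difference) was considered and rejected: it
is dominated by speckle phase noise, which at realistic noise levels
exceeds the per-frame increment of even a 1 rad bulk drift, so it cannot
separate corrupted from clean loops.

`rejectLoops()` removes loops whose metric exceeds a threshold; the
default is three times the *lower quartile* of the loop metrics. The
lower quartile — rather than the median — anchors the threshold to the
clean-loop cluster even when up to half of the loops in a set are
corrupted, a regime in which any median-anchored rule is provably blind
(with half the mass in the corrupted cluster the median lies between the
clusters, and three times it exceeds the corrupted level). If every loop
exceeds the threshold the function stops with advice to review the
threshold rather than silently returning an empty set.

One estimator property is worth knowing: because the background of a
clamped difference image scales with
$\sqrt{1/n_\mathrm{on} + 1/n_\mathrm{off}}$, quantifying a set from
which half the loops were (correctly) rejected yields a delta-SBR about
$\sqrt{2/3} \approx 0.82$ of the full-set value — a replication-count
effect of the estimator, not residual artefact.

## Numerical choices and degenerate inputs

* Unwrapping ties: differences of exactly $\pm\pi$ are mapped to
  $+\pi$, keeping increments in $(-\pi,\pi]$.
* `trimToIntegerCycles()` uses a $10^{-9}$ relative tolerance for "whole
  cycle" and errors below one full cycle; `demodulate()` errors when
  $f_0$ is at or above the frame-rate Nyquist limit and warns on
  non-integer cycle counts instead of silently degrading.
* `sbr()` errors on a non-positive background mean (undefined ratio);
  `fitPowerLaw()` requires at least three distinct moduli and positive
  signals, and refuses data with no inverse relation (fitted
  $\beta \le 0$) rather than returning a misleading fit.
* `foldChange()` rounds half away from zero, so 2.5-fold reports as 3,
  not 2.
* Seeds are combined with a multiplicative congruential mix modulo
  $2^{31}-1$; derived seeds stay in 32-bit integer range.

## What the generator does and does not emulate

The generator reproduces the features the reconstruction depends on:
speckle statistics, phase-encoded axial motion at a known drive
frequency, field/concentration/stiffness scaling, paired sets with
shared speckle, loop structure, frame-rate/cycle mismatches and bulk
breathing drift. It does *not* emulate beamforming or plane-wave
compounding (the pipeline starts from beamformed I/Q), nonlinear
gas-vesicle acoustics (the AM contrast channel is represented by the
echogenicity ground truth), acoustic attenuation, speckle
decorrelation under large displacements, out-of-plane motion, or 3-D
volumes. Passing validation on synthetic data therefore demonstrates the
correctness of the *analysis* — unwrapping, demodulation, subtraction,
quantification, calibration — under the stated signal model, not the
fidelity of that model to any particular scanner.

Problem sizes used by the shipped validation suite were chosen to keep
the full run in the minutes range on one core: grids of 16–48 pixels a
side, 200–500-frame ensembles, 2–20 loops per set and about 10–64 seed
replicates per experiment, with the largest replicate counts reserved
for the artefact-rejection experiment whose comparison must resolve the
$\sqrt{2/3}$ replication floor described above.

## Limitations

* The magneto-elastic coupling $\kappa$ is not identifiable from imaging
  alone; absolute displacement scales are model units, and only
  stiffness *ratios* transfer across sessions through the power-law
  calibration.
* The clamped difference image has a noise-level-dependent positive
  background mean, so delta-SBR values depend on the number of loops
  averaged; longitudinal comparisons should keep loop counts constant
  (or use `normalizeSeries()` against a baseline acquired identically).
* The loop-rejection metric targets bulk motion; localized artefacts
  that move only part of the field of view are diluted by the spatial
  median and need a lower manual threshold.
* The power-law calibration is a deliberate simplification of the
  signal–modulus relation; it is monotone and invertible but makes no
  viscoelastic (frequency-dependent) claims.
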