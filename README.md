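# mmus — magnetomotive ultrasound stiffness imaging

`mmus` is an R package for analysing **magnetomotive ultrasound (MMUS)**
stiffness imaging with magneto-gas-vesicle (MGV) contrast agents, and for
simulating such acquisitions with known ground truth. It is aimed at
ultrasound/biomedical-imaging researchers who need a tested, reproducible
pipeline from complex I/Q frame ensembles to stiffness read-outs.

An oscillating magnetic field drives superparamagnetic agents embedded in
tissue; the induced axial micro-motion modulates the phase of beamformed
I/Q data and shrinks as the medium stiffens. The package reconstructs the
motion amplitude at the drive frequency `f0` per pixel:

```
r(x,z,n)  = arg(R_I + j R_Q)                      (temporal phase, unwrapped)
R(x,z,n)  = r(x,z,n) · exp(j·2π·f0·n·δt)          (quadrature detection)
A(x,z)    = 2·|mean_n R(x,z,n)| = 2·√(I² + Q²)    (amplitude at f0, rad)
```

Magnet-on minus magnet-off amplitude maps (clamped at zero) form **Δ
images**; ROI signal-to-background ratios (**SBR**), fold changes and the
**softness index** (MMUS SBR / AM-contrast SBR) quantify them; and a
power-law calibration `signal = α·E^(−β)` links signal to elastic modulus
`E`, with inversion, limit-of-detection and detectable-stiffness-range
estimators. The bundled simulator generates speckle phantoms whose agent
wells move according to the magneto-elastic law `d0 = κ·c·B²/E`, plus
breathing artefacts and longitudinal stiffness schedules, all
bit-reproducible from one seed.

## Worked example

Simulate a matched magnet-off/on session of one MGV well (74 Pa, 0.4 nM)
under a 5 Hz, 30 mT drive, reconstruct, and quantify:

```r
library(mmus)

ph <- phantomSpec(c(32L, 32L), wells = list(
  wellSpec(c(16L, 16L), 5L, elasticModulus = 74, concentration = 0.4)))
p  <- acquisitionParams(nLoops = 4L, seed = 42L)   # 500 frames @ 500 Hz
pair <- simulatePair(ph, p)

recOn  <- reconstructAmplitude(magOn(pair))
recOff <- reconstructAmplitude(magOff(pair))
dm <- deltaMap(recOn$map, recOff$map)
dm
#> AmplitudeMap (DELTA): 32 x 32, values in [0, 0.619] rad

sbr(dm, roi(10, 10, 22, 22, "well"), roi(0, 0, 32, 8, "background"))
#> [1] 859.8057
```

The well's reconstructed amplitude (0.6212 rad at its peak) matches the
simulated ground-truth phase amplitude (0.6193 rad): the agent's ~4.9 µm
displacement read through the 4πd/λ pulse-echo relation. The Δ-image SBR
of ~860 says the well's magnetically induced motion stands that far above
the agent-free background floor. Calibration and inversion:

```r
E <- c(63, 74, 564, 5828)                     # phantom moduli, Pa
fit <- fitPowerLaw(E, 2000 / E, concentration = 0.4, fieldStrength = 30)
fit
#> CalibrationFit: signal = 2000 * E^-1 (n = 4, log-sd 8.49e-16)
#>   stratum: 0.4 nM, 30 mT
estimateModulus(27, fit)
#> [1] 74.07407                                # Pa, from a measured signal

foldChange(110.1, 9.1, 0)                     # group-mean fold change
#> [1] 12
```

An end-to-end run (simulate → trim → unwrap → demodulate → reject loops →
average → Δ → SBR) is driven by a YAML/JSON config; see
`inst/extdata/example-config.yaml` and the schema next to it:

```r
res <- runExperiment(system.file("extdata", "example-config.yaml",
                                 package = "mmus"))
res$delta_sbr
```

A thin CLI wrapper (`inst/cli/mmus.R`) exposes `run` and `simulate`
subcommands over the same functions. The methods vignette
(`vignettes/mmus-methods.Rmd`) documents the signal model, the estimator
design choices and the generator's scope.

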