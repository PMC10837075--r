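Package: mmus
Title: Magnetomotive Ultrasound Stiffness Imaging: Simulation,
    Reconstruction and Calibration
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for magnetomotive ultrasound (MMUS)
    stiffness imaging with magneto-gas-vesicle contrast agents. Converts
    complex I/Q frame ensembles into magnetically induced
    displacement-amplitude maps by per-pixel temporal phase unwrapping and
    quadrature (single-bin Fourier) demodulation at the magnetic drive
    frequency, forms magnet-on minus magnet-off difference images,
    quantifies them by ROI signal-to-background ratios and softness
    indices, and calibrates the inverse signal-stiffness relation
    (power-law fit, modulus inversion, limit of detection, detectable
    stiffness range). Includes a synthetic acquisition simulator with
    known ground truth (speckle, magnetomotive phase modulation,
    breathing artefacts, longitudinal stiffness schedules) for validation
    and power analysis, plus persistent stack/map/ROI/result formats and
    an end-to-end experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
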