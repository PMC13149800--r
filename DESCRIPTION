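Package: freerunMRA
Title: Free-Running 4D Carotid MR Angiography Simulation, Reconstruction and
    Stiffness Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates a continuously acquired (free-running) 3D radial
    phyllotaxis MR angiography examination of a pulsating carotid-like vessel
    phantom, sorts the readouts into cardiac bins from pulse-oximeter triggers,
    reconstructs cardiac-resolved 4D images by compressed sensing with temporal
    total-variation regularization (ADMM with a Kaiser-Bessel gridding
    non-uniform Fourier operator), measures lumen diameters by full-width at
    half-maximum contouring, processes parallel synthetic M-mode ultrasound
    wall traces, derives the five carotid stiffness metrics (relative diameter
    change, stiffness index, arterial compliance, one-point pulse wave
    velocity, pressure-strain elastic modulus), and quantifies scan-rescan
    repeatability (ICC(2,1), coefficient of variation) and intermodality
    agreement (Bland-Altman, regression, paired tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
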