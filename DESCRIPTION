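Package: afdriverloc
Title: Non-Invasive Atrial Fibrillation Driver Localization from Body
    Surface Potentials
Version: 0.1.0
Authors@R:
    person("BSP", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Simulates atrial fibrillation on synthetic atrial surface
    meshes with an anisotropic monodomain model, projects transmembrane
    potentials to body-surface potentials through a dipole-summation
    forward model referenced to the Wilson Central Terminal, converts
    64-electrode body-surface frames into image tensors, and classifies
    the driver's atrial region (seven regions plus "no driver") with a
    compact convolutional neural network implemented in C++.  Includes
    calibrated noise corruption, zero-phase Butterworth band-pass
    filtering, two train/test split schemes, class weighting, and
    multiclass evaluation (accuracy, Cohen's kappa, per-class
    sensitivity and specificity, SNR robustness sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    yaml,
    withr
Config/testthat/edition: 3
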