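Package: synaps4d
Title: Synchronized Free-Running 4D Flow MRI Simulation and Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and reconstruction pipeline for 4D flow MRI
    built from two consecutively acquired free-running 3D radial sequences: a
    bright-blood fast-interrupted steady-state (FISS) anatomical acquisition and
    a balanced 4-point velocity-encoded phase-contrast (PC) acquisition,
    synchronized through pilot-tone physiological signals. Provides a dynamic
    beating and breathing digital torso phantom with pulsatile parabolic vessel
    flow, golden-angle and spiral-phyllotaxis radial trajectory generation,
    multi-coil non-uniform Fourier encoding with velocity-encoding phase and
    rigid respiratory displacement, pilot-tone cardiac trigger and respiratory
    curve extraction (PCA, FastICA, adaptive filtering), focused-navigation
    (fNAV) autofocus motion correction driven by gradient-image entropy,
    k-t sparse SENSE reconstruction with total-variation regularization along
    the cardiac and spatial dimensions, balanced 4-point velocity decoding, and
    dynamic vessel segmentation with flow quantification and agreement
    statistics (Dice, Pearson, linear regression, Bland-Altman, Wilcoxon).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    signal,
    EBImage,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
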