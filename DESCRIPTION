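Package: visreason
Title: Same-Different versus Spatial-Relation Visual Reasoning: Network
    Simulations, Adaptive Psychophysics and EEG Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the dichotomy between same-different (SD)
    and spatial-relation (SR) visual reasoning in feedforward networks and
    in EEG. Provides an exhaustive free-hexomino stimulus dictionary,
    paired-item stimulus generation and rendering on 50x80 rasters, a small
    convolutional network and a Siamese (segmentation-oracle) variant
    trained from scratch with an Adam optimizer, a QUEST Bayesian adaptive
    staircase with simulated Weibull observers, a synthetic multichannel
    EEG epoch generator with controllable ERP and beta-band effects, an ERP
    difference pipeline with pointwise t tests and Benjamini-Hochberg FDR
    correction, and a Morlet wavelet time-frequency pipeline with
    cluster-based permutation statistics and effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
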