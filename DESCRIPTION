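Package: dmsnet
Title: Dense Multi-Scale Convolutional Networks for Knee Osteoarthritis Grading
Version: 0.1.0
Authors@R: person("DMS", "Maintainers", email = "maintainers@dmsnet.dev", role = c("aut", "cre"))
Description: Implements the Dense Multi-Scale (DMS) convolutional architecture
    for 5-grade (Kellgren-Lawrence 0-4) knee osteoarthritis radiograph
    classification, together with its surrounding pipeline: radiograph
    preprocessing (Gaussian denoising, Sobel edge accumulation, histogram
    equalization), class-balancing augmentation (rotation, cropping, flipping),
    stratified splitting and training with gradient clipping, one-vs-rest
    confusion-matrix metrics with ROC/AUC, and class-activation heatmaps
    (plain and gradient-weighted). A synthetic phantom-radiograph generator
    with grade-monotone pathology features makes every stage testable without
    access to a clinical image corpus. The network, batch normalization,
    backpropagation and the Adam optimizer are implemented in the package
    (RcppArmadillo convolutions), so no external deep-learning framework is
    required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
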