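Package: slscgcnr
Title: Short-Lag Spatial Coherence Imaging and gCNR-Based Classification of
    Breast Masses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates raw ultrasound radiofrequency channel data for
    phantoms containing fluid, solid and mixed hypoechoic lesions; forms
    B-mode and short-lag spatial coherence (SLSC) images with both the
    offline coherence-function formulation and the real-time
    correlation-sum formulation; quantifies mass conspicuity with the
    generalized contrast-to-noise ratio (gCNR) on matched elliptical
    regions of interest; and evaluates threshold classification of mass
    content with ROC curves, trapezoidal AUC, optimal-threshold selection
    and Fleiss' kappa inter-rater agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
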