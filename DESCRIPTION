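Package: neuroBAG
Title: Multimodal Brain Age Prediction and Brain Age Gap Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for multimodal biological brain
    age estimation. Generates synthetic cohorts with configurable demographic
    and cardiovascular risk-factor structure, T1-like morphometry tables and
    phantom T1/TOF-MRA volumes with known age effects; extracts hand-crafted
    artery features (segmentation, 3D centerline thinning, distance-transform
    thickness, territory aggregation); trains multilayer perceptron and 3D
    convolutional age predictors under age-stratified cross-validation; fuses
    predictions by stacked linear regression; applies linear age-bias
    correction; and quantifies associations between the brain age gap and
    cardiovascular risk factors with false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml,
    withr,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
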