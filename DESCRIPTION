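Package: dermrad
Title: Dose-Gradient Multi-Region Radiomics Modelling of Radiation Dermatitis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for predicting grade >= 2 radiation-induced dermatitis in
    breast-cancer radiotherapy from planning CT, dose and clinical data. The
    package builds dose-gradient regions of interest (PTV sub-volumes at 100,
    105 and 108 percent of the prescription and 20/30/40 Gy skin isodose
    shells), extracts an 884-feature radiomics bank per region (shape,
    intensity, histogram, Gaussian-fit, GLCM, run-length and neighbourhood
    gray-tone difference families, 2.5D convention), screens features through
    a Mann-Whitney / variance / correlation / VIF / random-forest wrapper
    cascade, rebalances classes with SMOTE, and fits a from-scratch binary
    gradient-boosted decision tree with Bernoulli loss. Evaluation uses
    repeated stratified 70/30 splits with DeLong confidence intervals. A
    synthetic phantom-cohort generator makes the whole workflow runnable and
    testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    ranger,
    nnet,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
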