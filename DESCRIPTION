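Package: fdopaqc
Title: Automated Quality Control for FDOPA Brain PET SUVr Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quality control (QC) for [18F]-FDOPA brain PET
    standardised uptake value ratio (SUVr) maps. Provides a synthetic
    striatal phantom generator on the MNI 91x109x91 2 mm grid, simulators
    for the two dominant QC failure modes (rigid misalignment from the
    template and low signal-to-noise ratio from multiplicative Gaussian
    noise), rule-based QC criteria (motion threshold, physiological SUVr
    ranges, brain SNR statistic), 2D slice and 1D profile reductions, and
    a dimension-generic (1D/2D/3D) DenseNet classifier with batch
    normalisation, dropout and L2 regularisation, trained by SGD with
    Nesterov momentum or Adam under stratified 5-fold cross-validation.
    The convolutional kernels are implemented in C++ over BLAS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
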