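Package: mvskel
Title: Multiview Hierarchical Classification of Skeletal Abnormalities in
    Mouse Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and localizing skeletal abnormalities in
    whole-body mouse X-ray screens of the kind produced by large
    phenotyping consortia.  Builds a compact three-channel multiview
    representation per specimen (mean dorsoventral view, mean lateral
    view, and a weighted blend of their Canny edge maps), derives
    three-level hierarchical multi-label annotations (normal/abnormal;
    anatomical subclass; specific abnormality) from expert codes, and
    fits hierarchical classifiers chained level by level on top of either
    a small convolutional backbone or a convolutional autoencoder.
    Includes a phantom-skeleton radiograph simulator with view-dependent
    abnormality visibility, a multi-seed stratified-split AUC evaluation
    protocol comparing single-view and multiview inputs, and class
    activation maps for decision interpretation.  The neural-network
    training engine (convolution, pooling, dense layers, Adam, early
    stopping) is implemented in the package with compiled kernels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
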