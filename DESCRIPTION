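Package: stripseg
Title: High-Resolution Strip-Attention Network for Retinal Vessel Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based segmentation of retinal blood vessels in fundus
    photographs with a three-stream high-resolution convolutional network whose
    multi-resolution fusions are gated by a strip attention module (horizontal
    and vertical axis attention with learnable residual weights). Provides the
    full pipeline: CLAHE-based fundus preprocessing, field-of-view mask
    estimation, random 48x48 patch extraction, joint Dice + cross-entropy
    training with Adam, plateau learning-rate halving and early stopping,
    overlap-tiled whole-image reconstruction, and field-of-view restricted
    evaluation (accuracy, sensitivity, specificity, F1, AUC). Includes a
    synthetic vessel-phantom generator so the whole pipeline is testable
    without external data, and a small tape-based backpropagation engine for
    the network itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
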