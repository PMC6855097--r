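Package: thyronet
Title: Cascaded DenseU-Net Segmentation and Two-Stream CNN Fusion for
    Thyroid Nodule Detection in CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects benign and malignant thyroid nodules in 2D
    contrast-enhanced CT slices by a two-stage cascade: a DenseU-Net
    (U-Net skeleton with dense-block encoder and residual-block skip
    connections) segments the thyroid region of interest, and a fused
    two-stream convolutional classifier (a deep stream over the raw
    image and a shallower stream over the mask-restricted image,
    concatenated into a single softmax head) labels the nodule. Includes
    a self-contained neural-network engine (dense blocks, batch
    normalisation, max pooling, Adam/SGD, Dice and cross-entropy
    losses), a synthetic pseudo-CT phantom generator with ground-truth
    masks for fully reproducible experiments, window-level intensity
    normalisation, patient-grouped cross-validation, staged
    freeze/unfreeze fine-tuning, and a confusion-matrix/ROC metrics
    suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
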