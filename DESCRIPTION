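Package: bcmseg
Title: Batch-Controlled Minibatch Training for Lung-Opacity Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training and evaluation stack for class-imbalanced lung-opacity
    classification on frontal chest radiographs via semantic segmentation.
    Implements the batch control method (BCM): minibatches with a fixed
    positive:negative composition (schemes P100..P17 at batch size 6) versus
    unconstrained random batches (RAND), a compact UNet encoder-decoder
    trained with Adam and per-pixel cross-entropy, mask-to-bounding-box
    extraction, overlap-based case adjudication (TP/FP/TN/FN), multi-trial
    aggregation including the coefficient of variation of the F1-score, and
    the analogous ROC/AUC traced by the family of batch-composition operating
    points. A synthetic chest-phantom generator with ground-truth opacity
    masks makes the full pipeline testable without the radiograph download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
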