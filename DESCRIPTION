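Package: pathomil
Title: Interpretable Multiple-Instance Learning for Ordinal Grading of
    Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised multiple-instance learning (MIL) for ordinal
    grading of colorectal whole-slide images into non-neoplastic, low-grade
    and high-grade dysplasia. Implements tissue segmentation by Otsu
    thresholding on the HSV saturation channel, non-overlapping 512x512
    tile extraction at a 100% tissue threshold, a differentiable quadratic
    weighted kappa (QWK) loss for ordinal tile classification, expected-value
    tile ranking with top-L instance selection for weakly supervised
    training, slide-level aggregation of the features of the worst tiles
    with eight classifiers and soft-voting ensembles, and interpretable
    tile-prediction maps on the downsampled slide canvas. A synthetic
    slide generator provides seeded, desk-scale fixtures with ground-truth
    tissue and lesion masks so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    e1071,
    caret,
    ranger,
    xgboost,
    rpart,
    pROC,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
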