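Package: histofuse
Title: Ensemble Fusion and Scoring Tools for Nucleus Segmentation and
    Radiology-Pathology Case Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for glioma digital-pathology pipelines built around
    pluggable predictors: greedy mask-level non-maximum-suppression (MASK-NMS)
    fusion of scored instance-segmentation candidates from multiple models or
    cross-validation folds; challenge-style scoring of nucleus instance
    segmentations (standard Dice, a split/merge-aware object Dice, and average
    precision over an IOU-threshold grid); whole-slide-tissue patch machinery
    (HSV and Otsu tissue detection, grid and uniform-random patch extraction,
    Reinhard and histogram-equalization colour normalization, isolation-forest
    patch filtering, rotation-based class balancing, patch voting); and three
    radiology-pathology decision-fusion strategies for case classification
    (confidence voting, dropout-sampled feature concatenation with a linear
    SVM, and weighted-average fusion) together with a PCA plus cross-validated
    logistic-regression radiomics head. Deterministic synthetic generators
    stand in for the original challenge images and deep networks so every
    stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
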