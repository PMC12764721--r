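Package: thermoseg
Title: Segmentation and Classification of Plantar Thermograms for Diabetic
    Foot Ulcer Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for plantar thermogram analysis: a
    U-shaped segmenter built from modified Swin-transformer blocks
    (shifted-window self-attention with a hybrid channel-spatial attention
    variant and multi-level feature fusion), a capsule-network feature
    extractor with iterative dynamic routing, and an extreme learning
    machine classifier solved in closed form. Includes a synthetic
    thermogram generator with ground-truth lesion masks, pixel screening
    and CLAHE preprocessing, affine augmentation, a five-fold subject-level
    cross-validation harness with Dice/IoU and confusion-matrix metrics,
    and a small reverse-mode automatic-differentiation engine that the
    trainable components run on.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    yaml,
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    MASS,
    withr
Config/testthat/edition: 3
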