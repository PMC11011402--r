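Package: greendet
Title: Green-Fruit Detection in Small Orchard Image Sets with an
    Attention-Augmented Single-Stage Detector
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting green fruit against green foliage in small
    RGB image datasets. Implements an anchor-based single-stage detector
    whose backbone downsampling blocks integrate channel and spatial
    attention through concatenation (the Conv-AT block), a three-way
    augmentation pipeline (mask-guided Copy-Paste, Mosaic, Mixup), a
    synthetic green-on-green orchard scene generator with per-instance
    ground-truth masks, YOLO-format label input/output, and an evaluation
    suite reporting precision, recall, F1, average precision and mAP at an
    IoU threshold of 0.5. Networks are trained with a built-in
    reverse-mode automatic differentiation engine backed by compiled
    convolution and pooling kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
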