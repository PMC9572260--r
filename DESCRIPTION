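Package: wheatSeg
Title: Semantic Segmentation and Online Impurity-Rate Quantification for
    Mechanically Harvested Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end machine-vision pipeline for estimating the
    impurity rate (mass percentage of straw, awn and husk) of mechanically
    harvested wheat from RGB images of grain piles. Provides a DeepLabV3+
    encoder-decoder semantic segmentation model (atrous spatial pyramid
    pooling, selectable width-scalable backbones) running on a lightweight
    pure-R CPU engine, LabelMe-style polygon annotation handling with
    even-odd rasterisation, the bilinear-resize/augmentation/split dataset
    protocol, per-class pixel metrics (precision, recall, F1, IOU, MIOU),
    a pixel-count-to-mass quantification model with calibrated grain-to-
    impurity mass ratio, bench/field trial error statistics, and a synthetic
    grain-pile scene generator with exact ground truth for testing every
    stage without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
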