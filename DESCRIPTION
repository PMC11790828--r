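Package: isdiou
Title: Bounding-Box Regression Losses, Pyramid Pooling and Attention
    Blocks, and Detection Metrics for Cardiac MRI Lesion Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Reference implementation of the iSD-IoU bounding-box
    regression loss (inner-box IoU with exponential distance and shape
    penalties) together with the forward semantics of a multi-channel
    spatial-pyramid-pooling block (SPPMC), a joint squeeze-excitation /
    coordinate attention block (UECA), a receptive-field calculator,
    COCO-style detection metrics (precision, recall, F1, AP, mAP), and a
    desk-scale bounding-box regression simulator with synthetic cardiac
    MRI phantom fixtures.  All components operate on plain data frames
    and numeric arrays; no deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
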