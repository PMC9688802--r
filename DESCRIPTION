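Package: glucopad
Title: Chemometric Quantification of Glucose from Paper-Pad Colorimetric Spot Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end chemometric pipeline for quantifying glucose from
    photographs of chromogenic spots on paper-based analytical devices
    (uPADs).  Provides a seeded synthetic spot-image generator with full
    ground truth, region-of-interest segmentation, multi-color-space
    feature extraction (per-channel moment statistics plus gray-level
    co-occurrence texture metrics, 51 features in total), logarithmic
    response calibration with a signal-domain limit of detection, support
    vector regression of concentration on the feature vectors, and
    shelf-life intensity-decay summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    png,
    jsonlite,
    yaml,
    withr,
    stats,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
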