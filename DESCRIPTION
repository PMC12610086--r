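Package: mitovasc
Title: Spatial Morphometry of Mitoses and Vasculature in Whole-Slide Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream spatial analysis of whole-slide histology annotations for
    lung adenocarcinoma: per-vessel morphometry (shoelace area, rotating-calipers
    Feret diameters, caliber classification at a 300 square-micron threshold,
    tumor-center versus periphery compartment assignment), spatial statistics of
    mitotic figures (grid-binned Shannon entropy in dits, hot-spot detection,
    perivascular clustering), segmented and gradient heatmap rendering, detection
    evaluation metrics (sensitivity, specificity, F1, IoU, Dice, ROC AUC,
    hard-negative confusion aggregation), and a rule-plus-nearest-centroid
    classifier of five trophic patterns. A seeded synthetic-slide generator
    emulates per-subtype cohorts so the whole pipeline is testable without
    whole-slide image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    png,
    mgcv,
    pROC,
    stats,
    grDevices,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
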