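Package: ClonoTrack
Title: Colony-Forming Assay Quantification on Brightfield Z-Stacks via
    Multi-Object Tracking
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection, Z-axis multi-object tracking, counting and
    dose-response analysis for clonogenic colony-forming assays imaged as
    brightfield Z-stacks. Per-slice objects (single cells, clusters,
    colonies and out-of-focus candidates) are localized with a classical
    blob detector or imported from external detection files, merged along
    the Z axis into unique 2.5D objects by two-stage IoU association, and
    classified hierarchically over each trajectory. Includes identity-based
    tracking metrics (IDF1/IDP/IDR, track coverage, ID switches), detector
    evaluation (AP50, confusion matrix), a seeded hyperparameter search,
    plating-efficiency and survival-fraction read-outs, four-parameter
    logistic IC50 fitting with a linear fallback, and a fully synthetic
    Z-stack and assay-data generator so the entire pipeline is testable
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    EBImage,
    minpack.lm,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
biocViews: CellBasedAssays, Visualization, Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
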