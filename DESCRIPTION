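Package: ctcsegaudit
Title: Star-Convex Segmentation and Audit Pipeline for Circulating
    Tumor Cell Enumeration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ground-truthed simulation of CellSearch-style immunofluorescence
    cartridges (DAPI, cytokeratin-PE, CD45-APC channels), a training-free
    star-convex instance segmentation stage with greedy polygon non-maximum
    suppression, a rule-based candidate circulating-tumor-cell (CTC) gate,
    and the comparison and audit statistics used to evaluate segmentation
    quality for CTC enumeration: recovery and split/merge/partial/missed
    classification, segmentation-size audits, event-density empirical CDFs
    with stochastic-dominance flags, spike-in correlation, image-edge
    heatmaps, and CTC-gain regression with risk-group conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
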