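Package: doee
Title: Detection and Outline Error Estimates for Segmentation Rater Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes the disagreement between two raters' lesion
    segmentations into Detection Error (regions marked by only one rater)
    and Outline Error (boundary disagreement on jointly detected regions).
    Connected regions of the union mask are classified per slice as
    single-rater or shared, yielding DE, OE, the Outline Error Rate
    (OER = OE/MTA), mean total area (MTA), the Similarity (Dice) Index and
    its exact DE/OE decomposition, Jaccard and Cohen's kappa relations.
    Models the dependence of the Similarity Index on lesion burden and
    compares mean, linear, quadratic and detection/outline-based fits by
    finite-sample-corrected AICc. Includes Cumulative Detection Error and
    Outline Error Distribution diagnostics, readers for NIfTI and PNG mask
    volumes and a polygon-contour JSON dialect with upsampled
    rasterization, and a calibrated synthetic generator of paired rater
    segmentations for validation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph,
    RNifti,
    png
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
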