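Package: boutonca
Title: Presynaptic Bouton Calcium Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for two-channel (green calcium indicator /
    red reference) fluorescence time-lapse imaging of presynaptic boutons in
    brain slices. Covers deinterleaving of alternating-excitation stacks,
    double-exponential photobleach fitting on no-stimulus controls and
    divisive correction, F/F0 normalization, Laplacian-threshold punctum
    segmentation with 3x3 maximum-intensity ROIs and neighboring background
    ROIs, hierarchical-clustering responder classification, transient
    kinetics (peak, time to peak, initial slope, single/double exponential
    decay, area under the curve), stimulus-response curve fits (sigmoid,
    linear sub-range), Gaussian flat-field correction with known-layout tile
    stitching, ratiometric green/red quantification, line-profile Pearson
    colocalization, and a synthetic-data generator with ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    igraph,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
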