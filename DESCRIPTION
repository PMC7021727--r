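Package: beadflow
Title: Microbead Tracking and Ciliary Beat Frequency Analysis for
    Ependymal Flow Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and tracks fluorescent microbeads in time-lapse
    fluorescence microscopy of the lateral-ventricle wall to quantify
    cilia-driven ependymal flow. Beads are localized with a bank of
    multi-scale Laplacian-of-Gaussian filters, refined by non-minima
    suppression, Gaussian-heatmap merging and removal of stationary
    detections via complete-linkage clustering under the Chebyshev
    metric, then linked through time with a constant-velocity Kalman
    filter. Per-track speeds and flow direction are summarized and
    compared between groups with the Mann-Whitney rank-sum test. An
    auxiliary module estimates ciliary beat frequency from confocal
    linescan traces, and a synthetic-scene generator produces bead
    videos and linescans with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
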