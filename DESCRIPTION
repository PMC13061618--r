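Package: veiscope
Title: In Silico Characterization of Visual Receptive-Field Invariance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gradient-based synthesis of most exciting inputs (MEIs) and varied
    exciting inputs (VEIs) against differentiable model neurons, calibrated
    diversity indices anchored by analytic simple and complex cells, bipartite
    (fixed plus shift-invariant) receptive-field parameterizations with control
    models and a bipartite invariance index, segmentation-boundary alignment
    scoring, and functional-connectomics statistics on pairwise connectivity
    tables. Includes synthetic-fixture generators (naturalistic 1/f imagery,
    blob segmentation masks, planted ground-truth neurons, synthetic
    connectomes) so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    EBImage,
    png,
    jsonlite,
    mgcv,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
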