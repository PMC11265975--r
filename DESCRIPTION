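Package: scalpfit
Title: Scalp Surface Reconstruction and Head Registration from Sparse
    Surface Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a complete scalp surface and registers a subject's
    head from sparse, unordered surface samples, such as those collected with
    a tracked neuronavigation pointer. A linear statistical shape model (3D
    morphable model) of the head acts as a prior; a non-uniform similarity
    transform and the model's shape weights are optimized jointly against a
    one-sided Chamfer loss with optional normal consistency and Frobenius
    regularization. Includes mesh and point-cloud utilities, simulators for
    contiguous scalp sampling trajectories (side-to-top, side-to-side, half
    side-to-top, random walk), a landmark-based registration benchmark with
    3 or 7 fiducials, accuracy metrics and cross-validation protocols, and
    regression models relating reconstruction error to trajectory length.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
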