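Package: ctnet
Title: Complex-Network Motion Artifact Detection for Head CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects motion artifacts in head computed-tomography (CT) slices
    by mapping each slice to a pixel-level complex network (edges gated by
    spatial radius and grey-level difference) and the dataset to a slice-level
    network (edges between slices sharing anatomical region and quality label),
    extracting topological properties (average degree, average clustering
    coefficient, average path length, edge counts) alongside physical intensity
    statistics, and classifying slices with an RBF-kernel support vector
    machine or a 1000-tree random forest. Includes an ellipse-based head
    phantom simulator with a configurable motion-artifact model
    (ghosting, streaks, shading) for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    e1071,
    randomForest,
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
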