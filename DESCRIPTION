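Package: coolspot
Title: Center-Finding Trial Analysis for Heated-Arena Insect Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for the heated-arena ("dry water maze")
    center-finding paradigm: construction of the four canonical arena
    geometries with a central cool refuge spot, calibration and ingestion of
    video-tracker tables, per-trial behavioural metrics (latency to the cool
    spot, on-spot bouts, path length, rest and wall-following time, occupancy
    heatmaps), isolation of approach paths preceding successful stays,
    wall-distance featurization, dynamic-time-warping distances with
    k-medoid (PAM) strategy clustering and validity indices, learning-slope
    estimation on transformed responses, and the elementary tests used in
    this paradigm (Mann-Whitney U with Bonferroni adjustment, 2x2
    chi-square). Includes a synthetic trajectory generator with known
    strategy labels and learning dynamics so every stage is testable without
    recorded data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    mclust,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
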