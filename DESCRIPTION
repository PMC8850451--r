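Package: loomnet
Title: Brain-Wide Network Analysis of Visual Habituation in Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying visual habituation to looming stimuli in
    larval zebrafish, from free-swimming escape behavior to brain-wide calcium
    imaging networks. Includes a synthetic-cohort generator (stimulus trains,
    archetype-based ROI fluorescence traces, behavior tracks), behavioral
    habituation statistics (escape detection, response probabilities,
    constrained one-phase decay fits, per-loom binomial tests), functional
    clustering of ROI responses (cityblock k-means, regressor-based
    classification, proportion and behavior-correlation tables),
    spatial-functional node graphs with per-loom correlation matrices
    (thresholding, density, participation coefficients, matrix matching),
    amplitude-adjusted Fourier transform surrogate nulls, multilayer
    modularity optimization with generalized Louvain and consensus partitions
    (flexibility, cohesion, promiscuity), and persistent homology of
    correlation-filtered clique complexes (dimensions 0-2, barcodes and
    lifetime sums).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
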