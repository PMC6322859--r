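Package: megrsa
Title: Representational Similarity Analysis of Paired-Design MEG Epochs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spatial and temporal representational similarity analysis (RSA)
    for epoched MEG data with a paired stimulus design: spatial-pattern
    similarity time series, cross-temporal (temporal generalization)
    similarity matrices, sensor- and source-level temporal similarity maps,
    cluster-based permutation tests with cluster-mass statistics, and LCMV
    beamformer source reconstruction with SVD orientation selection.
    Includes a synthetic epoch generator that embeds item-specific
    "prediction" signatures shared within sentence pairs, plus simulation
    studies for type-I error, familywise error and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
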