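Package: crossOmics
Title: Pair-Wise Similarity Visualisation for Two-Block Omics Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates two omics data matrices measured on the same samples
    with partial least squares (regression and canonical modes, including
    sparse variable selection) and canonical correlation analysis (classical
    and ridge-regularized), estimates the pair-wise variable similarity
    matrix from the projected variables, and renders its three graphical
    consumers: Correlation Circle plots, bipartite Relevance Networks and
    Clustered Image Maps. A block-structured multivariate-normal simulator
    reproduces a validation design with known cross-correlated variable
    groups so the whole stack can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    jsonlite,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
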