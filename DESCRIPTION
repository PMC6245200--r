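Package: hyperembed
Title: Hyperbolic Embedding of Complex Networks via Laplacian Drafts and
    Likelihood Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to map undirected, unweighted, single-component networks
    into the two-dimensional hyperbolic plane. Implements the
    popularity-similarity growth model as a network simulator with
    ground-truth coordinates, a fast spectral embedding based on the graph
    Laplacian (LaBNE), a maximum-likelihood embedding that replays
    hyperbolic network growth (HyperMap, fast hybrid version), and the
    hybrid scheme that refines the spectral draft inside an angular window
    (LaBNE+HM). Includes an evaluation suite: greedy routing and hop
    stretch, distance-dependent connection-probability curves, network
    temperature estimation from clustering coefficients, and
    maximum-likelihood power-law exponent fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
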