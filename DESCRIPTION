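Package: rsgnn
Title: Ranking Node Spreading Influence with a Relationship-Strength Graph
    Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies influential spreaders in undirected networks with a
    trainable message-passing model whose propagation operator weights
    neighbours by neighbourhood overlap (common-neighbour counts). Node input
    features fuse the degree and the mean neighbour degree with weights set
    objectively by the entropy weight method. Ground-truth influence labels
    come from discrete-time susceptible-infected-recovered (SIR) Monte Carlo
    simulations at the epidemic threshold, and rankings are evaluated against
    those labels with the Kendall rank correlation, alongside classical
    centrality baselines (degree, K-shell, betweenness, PageRank). Includes
    Barabasi-Albert and LFR-style benchmark generators for training data and
    a command-line pipeline for generation, labelling, training and
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
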