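Package: strengthnulls
Title: Strength Sequence-Preserving Null Models for Weighted Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Randomization of weighted networks under progressively stricter
    null constraints: classic Maslov-Sneppen degree-preserving edge rewiring,
    Rubinov-Sporns rank-matched weight reassignment, and strength
    sequence-preserving randomization by simulated annealing with a Metropolis
    acceptance criterion, in undirected, directed and signed variants. Includes
    weighted graph metrics (clustering intensity, characteristic path length,
    strength assortativity, Louvain modularity), nonparametric heavy-tail hub
    detection, weighted rich-club normalization against null ensembles, and
    ensemble benchmarking statistics (Spearman, Kolmogorov-Smirnov,
    Mann-Whitney U with common-language effect sizes) with morphospace and
    subsample-convergence summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
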