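Package: consnet
Title: Consensus Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers gene relevance networks from expression matrices by
    Pearson correlation thresholding with automated threshold selection,
    builds consensus networks across independent studies, and assesses their
    significance with degree-preserving Maslov-Sneppen randomization.
    Provides topological characterization (betweenness, clustering,
    assortativity, diameter, modularity) against rewired null models,
    discrete power-law degree-distribution fitting with bootstrap
    goodness-of-fit, graph partitioning by Louvain and Markov clustering,
    functional-coherence scoring of partitions against size-matched random
    partitions, and hypergeometric gene-set enrichment with
    Benjamini-Hochberg adjustment. A synthetic multi-study expression
    generator with planted co-expression modules supports end-to-end
    validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
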