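Package: mitochapnet
Title: Chaperone-Client Co-Expression Networks with Map-Equation Community Detection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds weighted bipartite chaperone-client interaction networks from
    multi-cohort gene expression data. Per-cohort Spearman rank correlations between
    a chaperone panel and a client panel are screened with Bonferroni-corrected
    significance and positivity filters, aggregated across cohorts by cell-wise
    medians, and assembled into a weighted bipartite network. Community structure
    is found by minimising the two-level map equation with a seeded greedy search
    (with an exhaustive small-graph oracle), and its significance is assessed with
    a two-stage permutation null: curveball margin-preserving randomisation of the
    binary incidence matrix followed by random redistribution of the observed edge
    weights. Includes a synthetic multi-cohort generator with planted modular
    structure, hierarchical clustering of interaction profiles, pairwise client-set
    partitions, and an end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ape,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
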