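Package: mirhub
Title: Hub miRNA Ranking and Synthetic Circuit Validation for NSCLC
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying hub microRNAs in miRNA-target bipartite
    regulatory networks and for validating an inducible synthetic gene
    circuit that re-expresses a tumour-suppressive miRNA. Provides global
    bipartite network statistics, eleven node-centrality scoring methods
    with frequency-of-occurrence hub aggregation, hypergeometric term
    over-representation with Benjamini-Hochberg control, enrichment-map
    graphs, weighted running-sum gene-set enrichment analysis over
    GCT/CLS/GMT inputs, seed-match target-site scanning with
    Knuth-Morris-Pratt search and simplified context features, a
    toggle-switch/repressilator ODE model with ON/OFF case analysis,
    best-fit Boolean network inference with exhaustive synchronous
    attractor enumeration, and Gibbs-variable-selection dynamic Bayesian
    network inference with multi-chain convergence checking. Seeded
    synthetic-data generators produce every input with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    deSolve,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
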