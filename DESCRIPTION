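Package: funalign
Title: Supervised Cross-Species Network Alignment and Functional Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data-driven alignment of two protein-protein interaction (PPI)
    networks joined by sequence-similarity anchor links. Extracts per-node
    topological features from the integrated two-species network (graphlet
    orbit counts; unconstrained and metapath-constrained random-walk
    embeddings), trains a logistic-regression classifier on functionally
    related versus unrelated cross-species protein pairs derived from Gene
    Ontology annotations, builds alignments from held-out pairs predicted
    related, transfers GO annotations across species by hypergeometric
    enrichment, and forms a high-precision consensus by intersecting the
    prediction sets of independent feature pipelines. Includes a synthetic
    two-species world generator with planted functional modules for fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    pROC,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
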