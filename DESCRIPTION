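Package: codac
Title: Bipartite Graph Enrichment by Common-Neighbour Cosine Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Enriches a sparse bipartite association graph (X-Y) inside a
    tripartite setting (X-Z, Y-Z) by scoring candidate X-Y edges on
    common-neighbour cosine similarity, calibrating a decision threshold
    against a degree-preserving shuffled-graph gold standard, combining
    multiple evidence datasets via ROC-AUC-optimized weights, and attaching
    hypergeometric significance with Bonferroni correction and
    Gold/Silver/Bronze quality classes. Includes rooted-DAG ontology
    propagation and most-specific-term filtering for ontology-typed X
    vocabularies (as used for GO term to protein domain discovery), a
    redundancy-clustering step for the common-neighbour vocabulary, and a
    synthetic tripartite data generator with planted associations for
    testing the full method at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    optparse
Config/testthat/edition: 3
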