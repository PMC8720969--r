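Package: herbnet
Title: Network Pharmacology Screening for Multi-Component Herbal Formulae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end network-pharmacology inference chain for
    multi-component herbal medicines: ADME-based active-component filtering
    (oral bioavailability and drug-likeness thresholds), two-group
    differential expression calling on log2 expression matrices,
    compound-target/DEG intersection and bipartite network summaries,
    hypergeometric over-representation analysis with Benjamini-Hochberg
    control, preranked gene-set enrichment analysis, two-stage topological
    screening of protein-protein interaction networks (double-median-degree
    subnetwork extraction followed by degree and betweenness core
    filtering), hub-target selection by double intersection, Pearson
    coexpression flagging against phenotype-indicator genes, and ranking of
    externally produced molecular-docking result tables. Ships synthetic
    generators with ground-truth ledgers for every input so the whole chain
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
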