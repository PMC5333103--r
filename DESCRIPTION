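Package: netprio
Title: Network-Distance-Based Prioritization of Candidate Disease Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease genes on a weighted functional
    association network by guilt-by-association. Edge confidence scores are
    converted to distances (1000/S), all-pairs shortest-path distances are
    computed with Dijkstra's algorithm, and a centrality-adjusted network
    distance is derived by normalizing each raw distance by the two endpoints'
    mean raw distances to the whole network, damping hub bias. A
    disease-specific gene weight (mean adjusted distance to all genes minus
    mean adjusted distance to the known disease genes) ranks every gene, and a
    precision-based score conversion makes rankings comparable across
    diseases. Includes the full evaluation battery (leave-one-out cross
    validation, precision-recall curves and AUC, F-max, true-positive rate at
    top-k, rank ratios, cross-disease pooling), post-GWAS SNP prioritization,
    a seeded synthetic-network generator with planted disease modules, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
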