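Package: neighbournet
Title: Classification and Topology of Cancer-Related Proteins and Their
    First Neighbours in Tissue-Specific Interactomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds tissue-specific protein interaction networks from
    binary (on/off) discretized expression data, partitions their nodes
    into cancer-related, first-neighbour and unaffected classes, and
    identifies influencer proteins with directed interactions into first
    neighbours.  Provides node-level topology statistics (degree,
    betweenness centrality, local clustering coefficient) with
    nonparametric class comparisons, a label-permutation giant-component
    test, a seed-randomization robustness analysis, a gene-ontology
    added-biological-process test, and drug/compound repurposing filters
    on bioactivity tables.  A synthetic-data module generates
    interactomes, expression profiles, mutation lists, GO annotations and
    bioactivity tables with ground truth so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
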