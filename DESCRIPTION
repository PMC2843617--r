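Package: ListNet
Title: Gene-List Integration: Set Algebra, Fisher-Exact Enrichment and
    Network Expansion of Gene Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates experimentally derived gene and protein lists.
    Provides gene-symbol normalization with optional synonym resolution, a
    GMT (Gene Matrix Transposed) library data model with readers and
    writers, set algebra on lists, one-sided Fisher-exact (hypergeometric
    upper-tail) overlap statistics against gene-set libraries with
    Bonferroni and Benjamini-Hochberg corrections and ranked enrichment
    tables, expansion of seed lists into connecting subnetworks over
    protein-protein interaction, co-expression or co-annotation background
    networks via all-shortest-paths with specificity-based filtering and
    ranking of intermediate nodes, construction of a network of lists whose
    edges mark statistically significant overlap, SIF and GraphML export
    for Cytoscape, seeded synthetic fixtures (planted-enrichment libraries,
    preferential-attachment graphs), and a scriptable command-line entry
    point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'genesets.R'
    'enrichment.R'
    'networks.R'
    'expansion.R'
    'listsNetwork.R'
    'synthetic.R'
    'cli.R'
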