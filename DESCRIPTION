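Package: pathmodtree
Title: Phylogenies from Signalling-Pathway Modules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds phylogenetic trees from species-specific signal
    transduction pathways. Pathway graphs are read from KGML (KEGG Markup
    Language) files, decomposed into modules with a degree-seeded
    modularization algorithm controlled by a user factor c, and compared
    across species by Jaccard overlap of module membership; the resulting
    distance matrix feeds neighbor-joining tree construction. An
    alternative whole-topology distance based on graphlet degree
    signatures and seed-and-extend global network alignment (edge
    correctness) is provided for comparison, together with an optimal
    branch-matching score between trees on the same leaf set and a
    synthetic generator that evolves pathway families along a known
    phylogeny by node gain and loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
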