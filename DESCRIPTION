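Package: hnauty
Title: Canonical Labeling and Isomorphism Testing for Hierarchical
    Molecule Graphs with Typed Edges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Data structures and algorithms for graphs with multiple edge
    types, as used in rule-based modeling of multi-component biomolecules:
    directed "hierarchy" edges express component/subcomponent containment
    (protein, domain, linear motif, residue) and undirected "bond" edges
    express molecular bonds.  Provides validated typed-graph and
    ordered-partition types, the power-of-two multi-edge-type adjacency
    encoding, generalized equitable partition refinement, and HNauty, an
    individualization-and-refinement canonical labeling algorithm in the
    style of Nauty, extended to several edge types, with automorphism-group
    and indicator-function pruning.  Includes brute-force reference oracles
    for small graphs, a seeded random two-edge-type graph generator with a
    permutation self-test, readers and writers for a line-oriented graph
    format, and worked fixtures (the Lck kinase and the T-cell receptor
    complex).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
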