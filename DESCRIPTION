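Package: CircuitKeys
Title: Electrical-Circuit Identification of Overlapping and Bridging Nodes
    in Community-Structured Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maps a network onto an electrical circuit (resistors for
    undirected edges, ideal diodes plus a universal ground for directed
    ones), solves Kirchhoff's equations for every source-target
    configuration, and derives a current-flow centrality C together with a
    flow-imbalance index D. Nodes with high C are the key connectors
    between communities; D separates overlapping nodes (balanced incident
    flows, membership in several communities) from bridging nodes (one
    dominant bridging edge). The method needs no community partition.
    Includes readers and writers for edge-list, GML and GraphML formats,
    bundled example networks, seeded generators for planted-community and
    LFR-style benchmarks with ground truth, and a command-line driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    optparse
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'network.R'
    'io.R'
    'solve.R'
    'centrality.R'
    'imbalance.R'
    'keynodes.R'
    'synthetic.R'
    'cli.R'
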