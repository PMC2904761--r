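Package: pathgrid
Title: Constraint-Aware Grid Layout of Biological Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Draws biological pathway diagrams by assigning nodes to points of
    an integer grid under sub-cellular localization constraints (rectangles,
    ovals, and torus-shaped membrane regions). A greedy combinatorial
    optimizer minimizes a cost that combines spring-embedder attraction and
    repulsion forces with exact counts of edge-edge and node-edge crossings,
    using cached delta costs and an incremental repulsion field for
    efficiency. An optional mode dynamically resizes and repositions
    compartments during the search, and a classical continuous-space spring
    embedder is included as a baseline. Utilities cover synthetic annotated
    pathway generation, GraphML/JSON input and output, SVG rendering, and a
    replicated experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
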