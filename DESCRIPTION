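Package: epgraph
Title: Elastic Principal Graphs for Approximating Complex Data Topologies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits elastic principal graphs - curves, circles, trees and
    user-defined topologies - to multidimensional point clouds. The graph
    embedding is learned by minimizing a trimmed mean squared approximation
    error penalized by an elastic energy (edge stretching plus star
    harmonicity), and the graph topology is learned by a gradient
    descent-like search over graph-grammar rewriting operations (bisect an
    edge, add a node to a node, remove a leaf, shrink an internal edge).
    Includes robust trimmed fitting for noisy data, bootstrap principal
    graph ensembles with consensus-graph construction, branching-point
    confidence intervals, pseudotime and branch decomposition utilities,
    and seeded generators of synthetic branching, circular and
    intersecting-curve datasets with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
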