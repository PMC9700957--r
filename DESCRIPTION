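Package: cellgraph
Title: Cell-Graphs and GNN Edge Classification for Basement-Membrane Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs node-labelled cell-graphs from nucleus centroid
    annotations of mucosal tissue tiles via d-distance-limited Delaunay
    triangulation, labels edges as crossing or not crossing the basement
    membrane from spline annotations, trains a GraphSage-style graph neural
    network edge classifier with max-pool aggregation, and evaluates
    predictions with per-class precision/recall/F1, accuracy and mean average
    precision. Includes a synthetic mucosa point-pattern generator with a
    detector-noise simulator so the full pipeline is testable without
    clinical image data, plus command-line entry points and figure-style
    rendering of edge predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
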