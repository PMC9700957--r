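# Cell-graph construction: d-distance-limited Delaunay triangulation.

#' Graph construction configuration
#'
#' @param d Maximum edge length in pixels; Delaunay edges longer than `d`
#'   are removed (closed comparison, length <= d is kept). The default of
#'   100 px corresponds to 50 micrometres at the 2 px/um export scale.
#' @param degeneracy_tolerance Perturbation scale (px) reserved for breaking
#'   cocircular degeneracies in controlled experiments; never applied
#'   silently during construction.
#' @return A list of class `graph_build_config`.
#' @export
graph_build_config <- function(d = 100, degeneracy_tolerance = 0) {
  if (!is_number(d) || d <= 0) stopf("`d` must be a positive number")
  structure(list(d = d, degeneracy_tolerance = degeneracy_tolerance),
            class = "graph_build_config")
}

#' Delaunay triangulation edge set
#'
#' Computes the edges of a Delaunay triangulation of a planar point set: a
#' triangle belongs to the triangulation exactly when its circumcircle
#' contains no other input point. Degenerate cases follow documented rules:
#' one point gives no edges, two points give the single edge, and three or
#' more collinear points give the path connecting consecutive points along
#' the line. For four or more cocircular points (triangulation not unique)
#' any valid Delaunay triangulation is returned.
#'
#' @param points Numeric matrix with two columns (x, y). Duplicate
#'   coordinates are rejected.
#' @return Integer matrix with two columns: row indices into `points` of
#'   each undirected edge, with `[, 1] < [, 2]`, rows in lexicographic order.
#' @export
#' @examples
#' delaunay_edges(cbind(c(0, 1, 0), c(0, 0, 1)))  # one triangle
delaunay_edges <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) != 2L || !is.numeric(points)) {
    stopf("`points` must be a numeric matrix with two columns")
  }
  if (anyNA(points)) stopf("`points` contains missing coordinates")
  n <- nrow(points)
  if (n < 1L) stopf("at least one point is required")
  dup <- duplicated(points)
  if (any(dup)) {
    j <- which(dup)[1]
    i <- which(points[, 1] == points[j, 1] & points[, 2] == points[j, 2])[1]
    stopf("duplicate points at rows %d and %d: (%g, %g)", i, j,
          points[j, 1], points[j, 2])
  }
  if (n == 1L) {
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("from", "to"))))
  }
  if (n == 2L) {
    return(matrix(c(1L, 2L), 1, 2, dimnames = list(NULL, c("from", "to"))))
  }
  if (all_collinear(points)) {
    # Documented fallback: the path through consecutive points on the line.
    o <- order(points[, 1], points[, 2])
    e <- cbind(o[-n], o[-1])
    e <- t(apply(e, 1, sort))
  } else {
    e <- .cpp_delaunay(points)
  }
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  dimnames(e) <- list(NULL, c("from", "to"))
  e
}

all_collinear <- function(points) {
  n <- nrow(points)
  if (n < 3L) return(TRUE)
  a <- points[1, ]
  # first point distinct from a in direction
  b <- points[2, ]
  cross <- (points[, 1] - a[1]) * (b[2] - a[2]) -
           (points[, 2] - a[2]) * (b[1] - a[1])
  all(cross == 0)
}

#' Remove triangulation edges longer than d
#'
#' Retains exactly the edges whose Euclidean endpoint distance is at most
#' `d` (closed comparison).
#'
#' @param edges Integer matrix of node index pairs (as from
#'   [delaunay_edges()]).
#' @param points Numeric matrix of node coordinates.
#' @param d Maximum edge length in pixels (> 0; `Inf` keeps all edges).
#' @return The filtered edge matrix.
#' @export
prune_long_edges <- function(edges, points, d) {
  if (!is_number(d) && !identical(d, Inf)) stopf("`d` must be a number")
  if (nrow(edges) == 0L || d <= 0) return(edges[integer(), , drop = FALSE])
  len <- sqrt((points[edges[, 1], 1] - points[edges[, 2], 1])^2 +
              (points[edges[, 1], 2] - points[edges[, 2], 2])^2)
  edges[len <= d, , drop = FALSE]
}

#' Build a partially labelled cell-graph from a tile
#'
#' Nodes carry the label triple (x, y, cell class); edges are the
#' d-distance-limited Delaunay triangulation of the centroids; edge labels
#' are left unset. The construction is invariant to the order of the node
#' list: permuting the input rows yields the same graph.
#'
#' @param tile A [tile_record()] with at least one node.
#' @param config A [graph_build_config()].
#' @return A [cell_graph()] with unlabelled edges.
#' @export
build_cell_graph <- function(tile, config = graph_build_config()) {
  stopifnot(inherits(tile, "tile_record"), inherits(config, "graph_build_config"))
  if (nrow(tile$nodes) < 1L) stopf("tile has no nodes")
  pts <- cbind(tile$nodes$x, tile$nodes$y)
  edges <- if (nrow(pts) == 1L) {
    matrix(integer(), 0, 2)
  } else {
    prune_long_edges(delaunay_edges(pts), pts, config$d)
  }
  edf <- if (nrow(edges) == 0L) NULL else
    data.frame(from = tile$nodes$id[edges[, 1]],
               to = tile$nodes$id[edges[, 2]],
               stringsAsFactors = FALSE)
  cell_graph(tile$nodes, edf, tile_id = tile$tile_id,
             width = tile$width, height = tile$height)
}
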