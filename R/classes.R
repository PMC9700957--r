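# Domain types: tiles, cell nodes and basement-membrane annotations.

#' The four cell classes
#'
#' Fixed class vocabulary used throughout the package, in the canonical
#' order that also defines the one-hot feature encoding: epithelial,
#' fibroblast/endothelial, inflammatory, lymphocytic.
#'
#' @return Character vector of the four class names.
#' @export
#' @examples
#' cell_classes()
cell_classes <- function() {
  c("epithelial", "fibroblast_endothelial", "inflammatory", "lymphocytic")
}

#' Create a basement-membrane annotation
#'
#' A BM annotation is an ordered list of spline segments; each segment is an
#' ordered set of control points interpreted as a piecewise-linear polyline.
#'
#' @param splines List of numeric matrices, each with two columns (x, y in
#'   pixels, origin top-left, y increasing downward) and at least two rows.
#' @return An object of class `bm_annotation` (a list of control-point
#'   matrices).
#' @export
#' @examples
#' bm <- bm_annotation(list(cbind(c(0, 100, 200), c(50, 60, 50))))
bm_annotation <- function(splines) {
  if (!is.list(splines) || length(splines) == 0L) {
    stopf("`splines` must be a non-empty list of control-point matrices")
  }
  splines <- lapply(seq_along(splines), function(i) {
    s <- splines[[i]]
    if (is.data.frame(s)) s <- as.matrix(s)
    if (!is.matrix(s) || ncol(s) != 2L || !is.numeric(s)) {
      stopf("spline %d is not a numeric matrix with 2 columns", i)
    }
    if (nrow(s) < 2L) {
      stopf("spline %d has fewer than 2 control points", i)
    }
    if (anyNA(s)) stopf("spline %d contains missing coordinates", i)
    dimnames(s) <- list(NULL, c("x", "y"))
    s
  })
  structure(splines, class = "bm_annotation")
}

#' Create a tile record
#'
#' A tile is the unit of annotation and processing: a `width` x `height`
#' pixel region carrying cell-nucleus centroid annotations and, optionally,
#' a basement-membrane annotation. Coordinates are continuous pixels with
#' origin at the top-left corner and y increasing downward; `scale` records
#' pixels per micrometre as metadata only (the export convention of
#' 1 micrometre per 2 pixels gives `scale = 2`).
#'
#' @param tile_id Character identifier.
#' @param width,height Tile dimensions in pixels.
#' @param nodes Data frame with columns `id`, `x`, `y`, `cell_class`
#'   (or `NULL` for an empty tile).
#' @param bm Optional [bm_annotation()].
#' @param scale Pixels per micrometre (metadata only), default 2.
#' @return An object of class `tile_record`.
#' @export
#' @examples
#' tile_record("t1", 100, 100,
#'   nodes = data.frame(id = "c1", x = 10, y = 20, cell_class = "epithelial"))
tile_record <- function(tile_id, width, height, nodes = NULL, bm = NULL,
                        scale = 2) {
  if (!is.character(tile_id) || length(tile_id) != 1L || is.na(tile_id)) {
    stopf("`tile_id` must be a single string")
  }
  if (!is_number(width) || !is_number(height) || width <= 0 || height <= 0) {
    stopf("`width` and `height` must be positive numbers")
  }
  width <- as.numeric(width)
  height <- as.numeric(height)
  scale <- as.numeric(scale)
  if (is.null(nodes)) {
    nodes <- data.frame(id = character(), x = numeric(), y = numeric(),
                        cell_class = character(), stringsAsFactors = FALSE)
  }
  nodes <- validate_nodes(nodes, width, height)
  if (!is.null(bm)) {
    if (!inherits(bm, "bm_annotation")) bm <- bm_annotation(bm)
    for (i in seq_along(bm)) {
      s <- bm[[i]]
      if (any(s[, 1] < 0 | s[, 1] > width | s[, 2] < 0 | s[, 2] > height)) {
        stopf("BM spline %d has control points outside the tile bounds", i)
      }
    }
  }
  structure(
    list(tile_id = tile_id, width = width, height = height, scale = scale,
         nodes = nodes, bm = bm),
    class = "tile_record"
  )
}

validate_nodes <- function(nodes, width, height) {
  req <- c("id", "x", "y", "cell_class")
  if (!is.data.frame(nodes) || !all(req %in% names(nodes))) {
    stopf("`nodes` must be a data frame with columns %s",
          paste(req, collapse = ", "))
  }
  nodes <- nodes[, req, drop = FALSE]
  nodes$id <- as.character(nodes$id)
  nodes$x <- as.numeric(nodes$x)
  nodes$y <- as.numeric(nodes$y)
  nodes$cell_class <- as.character(nodes$cell_class)
  if (nrow(nodes) == 0L) {
    rownames(nodes) <- NULL
    return(nodes)
  }
  if (anyNA(nodes)) stopf("node table contains missing values")
  bad <- !(nodes$cell_class %in% cell_classes())
  if (any(bad)) {
    stopf("unknown cell class %s for node '%s'",
          dQuote(nodes$cell_class[which(bad)[1]]), nodes$id[which(bad)[1]])
  }
  if (anyDuplicated(nodes$id)) {
    stopf("duplicate node id '%s'", nodes$id[anyDuplicated(nodes$id)])
  }
  oob <- nodes$x < 0 | nodes$x > width | nodes$y < 0 | nodes$y > height
  if (any(oob)) {
    i <- which(oob)[1]
    stopf("node '%s' at (%g, %g) lies outside the %g x %g tile",
          nodes$id[i], nodes$x[i], nodes$y[i], width, height)
  }
  rownames(nodes) <- NULL
  nodes
}

#' @export
print.tile_record <- function(x, ...) {
  cat(sprintf("<tile_record> %s: %g x %g px, %d cells, BM %s\n",
              x$tile_id, x$width, x$height, nrow(x$nodes),
              if (is.null(x$bm)) "absent" else
                sprintf("present (%d spline%s)", length(x$bm),
                        if (length(x$bm) == 1L) "" else "s")))
  if (nrow(x$nodes) > 0L) {
    print(table(factor(x$nodes$cell_class, levels = cell_classes())))
  }
  invisible(x)
}

#' Create a cell-graph
#'
#' A cell-graph is an undirected labelled graph whose nodes are cell-nucleus
#' centroids (labelled with coordinates and cell class) and whose edges
#' represent spatial proximity. Edges may carry an optional Boolean
#' `crossing` label indicating whether the straight segment between the two
#' centroids crosses the basement membrane.
#'
#' @param nodes Data frame with columns `id`, `x`, `y`, `cell_class`.
#' @param edges Data frame with character columns `from`, `to` (node ids)
#'   and optionally a logical `crossing` column; or `NULL` for no edges.
#' @param tile_id,width,height Provenance metadata (optional).
#' @return An object of class `cell_graph`.
#' @export
cell_graph <- function(nodes, edges = NULL, tile_id = NA_character_,
                       width = NA_real_, height = NA_real_) {
  nodes <- validate_nodes(nodes, width = Inf, height = Inf)
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        crossing = logical(), stringsAsFactors = FALSE)
  }
  if (!all(c("from", "to") %in% names(edges))) {
    stopf("`edges` must have columns `from` and `to`")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!"crossing" %in% names(edges)) edges$crossing <- rep(NA, nrow(edges))
  edges$crossing <- as.logical(edges$crossing)
  edges <- edges[, c("from", "to", "crossing"), drop = FALSE]
  if (nrow(edges) > 0L) {
    known <- c(edges$from, edges$to) %in% nodes$id
    if (!all(known)) {
      stopf("edge references unknown node id '%s'",
            c(edges$from, edges$to)[!known][1])
    }
    if (any(edges$from == edges$to)) stopf("self-loop edges are not allowed")
    # canonical order: from < to, rows sorted, to make graphs comparable
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    if (anyDuplicated(edges[, c("from", "to")])) {
      stopf("duplicate edges are not allowed")
    }
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(
    list(nodes = nodes, edges = edges, tile_id = tile_id,
         width = width, height = height),
    class = "cell_graph"
  )
}

#' @export
print.cell_graph <- function(x, ...) {
  lab <- if (nrow(x$edges) == 0L) "no edges"
  else if (all(is.na(x$edges$crossing))) "edges unlabelled"
  else if (anyNA(x$edges$crossing)) "edges partially labelled"
  else sprintf("%d crossing / %d non-crossing",
               sum(x$edges$crossing), sum(!x$edges$crossing))
  cat(sprintf("<cell_graph> %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges), lab))
  invisible(x)
}

# Edge endpoints as a 2-column index matrix into the node table.
edge_indices <- function(graph) {
  m <- cbind(match(graph$edges$from, graph$nodes$id),
             match(graph$edges$to, graph$nodes$id))
  storage.mode(m) <- "integer"
  m
}

# Euclidean edge lengths.
edge_lengths <- function(graph) {
  idx <- edge_indices(graph)
  if (nrow(idx) == 0L) return(numeric())
  sqrt((graph$nodes$x[idx[, 1]] - graph$nodes$x[idx[, 2]])^2 +
       (graph$nodes$y[idx[, 1]] - graph$nodes$y[idx[, 2]])^2)
}
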