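# Annotation and graph file I/O, tiling windows, dataset splitting.
#
# Annotation file dialect (JSON):
#   {"format": "cellgraph-tile", "version": 1,
#    "tile_id": str, "width": num, "height": num, "scale": num,
#    "cells": [{"id": str, "x": num, "y": num, "class": str}, ...],
#    "bm_splines": [[[x, y], ...], ...]}          # optional
# Class strings are exactly the four values of cell_classes().
#
# Graph file dialect (JSON):
#   {"format": "cellgraph-graph", "version": 1,
#    "tile_id": str, "width": num, "height": num,
#    "nodes": [{"id", "x", "y", "class"}, ...],
#    "edges": [{"from", "to", "crossing"?}, ...]}

TILE_FORMAT <- "cellgraph-tile"
GRAPH_FORMAT <- "cellgraph-graph"
FILE_VERSION <- 1L

#' Write a tile record to a JSON annotation file
#'
#' The output is byte-stable for identical input and coordinates are stored
#' with 17 significant digits so that [read_tile()] recovers them exactly.
#'
#' @param tile A [tile_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_tile()]
#' @export
write_tile <- function(tile, path) {
  stopifnot(inherits(tile, "tile_record"))
  doc <- list(
    format = TILE_FORMAT,
    version = FILE_VERSION,
    tile_id = tile$tile_id,
    width = tile$width,
    height = tile$height,
    scale = tile$scale,
    cells = if (nrow(tile$nodes) == 0L) list() else
      data.frame(id = tile$nodes$id, x = tile$nodes$x, y = tile$nodes$y,
                 class = tile$nodes$cell_class, stringsAsFactors = FALSE)
  )
  if (!is.null(tile$bm)) {
    doc$bm_splines <- lapply(tile$bm, function(s) unname(s))
  }
  write_json_doc(doc, path)
  invisible(path)
}

#' Read a tile record from a JSON annotation file
#'
#' Validates the schema: unknown cell-class strings, duplicate ids and
#' out-of-bounds coordinates are rejected with an error naming the offending
#' record.
#'
#' @param path Path to a file written by [write_tile()] (or conforming to the
#'   documented dialect).
#' @return A [tile_record()].
#' @export
read_tile <- function(path) {
  doc <- read_json_doc(path, TILE_FORMAT)
  for (f in c("tile_id", "width", "height")) {
    if (is.null(doc[[f]])) stopf("annotation file %s: missing field '%s'",
                                 path, f)
  }
  cells <- doc$cells
  if (is.null(cells) || length(cells) == 0L) {
    nodes <- NULL
  } else {
    if (!is.data.frame(cells)) {
      stopf("annotation file %s: 'cells' must be an array of records", path)
    }
    for (f in c("id", "x", "y", "class")) {
      if (is.null(cells[[f]])) {
        stopf("annotation file %s: cell records lack field '%s'", path, f)
      }
    }
    nodes <- data.frame(id = as.character(cells$id), x = cells$x, y = cells$y,
                        cell_class = as.character(cells$class),
                        stringsAsFactors = FALSE)
  }
  bm <- NULL
  if (!is.null(doc$bm_splines) && length(doc$bm_splines) > 0L) {
    bm <- bm_annotation(normalize_spline_json(doc$bm_splines))
  }
  tile_record(doc$tile_id, doc$width, doc$height, nodes = nodes, bm = bm,
              scale = if (is.null(doc$scale)) 2 else doc$scale)
}

#' Compute evenly distributed crop windows over a tile
#'
#' Per axis, the number of crops `k` is the smallest count such that
#' `k * crop - (k - 1) * overlap` covers the axis, and crop origins are
#' spread evenly as `round(i * (length - crop) / (k - 1))`. A 2000 x 2000
#' tile with 512-px crops and 16-px overlap yields 16 windows.
#'
#' @param width,height Tile dimensions in pixels.
#' @param crop Square crop side length in pixels.
#' @param overlap Minimum overlap between adjacent crops in pixels.
#' @return Data frame with columns `x0`, `y0`, `x1`, `y1` (half-open
#'   windows `[x0, x1) x [y0, y1)`).
#' @export
#' @examples
#' nrow(tile_windows(2000, 2000, 512, 16))  # 16
tile_windows <- function(width, height, crop, overlap = 0) {
  stopifnot(is_number(width), is_number(height), is_number(crop),
            is_number(overlap))
  if (crop > width || crop > height) {
    stopf("crop size %g exceeds tile dimensions %g x %g", crop, width, height)
  }
  if (overlap >= crop) stopf("overlap must be smaller than the crop size")
  axis_starts <- function(len) {
    k <- ceiling((len - overlap) / (crop - overlap))
    k <- max(k, 1)
    if (k == 1L) return(0)
    round((seq_len(k) - 1) * (len - crop) / (k - 1))
  }
  xs <- axis_starts(width)
  ys <- axis_starts(height)
  grid <- expand.grid(x0 = xs, y0 = ys)
  data.frame(x0 = grid$x0, y0 = grid$y0,
             x1 = grid$x0 + crop, y1 = grid$y0 + crop)
}

#' Discard windows with too few cell annotations
#'
#' A centroid belongs to the half-open window `[x0, x1) x [y0, y1)`, so
#' points on shared window boundaries are counted exactly once.
#'
#' @param windows Data frame as returned by [tile_windows()].
#' @param nodes Data frame with `x`, `y` columns (e.g. `tile$nodes`).
#' @param min_count Minimum number of centroids a window must contain to be
#'   kept (windows with fewer are discarded).
#' @return The subset of `windows` containing at least `min_count` centroids.
#' @export
filter_windows <- function(windows, nodes, min_count = 10L) {
  stopifnot(is_count(min_count))
  if (nrow(windows) == 0L) return(windows)
  counts <- count_in_windows(windows, nodes)
  out <- windows[counts >= min_count, , drop = FALSE]
  rownames(out) <- NULL
  out
}

count_in_windows <- function(windows, nodes) {
  vapply(seq_len(nrow(windows)), function(i) {
    sum(nodes$x >= windows$x0[i] & nodes$x < windows$x1[i] &
        nodes$y >= windows$y0[i] & nodes$y < windows$y1[i])
  }, integer(1))
}

#' Split tile ids into train/validation/test sets
#'
#' Tile-level (not node-level) split: the test fraction is taken from the
#' full set according to `ratio`, and the validation set is then drawn from
#' the training tiles as `val_fraction` of them (size rounded half-up).
#' Assignment is uniform at random and reproducible for a fixed seed.
#'
#' @param tile_ids Character vector of tile identifiers.
#' @param ratio Train:test ratio as a string (`"70:30"`) or a numeric pair
#'   summing to 100. The study design uses 60:40, 65:35 and 70:30.
#' @param val_fraction Fraction of the training tiles held out for
#'   validation (default 0.15).
#' @param seed Integer seed.
#' @return List with character elements `train`, `val`, `test` (pairwise
#'   disjoint, union equal to `tile_ids`) plus the `ratio` used.
#' @export
split_dataset <- function(tile_ids, ratio = "70:30", val_fraction = 0.15,
                          seed = 1L) {
  tile_ids <- as.character(tile_ids)
  if (anyDuplicated(tile_ids)) stopf("tile ids must be unique")
  if (is.character(ratio)) {
    ratio <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
  }
  if (length(ratio) != 2L || anyNA(ratio) || any(ratio < 0) ||
      abs(sum(ratio) - 100) > 1e-9) {
    stopf("`ratio` must be two non-negative parts summing to 100")
  }
  if (!is_number(val_fraction) || val_fraction < 0 || val_fraction >= 1) {
    stopf("`val_fraction` must be in [0, 1)")
  }
  n <- length(tile_ids)
  n_parts <- sum(ratio > 0) + (val_fraction > 0)
  if (n < n_parts) {
    stopf("%d tiles cannot be split into %d non-empty partitions", n, n_parts)
  }
  with_seed(seed, {
    shuffled <- sample(tile_ids)
    n_test <- round(n * ratio[2] / 100)
    test <- sort(shuffled[seq_len(n_test)])
    train_all <- shuffled[setdiff(seq_len(n), seq_len(n_test))]
    n_val <- round_half_up(val_fraction * length(train_all))
    val <- sort(train_all[seq_len(n_val)])
    train <- sort(train_all[setdiff(seq_along(train_all), seq_len(n_val))])
    list(train = train, val = val, test = test,
         ratio = paste(ratio, collapse = ":"))
  })
}

#' Save a cell-graph to a JSON file
#'
#' Lossless round-trip of nodes, edges, node labels and (possibly unset)
#' Boolean edge labels; see [load_graph()].
#'
#' @param graph A [cell_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_graph <- function(graph, path) {
  stopifnot(inherits(graph, "cell_graph"))
  doc <- list(
    format = GRAPH_FORMAT,
    version = FILE_VERSION,
    tile_id = graph$tile_id,
    width = graph$width,
    height = graph$height,
    nodes = if (nrow(graph$nodes) == 0L) list() else
      data.frame(id = graph$nodes$id, x = graph$nodes$x, y = graph$nodes$y,
                 class = graph$nodes$cell_class, stringsAsFactors = FALSE),
    edges = if (nrow(graph$edges) == 0L) list() else graph$edges
  )
  write_json_doc(doc, path)
  invisible(path)
}

#' Load a cell-graph from a JSON file
#'
#' @param path Path to a file written by [save_graph()]. A version mismatch
#'   raises an explicit error.
#' @return A [cell_graph()].
#' @export
load_graph <- function(path) {
  doc <- read_json_doc(path, GRAPH_FORMAT)
  nodes <- if (is.null(doc$nodes) || length(doc$nodes) == 0L) {
    data.frame(id = character(), x = numeric(), y = numeric(),
               cell_class = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(id = as.character(doc$nodes$id), x = doc$nodes$x,
               y = doc$nodes$y, cell_class = as.character(doc$nodes$class),
               stringsAsFactors = FALSE)
  }
  edges <- if (is.null(doc$edges) || length(doc$edges) == 0L) NULL else {
    e <- data.frame(from = as.character(doc$edges$from),
                    to = as.character(doc$edges$to),
                    stringsAsFactors = FALSE)
    e$crossing <- if (is.null(doc$edges$crossing)) NA else doc$edges$crossing
    e
  }
  cell_graph(nodes, edges,
             tile_id = if (is.null(doc$tile_id)) NA_character_ else doc$tile_id,
             width = if (is.null(doc$width)) NA_real_ else as.numeric(doc$width),
             height = if (is.null(doc$height)) NA_real_ else
               as.numeric(doc$height))
}

#' Export a cell-graph to GraphML
#'
#' Optional interoperability export (requires the igraph package). Node
#' attributes `x`, `y`, `cell_class` and the edge attribute `crossing` are
#' preserved.
#'
#' @param graph A [cell_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stopf("GraphML export requires the 'igraph' package")
  }
  vertices <- data.frame(name = graph$nodes$id, x = graph$nodes$x,
                         y = graph$nodes$y, cell_class = graph$nodes$cell_class,
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = vertices)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# jsonlite may simplify the nested spline arrays to a matrix (one spline) or
# a 3-d array (several equal-length splines); normalize back to a list of
# 2-column control-point matrices.
normalize_spline_json <- function(bs) {
  if (is.array(bs) && length(dim(bs)) == 3L) {
    return(lapply(seq_len(dim(bs)[1]), function(i) bs[i, , , drop = TRUE]))
  }
  if (is.matrix(bs)) return(list(bs))
  bs
}

write_json_doc <- function(doc, path) {
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           dataframe = "rows", na = "null", pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
}

read_json_doc <- function(path, expected_format, simplify_df = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = simplify_df),
    error = function(e) stopf("failed to parse %s: %s", path, conditionMessage(e))
  )
  if (!identical(doc$format, expected_format)) {
    stopf("%s is not a %s file (format field: %s)", path, expected_format,
          if (is.null(doc$format)) "absent" else doc$format)
  }
  if (is.null(doc$version) || doc$version != FILE_VERSION) {
    stopf("%s: unsupported file version %s (this build reads version %d)",
          path, if (is.null(doc$version)) "absent" else doc$version,
          FILE_VERSION)
  }
  doc
}
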