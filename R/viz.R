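# Rendering of edge predictions in the figure style of the study:
# true-positive edges green, false negatives yellow, false positives red,
# true negatives omitted; BM polyline blue; nodes coloured by cell class.

NODE_COLOURS <- c(epithelial = "red", fibroblast_endothelial = "blue",
                  inflammatory = "green3", lymphocytic = "yellow")
EDGE_COLOURS <- c(tp = "green3", fn = "yellow", fp = "red")
BM_COLOUR <- "blue"

#' Render edge predictions against ground truth
#'
#' Draws the tile with nodes coloured by cell class (epithelial red,
#' fibroblast/endothelial blue, inflammatory green, lymphocytic yellow) and
#' edges coloured by prediction outcome: true positives green, false
#' negatives yellow, false positives red; true negatives are not drawn. The
#' ground-truth BM annotation, when given, is superimposed as a blue line.
#' Pure function of its inputs: the graph is never modified.
#'
#' @param graph A [cell_graph()].
#' @param gt_labels Logical vector of ground-truth crossing labels, aligned
#'   with `graph$edges` (default: the graph's own `crossing` column).
#' @param pred_labels Logical vector of predicted labels, or the data frame
#'   returned by [predict_edges()].
#' @param bm Optional [bm_annotation()] to overlay.
#' @param path Output PNG path.
#' @param pixels Output image size in pixels (square).
#' @return Invisibly, a list with the number of drawn primitives:
#'   `tp`, `fn`, `fp`, `edges_drawn`, `nodes`.
#' @export
render_edge_predictions <- function(graph, gt_labels = graph$edges$crossing,
                                    pred_labels, bm = NULL, path,
                                    pixels = 1000) {
  stopifnot(inherits(graph, "cell_graph"))
  if (is.data.frame(pred_labels)) {
    key_g <- paste(graph$edges$from, graph$edges$to)
    key_p <- paste(pred_labels$from, pred_labels$to)
    m <- match(key_g, key_p)
    if (anyNA(m)) stopf("prediction table does not cover all graph edges")
    pred_labels <- pred_labels$crossing[m]
  }
  gt_labels <- as.logical(gt_labels)
  pred_labels <- as.logical(pred_labels)
  ne <- nrow(graph$edges)
  if (length(gt_labels) != ne || length(pred_labels) != ne ||
      anyNA(gt_labels) || anyNA(pred_labels)) {
    stopf("label sets must cover all %d edges without missing values", ne)
  }
  idx <- edge_indices(graph)
  status <- rep(NA_character_, ne)
  status[gt_labels & pred_labels] <- "tp"
  status[gt_labels & !pred_labels] <- "fn"
  status[!gt_labels & pred_labels] <- "fp"
  draw <- !is.na(status)

  W <- if (is.finite(graph$width)) graph$width else max(graph$nodes$x)
  H <- if (is.finite(graph$height)) graph$height else max(graph$nodes$y)
  grDevices::png(path, width = pixels, height = pixels)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0))
  # image convention: origin top-left, y increases downward
  graphics::plot(NA, xlim = c(0, W), ylim = c(H, 0), asp = 1, axes = FALSE,
                 xlab = "", ylab = "")
  if (any(draw)) {
    graphics::segments(graph$nodes$x[idx[draw, 1]],
                       graph$nodes$y[idx[draw, 1]],
                       graph$nodes$x[idx[draw, 2]],
                       graph$nodes$y[idx[draw, 2]],
                       col = EDGE_COLOURS[status[draw]], lwd = 2)
  }
  if (!is.null(bm)) {
    for (s in bm) graphics::lines(s[, 1], s[, 2], col = BM_COLOUR, lwd = 3)
  }
  graphics::points(graph$nodes$x, graph$nodes$y,
                   col = NODE_COLOURS[graph$nodes$cell_class], pch = 16,
                   cex = 0.6)
  invisible(list(tp = sum(status == "tp", na.rm = TRUE),
                 fn = sum(status == "fn", na.rm = TRUE),
                 fp = sum(status == "fp", na.rm = TRUE),
                 edges_drawn = sum(draw), nodes = nrow(graph$nodes)))
}
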