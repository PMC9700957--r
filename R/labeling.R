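# Ground-truth edge labelling: an edge is "crossing" iff its straight
# segment intersects any basement-membrane spline.

# Tolerance (px) for the orientation predicates: tangential touches and
# endpoints lying exactly on the curve count as crossing.
EPS_GEOM <- 1e-9

#' Does a straight segment cross a polyline?
#'
#' Splines are interpreted as piecewise-linear polylines through their
#' control points. Touching counts: a tangential contact or an endpoint
#' exactly on the polyline is reported as a crossing (within a 1e-9 px
#' tolerance). A zero-length segment returns `FALSE`.
#'
#' @param a,b Numeric length-2 vectors, the segment endpoints (x, y).
#' @param polyline Numeric matrix of polyline vertices (>= 2 rows).
#' @return Logical scalar.
#' @export
#' @examples
#' bm <- cbind(c(0, 10), c(5, 5))
#' segment_crosses_polyline(c(5, 0), c(5, 10), bm)  # TRUE
#' segment_crosses_polyline(c(5, 0), c(5, 4), bm)   # FALSE
segment_crosses_polyline <- function(a, b, polyline) {
  if (is.data.frame(polyline)) polyline <- as.matrix(polyline)
  stopifnot(length(a) == 2L, length(b) == 2L, is.matrix(polyline),
            ncol(polyline) == 2L, nrow(polyline) >= 2L)
  segments_cross_polyline(matrix(a, 1), matrix(b, 1), polyline)[1]
}

# Vectorized core: P1, P2 are n x 2 matrices of segment endpoints; returns a
# logical vector of length n. Touching (any |cross product| <= EPS_GEOM with
# the touching point inside the other segment's bounding range) counts.
segments_cross_polyline <- function(P1, P2, polyline) {
  n <- nrow(P1)
  out <- rep(FALSE, n)
  zero_len <- P1[, 1] == P2[, 1] & P1[, 2] == P2[, 2]
  for (s in seq_len(nrow(polyline) - 1L)) {
    q1 <- polyline[s, ]
    q2 <- polyline[s + 1L, ]
    todo <- !out & !zero_len
    if (!any(todo)) break
    out[todo] <- out[todo] |
      segs_intersect(P1[todo, , drop = FALSE], P2[todo, , drop = FALSE],
                     q1, q2)
  }
  out
}

# Segment-segment intersection of (p1, p2) against a fixed segment (q1, q2),
# vectorized over the p-segments. Proper crossings plus boundary touches.
segs_intersect <- function(P1, P2, q1, q2) {
  eps <- EPS_GEOM
  qd <- q2 - q1
  d1 <- qd[1] * (P1[, 2] - q1[2]) - qd[2] * (P1[, 1] - q1[1])
  d2 <- qd[1] * (P2[, 2] - q1[2]) - qd[2] * (P2[, 1] - q1[1])
  pdx <- P2[, 1] - P1[, 1]
  pdy <- P2[, 2] - P1[, 2]
  d3 <- pdx * (q1[2] - P1[, 2]) - pdy * (q1[1] - P1[, 1])
  d4 <- pdx * (q2[2] - P1[, 2]) - pdy * (q2[1] - P1[, 1])

  proper <- ((d1 > eps & d2 < -eps) | (d1 < -eps & d2 > eps)) &
            ((d3 > eps & d4 < -eps) | (d3 < -eps & d4 > eps))

  on_q <- function(d, pt_x, pt_y) {
    abs(d) <= eps &
      pt_x >= pmin(q1[1], q2[1]) - eps & pt_x <= pmax(q1[1], q2[1]) + eps &
      pt_y >= pmin(q1[2], q2[2]) - eps & pt_y <= pmax(q1[2], q2[2]) + eps
  }
  on_p <- function(d, pt) {
    abs(d) <= eps &
      pt[1] >= pmin(P1[, 1], P2[, 1]) - eps &
      pt[1] <= pmax(P1[, 1], P2[, 1]) + eps &
      pt[2] >= pmin(P1[, 2], P2[, 2]) - eps &
      pt[2] <= pmax(P1[, 2], P2[, 2]) + eps
  }
  touch <- on_q(d1, P1[, 1], P1[, 2]) | on_q(d2, P2[, 1], P2[, 2]) |
           on_p(d3, q1) | on_p(d4, q2)
  proper | touch
}

#' Label all graph edges against the basement membrane
#'
#' Sets the Boolean `crossing` label of every edge: `TRUE` iff the straight
#' segment between the two node centroids intersects at least one BM spline
#' (see [segment_crosses_polyline()]). Node labels are untouched. Labels are
#' invariant to spline orientation and to edge endpoint order.
#'
#' @param graph A [cell_graph()].
#' @param bm A [bm_annotation()] (or the `bm` field of a [tile_record()]);
#'   required.
#' @return The graph with a fully populated `crossing` edge label.
#' @export
label_ground_truth_edges <- function(graph, bm) {
  stopifnot(inherits(graph, "cell_graph"))
  if (is.null(bm)) stopf("cannot label edges: no BM annotation supplied")
  if (!inherits(bm, "bm_annotation")) bm <- bm_annotation(bm)
  if (nrow(graph$edges) == 0L) return(graph)
  idx <- edge_indices(graph)
  P1 <- cbind(graph$nodes$x[idx[, 1]], graph$nodes$y[idx[, 1]])
  P2 <- cbind(graph$nodes$x[idx[, 2]], graph$nodes$y[idx[, 2]])
  crossing <- rep(FALSE, nrow(idx))
  for (spline in bm) {
    crossing <- crossing | segments_cross_polyline(P1, P2, spline)
  }
  graph$edges$crossing <- crossing
  graph
}
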