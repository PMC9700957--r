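# Independent oracles and fixture builders used across the test files.

# Brute-force Delaunay: edge {i, j} belongs to the triangulation iff some
# circle through i and j (here: a circumcircle with a third point) is empty
# of all other points. O(n^3) triple enumeration; trusted reference for
# small point sets in general position.
brute_delaunay <- function(pts) {
  n <- nrow(pts)
  if (n == 2L) return(matrix(c(1L, 2L), 1, 2))
  circum <- function(a, b, c) {
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
              c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-14) return(NULL)
    s <- c(sum(a^2), sum(b^2), sum(c^2))
    cbind(
      (s[1] * (b[2] - c[2]) + s[2] * (c[2] - a[2]) + s[3] * (a[2] - b[2])) / d,
      (s[1] * (c[1] - b[1]) + s[2] * (a[1] - c[1]) + s[3] * (b[1] - a[1])) / d
    )
  }
  out <- matrix(integer(), 0, 2)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      for (k in setdiff(seq_len(n), c(i, j))) {
        cc <- circum(pts[i, ], pts[j, ], pts[k, ])
        if (is.null(cc)) next
        r2 <- sum((pts[i, ] - cc)^2)
        others <- setdiff(seq_len(n), c(i, j, k))
        d2 <- (pts[others, 1] - cc[1])^2 + (pts[others, 2] - cc[2])^2
        if (all(d2 > r2 * (1 + 1e-12))) {
          out <- rbind(out, c(i, j))
          break
        }
      }
    }
  }
  out
}

edge_key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))

# Parametric segment-segment intersection oracle: solves the 2x2 linear
# system p1 + t (p2 - p1) = q1 + u (q2 - q1); intersecting (touch included)
# iff t, u in [0, 1]. Parallel/collinear handled by projection overlap.
segments_intersect_oracle <- function(p1, p2, q1, q2, eps = 1e-9) {
  r <- p2 - p1
  s <- q2 - q1
  denom <- r[1] * s[2] - r[2] * s[1]
  qp <- q1 - p1
  if (abs(denom) > eps) {
    t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
    u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
    return(t >= -eps && t <= 1 + eps && u >= -eps && u <= 1 + eps)
  }
  # parallel: intersect only if collinear and overlapping
  cross <- qp[1] * r[2] - qp[2] * r[1]
  if (abs(cross) > eps) return(FALSE)
  rl <- sum(r^2)
  if (rl < eps^2) return(all(abs(qp) <= eps))
  t0 <- sum(qp * r) / rl
  t1 <- t0 + sum(s * r) / rl
  max(min(t0, t1), 0) <= min(max(t0, t1), 1) + eps
}

polyline_cross_oracle <- function(a, b, poly, eps = 1e-9) {
  if (all(a == b)) return(FALSE)
  for (s in seq_len(nrow(poly) - 1)) {
    if (segments_intersect_oracle(a, b, poly[s, ], poly[s + 1, ], eps)) {
      return(TRUE)
    }
  }
  FALSE
}

# Brute-force planarity: no two edges of the graph properly cross.
properly_crossing_pairs <- function(pts, edges) {
  ne <- nrow(edges)
  if (ne < 2) return(0L)
  crossings <- 0L
  orient <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  for (i in seq_len(ne - 1)) {
    for (j in seq(i + 1, ne)) {
      v <- c(edges[i, ], edges[j, ])
      if (anyDuplicated(v)) next  # shared endpoint: cannot properly cross
      a <- pts[edges[i, 1], ]; b <- pts[edges[i, 2], ]
      c_ <- pts[edges[j, 1], ]; d <- pts[edges[j, 2], ]
      if (orient(a, b, c_) * orient(a, b, d) < 0 &&
          orient(c_, d, a) * orient(c_, d, b) < 0) {
        crossings <- crossings + 1L
      }
    }
  }
  crossings
}

# Small tile with hand-placed nodes.
make_tile <- function(x, y, classes, width = 100, height = 100, bm = NULL,
                      tile_id = "t") {
  tile_record(tile_id, width, height,
              nodes = data.frame(id = sprintf("n%02d", seq_along(x)),
                                 x = x, y = y, cell_class = classes,
                                 stringsAsFactors = FALSE),
              bm = bm)
}

# Tiny simulated tissue config for fast tests.
small_sim_config <- function(...) {
  defaults <- list(width = 500, height = 500, bm_baseline = 250,
                   bm_amplitude = 60, bm_wavelength = 350)
  args <- utils::modifyList(defaults, list(...))
  do.call(tissue_sim_config, args)
}

# A labelled graph from a small simulated tile.
small_labelled_graph <- function(seed = 1, d = 100, ...) {
  tile <- generate_tissue(small_sim_config(...), seed = seed)
  label_ground_truth_edges(build_cell_graph(tile, graph_build_config(d = d)),
                           tile$bm)
}
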