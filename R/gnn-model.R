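# GraphSage-style edge classifier: model container, feature encoding and the
# reference (vectorized R) forward pass.

#' Construct a GraphSage edge-classifier model
#'
#' Node features are one-hot cell classes (coordinates are deliberately not
#' used: they are orientation dependent). Each layer aggregates a sampled
#' neighborhood with an element-wise max over a learned transform
#' (max-pool aggregator), concatenates the aggregate with the node's previous
#' state, and applies a linear map and ReLU; layer outputs are L2-normalized
#' by default. Two edge heads are available:
#'
#' * `"pair_mlp"` (default): a fully connected network on the symmetric pair
#'   representation `[z_i + z_j ; |z_i - z_j|]` with output dimension 1 and a
#'   sigmoid. This is the default because a score of the form
#'   `sigmoid(f(z_i) . f(z_j))` is structurally unable to assign probability
#'   below 0.5 to an edge whose endpoints have identical embeddings (the dot
#'   product of a vector with itself is non-negative), and interior nodes of
#'   a tissue compartment have identical class-composition neighborhoods.
#' * `"dot"`: a single affine map to a scalar `o_v` per node with edge
#'   probability `sigmoid(o_i * o_j)` (see [edge_probability()]).
#'
#' @param hidden Hidden dimension of each GraphSage layer (default 64).
#' @param layers Number of message-passing layers K (default 2; deeper GNNs
#'   oversmooth).
#' @param sample_size Neighborhood sample size S (default 10, enough to
#'   cover the immediate neighborhood of almost every node in a d-limited
#'   Delaunay cell-graph).
#' @param normalize L2-normalize each layer output (default `TRUE`).
#' @param dropout Dropout rate applied to each layer output during training.
#' @param head `"pair_mlp"` or `"dot"`.
#' @param head_hidden Hidden width of the pair-MLP head.
#' @param input_dim Feature dimension (4 one-hot cell classes).
#' @param seed Seed for weight initialization (Glorot uniform).
#' @return An object of class `sage_model`.
#' @export
sage_model <- function(hidden = 64, layers = 2, sample_size = 10,
                       normalize = TRUE, dropout = 0.3,
                       head = c("pair_mlp", "dot"), head_hidden = 32,
                       input_dim = length(cell_classes()), seed = 1L) {
  head <- match.arg(head)
  stopifnot(is_count(layers, 0L), is_count(hidden, 1L),
            is_count(sample_size, 1L), dropout >= 0, dropout < 1)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  with_seed(seed, {
    dims <- c(input_dim, rep(hidden, layers))
    lyr <- lapply(seq_len(layers), function(k) {
      din <- dims[k]
      list(Wpool = glorot(hidden, din),
           bpool = rep(0, hidden),
           W = glorot(hidden, din + hidden))
    })
    zdim <- dims[length(dims)]
    hd <- if (head == "pair_mlp") {
      list(type = "pair_mlp",
           W1 = glorot(head_hidden, 2 * zdim),
           b1 = rep(0, head_hidden),
           w2 = as.numeric(glorot(head_hidden, 1)),
           b2 = 0)
    } else {
      list(type = "dot", w = as.numeric(glorot(zdim, 1)), b = 0)
    }
    structure(
      list(layers = lyr, head = hd,
           meta = list(hidden = hidden, n_layers = layers,
                       sample_size = sample_size, normalize = normalize,
                       dropout = dropout, input_dim = input_dim,
                       head_type = head, classes = cell_classes())),
      class = "sage_model"
    )
  })
}

#' @export
print.sage_model <- function(x, ...) {
  n_par <- sum(vapply(unlist(x$layers, recursive = FALSE), length, numeric(1))) +
    sum(vapply(x$head[-1], length, numeric(1)))
  cat(sprintf(
    "<sage_model> %d layer(s), hidden %d, sample size %d, %s head, %d parameters\n",
    x$meta$n_layers, x$meta$hidden, x$meta$sample_size, x$meta$head_type,
    as.integer(n_par)))
  invisible(x)
}

#' One-hot node features
#'
#' Encodes each node's cell class as a one-hot vector in the fixed class
#' order of [cell_classes()]. Coordinates are not part of the features.
#'
#' @param graph A [cell_graph()].
#' @return Numeric matrix (nodes x 4), rows named by node id.
#' @export
encode_node_features <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  classes <- cell_classes()
  idx <- match(graph$nodes$cell_class, classes)
  X <- matrix(0, nrow(graph$nodes), length(classes),
              dimnames = list(graph$nodes$id, classes))
  X[cbind(seq_along(idx), idx)] <- 1
  X
}

# Adjacency in compressed form: ptr (length n+1, 1-based offsets) and idx
# (neighbor node indices, grouped by node, ascending within each group).
graph_adjacency <- function(graph) {
  n <- nrow(graph$nodes)
  idx <- edge_indices(graph)
  both <- rbind(idx, idx[, 2:1, drop = FALSE])
  o <- order(both[, 1], both[, 2])
  both <- both[o, , drop = FALSE]
  deg <- tabulate(both[, 1], nbins = n)
  list(ptr = c(0L, cumsum(deg)), idx = both[, 2], deg = deg)
}

#' Sample the neighborhood of a node
#'
#' Returns all neighbors when the degree is at most `S` (a sample size of 10
#' typically covers the entire immediate neighborhood in a d-limited
#' Delaunay cell-graph); otherwise a uniform sample of `S` distinct
#' neighbors. An isolated node yields an empty set (its aggregated state is
#' then the zero vector).
#'
#' @param graph A [cell_graph()].
#' @param v Node id (character) or node index.
#' @param S Maximum sample size (>= 1).
#' @param seed Optional seed for reproducible sampling.
#' @return Character vector of neighbor node ids.
#' @export
sample_neighborhood <- function(graph, v, S = 10L, seed = NULL) {
  stopifnot(inherits(graph, "cell_graph"), is_count(S, 1L))
  vi <- if (is.character(v)) match(v, graph$nodes$id) else as.integer(v)
  if (is.na(vi) || vi < 1L || vi > nrow(graph$nodes)) {
    stopf("unknown node '%s'", as.character(v))
  }
  adj <- graph_adjacency(graph)
  nb <- adj$idx[seq_len(adj$deg[vi]) + adj$ptr[vi]]
  if (length(nb) > S) {
    nb <- with_seed(seed, sample(nb, S))
  }
  graph$nodes$id[nb]
}

#' Max-pool neighborhood aggregation
#'
#' Applies the learned transform `activation(W_pool %*% h + b)` to every
#' neighbor state and takes the element-wise maximum. An empty neighbor set
#' yields the zero vector (documented convention for isolated nodes).
#'
#' @param neighbor_states Numeric matrix (neighbors x dim), one row per
#'   neighbor; may have zero rows.
#' @param W_pool Pooling weight matrix (out_dim x dim).
#' @param b Bias vector (length out_dim).
#' @param activation Elementwise activation, default ReLU.
#' @return Numeric vector of length `nrow(W_pool)`.
#' @export
#' @examples
#' maxpool_aggregate(rbind(c(1, 2), c(3, 0)), diag(2), c(0, 0))  # c(3, 2)
maxpool_aggregate <- function(neighbor_states, W_pool, b,
                              activation = function(x) pmax(x, 0)) {
  if (is.null(neighbor_states) || nrow(neighbor_states) == 0L) {
    return(rep(0, nrow(W_pool)))
  }
  if (ncol(neighbor_states) != ncol(W_pool)) {
    stopf("neighbor state dimension %d does not match W_pool columns %d",
          ncol(neighbor_states), ncol(W_pool))
  }
  A <- activation(neighbor_states %*% t(W_pool) +
                  matrix(b, nrow(neighbor_states), length(b), byrow = TRUE))
  apply(A, 2, max)
}

#' GraphSage forward pass (reference implementation)
#'
#' Computes the layerwise node states: at layer k each node's sampled
#' neighborhood is max-pool aggregated, concatenated with the node's
#' previous state, linearly transformed and passed through ReLU, with
#' optional L2 normalization. `h^0` is the input feature matrix and the
#' final embedding is `z = h^K`. In exhaustive mode (default) every neighbor
#' is used and the pass is deterministic; dropout is never applied here
#' (this is the inference path).
#'
#' @param graph A [cell_graph()].
#' @param model A [sage_model()].
#' @param features Feature matrix (nodes x input_dim); defaults to
#'   [encode_node_features()].
#' @param exhaustive If `TRUE` use all neighbors; otherwise sample
#'   `model$meta$sample_size` neighbors per node per layer.
#' @param seed Seed for sampling when `exhaustive = FALSE`.
#' @return List with `z` (final embeddings, nodes x hidden) and `h` (list of
#'   per-layer state matrices, starting at `h[[1]] = h^0`).
#' @export
graphsage_forward <- function(graph, model, features = NULL,
                              exhaustive = TRUE, seed = NULL) {
  stopifnot(inherits(graph, "cell_graph"), inherits(model, "sage_model"))
  if (is.null(features)) features <- encode_node_features(graph)
  n <- nrow(graph$nodes)
  stopifnot(nrow(features) == n, ncol(features) == model$meta$input_dim)
  adj <- graph_adjacency(graph)
  S <- if (exhaustive) Inf else model$meta$sample_size

  nbr_ranks <- function(idx, ptr, deg) {
    # neighbor table by rank: list over r of (node, neighbor) index pairs
    maxdeg <- if (length(deg)) max(deg) else 0L
    lapply(seq_len(maxdeg), function(r) {
      v <- which(deg >= r)
      cbind(v = v, u = idx[ptr[v] + r])
    })
  }
  if (!exhaustive && is.finite(S)) {
    # rebuild a sampled adjacency, at most S neighbors per node
    adj <- with_seed(seed, {
      picks <- lapply(seq_len(n), function(v) {
        nb <- adj$idx[seq_len(adj$deg[v]) + adj$ptr[v]]
        if (length(nb) > S) sample(nb, S) else nb
      })
      deg <- lengths(picks)
      list(ptr = c(0L, cumsum(deg)), idx = unlist(picks), deg = deg)
    })
  }
  ranks <- nbr_ranks(adj$idx, adj$ptr, adj$deg)

  H <- vector("list", model$meta$n_layers + 1L)
  H[[1]] <- unname(features)
  Hcur <- H[[1]]
  for (k in seq_len(model$meta$n_layers)) {
    L <- model$layers[[k]]
    hk <- nrow(L$W)
    M <- pmax(Hcur %*% t(L$Wpool) +
              matrix(L$bpool, n, hk, byrow = TRUE), 0)
    AGG <- matrix(-Inf, n, hk)
    for (r in ranks) {
      AGG[r[, "v"], ] <- pmax(AGG[r[, "v"], , drop = FALSE],
                              M[r[, "u"], , drop = FALSE])
    }
    AGG[adj$deg == 0L, ] <- 0
    Hnew <- pmax(cbind(Hcur, AGG) %*% t(L$W), 0)
    if (model$meta$normalize) {
      rr <- pmax(sqrt(rowSums(Hnew^2)), 1e-12)
      Hnew <- Hnew / rr
    }
    H[[k + 1L]] <- Hnew
    Hcur <- Hnew
  }
  rownames(Hcur) <- graph$nodes$id
  list(z = Hcur, h = H)
}

# Edge logits for a model head given embeddings z (nodes x dim) and an edge
# index matrix (rows: from, to).
head_logits <- function(model, z, idx) {
  hd <- model$head
  if (nrow(idx) == 0L) return(numeric())
  if (hd$type == "pair_mlp") {
    zi <- z[idx[, 1], , drop = FALSE]
    zj <- z[idx[, 2], , drop = FALSE]
    C <- cbind(zi + zj, abs(zi - zj))
    Hh <- pmax(C %*% t(hd$W1) +
               matrix(hd$b1, nrow(C), length(hd$b1), byrow = TRUE), 0)
    as.numeric(Hh %*% hd$w2 + hd$b2)
  } else {
    o <- as.numeric(z %*% hd$w + hd$b)
    o[idx[, 1]] * o[idx[, 2]]
  }
}

#' Edge crossing probability from two scalar node scores
#'
#' The literal scalar-product edge head: the probability that the edge
#' between nodes i and j crosses the BM is the logistic function of the
#' product of their scalar head outputs. Symmetric in its arguments and
#' equal to 0.5 when either score is zero. See [sage_model()] for why the
#' package's default edge head generalizes this form.
#'
#' @param o_i,o_j Scalar node scores (vectorized).
#' @return Probabilities in (0, 1).
#' @export
#' @examples
#' edge_probability(1, 2)  # 0.8808
edge_probability <- function(o_i, o_j) {
  stats::plogis(o_i * o_j)
}

#' Focal loss
#'
#' `FL = -alpha * (1 - p)^gamma * log(p)` for positive labels and
#' `-(1 - alpha) * p^gamma * log(1 - p)` otherwise; probabilities are
#' clamped to `[1e-7, 1 - 1e-7]` before taking logs. At `gamma = 0`,
#' `alpha = 0.5` it reduces to 0.5 times the cross-entropy.
#'
#' @param p Predicted probabilities.
#' @param y Labels in \{0, 1\} (or logical).
#' @param alpha Class-balance weight in \[0, 1\].
#' @param gamma Focusing parameter (>= 0).
#' @return Loss values (vectorized).
#' @export
focal_loss <- function(p, y, alpha = 0.25, gamma = 2) {
  stopifnot(alpha >= 0, alpha <= 1, gamma >= 0)
  n <- max(length(p), length(y))
  p <- clamp(rep_len(p, n), 1e-7, 1 - 1e-7)
  y <- rep_len(as.numeric(y), n)
  out <- numeric(n)
  pos <- y == 1
  out[pos] <- -alpha * (1 - p[pos])^gamma * log(p[pos])
  out[!pos] <- -(1 - alpha) * p[!pos]^gamma * log(1 - p[!pos])
  out
}

#' Step-decay learning-rate schedule
#'
#' The learning rate starts at `initial` and is multiplied by `factor` after
#' every `every` epochs: with the defaults, epochs 1-40 run at 1e-3, 41-80
#' at 1e-4 and 81-100 at 1e-5.
#'
#' @param epoch Epoch number (1-based; vectorized).
#' @param initial Initial learning rate.
#' @param factor Multiplicative decay.
#' @param every Epochs between decays.
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, initial = 1e-3, factor = 0.1, every = 40L) {
  stopifnot(all(epoch >= 1))
  # normalize to 12 significant digits so decimal step factors give the
  # stepped rates exactly (1e-3, 1e-4, 1e-5), not 1e-3 * 0.1^k rounding dust
  signif(initial * factor^(floor((epoch - 1) / every)), 12)
}

#' Save / load a model checkpoint
#'
#' Single JSON file with a version tag, configuration and all weights;
#' [load_model()] restores an identical model.
#'
#' @param model A [sage_model()].
#' @param path File path.
#' @return `path` invisibly ([save_model()]); a [sage_model()]
#'   ([load_model()]).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sage_model"))
  doc <- list(format = "cellgraph-model", version = FILE_VERSION,
              meta = model$meta, layers = model$layers, head = model$head)
  write_json_doc(doc, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- read_json_doc(path, "cellgraph-model", simplify_df = FALSE)
  layers <- lapply(doc$layers, function(l) {
    list(Wpool = as_matrix(l$Wpool), bpool = as.numeric(l$bpool),
         W = as_matrix(l$W))
  })
  head <- doc$head
  if (head$type == "pair_mlp") {
    head$W1 <- as_matrix(head$W1)
    head$b1 <- as.numeric(head$b1)
    head$w2 <- as.numeric(head$w2)
  } else {
    head$w <- as.numeric(head$w)
  }
  meta <- doc$meta
  meta$classes <- as.character(meta$classes)
  structure(list(layers = layers, head = head, meta = meta),
            class = "sage_model")
}

as_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}
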