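test_that("node features are one-hot in the fixed class order", {
  tile <- make_tile(c(1, 2, 3, 4), c(1, 1, 1, 1), cell_classes())
  g <- build_cell_graph(tile)
  X <- encode_node_features(g)
  expect_equal(unname(X), diag(4))
  expect_true(all(rowSums(X) == 1))

  # features ignore coordinates entirely: translate/rotate and re-encode
  nodes2 <- tile$nodes
  th <- pi / 5
  x2 <- nodes2$x * cos(th) - nodes2$y * sin(th) + 10
  y2 <- nodes2$x * sin(th) + nodes2$y * cos(th) + 20
  tile2 <- make_tile(x2, y2, nodes2$cell_class)
  expect_identical(encode_node_features(build_cell_graph(tile2)), X)
})

test_that("neighborhood sampling covers small neighborhoods and is uniform", {
  # star graph: hub connected to 20 leaves
  n <- 21
  nodes <- data.frame(id = sprintf("n%02d", 1:n),
                      x = 2 + c(0, cos(seq_len(20))),
                      y = 2 + c(0, sin(seq_len(20))),
                      cell_class = "epithelial")
  edges <- data.frame(from = "n01", to = sprintf("n%02d", 2:n))
  g <- cell_graph(nodes, edges)

  # degree 6 node with S = 10: exactly the neighbors, no sampling
  expect_setequal(sample_neighborhood(g, "n02", S = 10), "n01")
  expect_setequal(sample_neighborhood(g, "n01", S = 25),
                  sprintf("n%02d", 2:n))
  expect_length(sample_neighborhood(g, "n01", S = 10), 10)
  expect_identical(sample_neighborhood(g, "n01", S = 10, seed = 4),
                   sample_neighborhood(g, "n01", S = 10, seed = 4))

  # isolated node
  g2 <- cell_graph(nodes, NULL)
  expect_length(sample_neighborhood(g2, "n01", S = 10), 0)

  # repeated draws are uniform over neighbors within 3 SE
  draws <- 3000
  counts <- table(unlist(lapply(seq_len(draws) + 100,
                                function(s) sample_neighborhood(g, "n01",
                                                                S = 10,
                                                                seed = s))))
  expected <- draws * 10 / 20
  se <- sqrt(draws * 0.5 * 0.5)
  expect_true(all(abs(counts - expected) <= 3 * se))
  expect_length(counts, 20)
})

test_that("max-pool aggregation matches hand computation", {
  expect_equal(maxpool_aggregate(rbind(c(1, 2), c(3, 0)), diag(2), c(0, 0)),
               c(3, 2))
  expect_equal(maxpool_aggregate(matrix(numeric(), 0, 2), diag(2), c(0, 0)),
               c(0, 0))
  expect_equal(maxpool_aggregate(rbind(c(1, -2)), diag(2), c(0, 0)),
               c(1, 0))  # single neighbor: sigma(W h + b)
  # bias and a non-trivial W: relu(W h + b) per neighbor, then max
  # h1 -> relu((3, -2) + (-3, 1)) = (0, 0); h2 -> relu((3, 0) + (-3, 1)) = (0, 1)
  W <- rbind(c(1, 1), c(0, -1))
  expect_equal(maxpool_aggregate(rbind(c(1, 2), c(3, 0)), W, c(-3, 1)),
               c(0, 1))
  expect_error(maxpool_aggregate(rbind(c(1, 2, 3)), diag(2), c(0, 0)),
               "dimension")
})

test_that("the forward pass reproduces a hand-computed two-node example", {
  tile <- make_tile(c(1, 2), c(1, 1), c("epithelial", "inflammatory"))
  g <- build_cell_graph(tile)
  m <- sage_model(hidden = 4, layers = 1, normalize = FALSE, dropout = 0,
                  seed = 1)
  m$layers[[1]]$Wpool <- diag(4)
  m$layers[[1]]$bpool <- rep(0, 4)
  m$layers[[1]]$W <- cbind(diag(4), diag(4))  # h1 = relu(x_self + agg)
  fw <- graphsage_forward(g, m)
  # node 1 (epithelial, neighbor inflammatory): (1,0,0,0) + (0,0,1,0)
  expect_equal(unname(fw$z), rbind(c(1, 0, 1, 0), c(1, 0, 1, 0)))
  expect_equal(fw$h[[1]], unname(encode_node_features(g)))

  # K = 0: embeddings are the input features
  m0 <- sage_model(hidden = 4, layers = 0, seed = 1)
  expect_equal(unname(graphsage_forward(g, m0)$z),
               unname(encode_node_features(g)))

  # exhaustive mode is deterministic
  g2 <- small_labelled_graph(seed = 3)
  m2 <- sage_model(seed = 2)
  expect_identical(graphsage_forward(g2, m2)$z, graphsage_forward(g2, m2)$z)
})

test_that("R and C++ forward passes agree on full graphs", {
  g <- small_labelled_graph(seed = 5)
  arr <- cellgraph:::graphs_to_arrays(list(g))
  for (head in c("pair_mlp", "dot")) {
    m <- sage_model(hidden = 16, head = head, seed = 11)
    pr <- predict_edges(g, m)
    pc <- cellgraph:::.cpp_sage_probs(m$layers, m$head, arr$X, arr$adj_ptr,
                                      arr$adj_idx, arr$E,
                                      arr$max_degree + 1L, TRUE)
    expect_equal(pr$probability, pmin(pmax(pc, 1e-7), 1 - 1e-7),
                 tolerance = 1e-10)
  }
})

test_that("analytic gradients match finite differences", {
  g <- small_labelled_graph(seed = 3, width = 300, height = 300,
                            bm_baseline = 150, bm_amplitude = 40,
                            bm_wavelength = 200)
  arr <- cellgraph:::graphs_to_arrays(list(g))
  eps <- 1e-6
  for (spec in list(list(head = "pair_mlp", loss = 0L),
                    list(head = "dot", loss = 1L))) {
    m <- sage_model(hidden = 5, head = spec$head, head_hidden = 4, seed = 7)
    lg <- cellgraph:::.cpp_sage_loss_grad(m$layers, m$head, arr$X,
                                          arr$adj_ptr, arr$adj_idx, arr$E,
                                          arr$y, 50L, TRUE, spec$loss, 2.5,
                                          0.25, 2)
    loss_at <- function(mm) {
      cellgraph:::.cpp_sage_loss_grad(mm$layers, mm$head, arr$X, arr$adj_ptr,
                                      arr$adj_idx, arr$E, arr$y, 50L, TRUE,
                                      spec$loss, 2.5, 0.25, 2)$loss
    }
    set.seed(5)
    for (probe in 1:8) {
      k <- sample(2, 1)
      nm <- sample(c("Wpool", "W", "bpool"), 1)
      target <- m$layers[[k]][[nm]]
      i <- sample(length(target), 1)
      mp <- m; mp$layers[[k]][[nm]][i] <- target[i] + eps
      mn <- m; mn$layers[[k]][[nm]][i] <- target[i] - eps
      num <- (loss_at(mp) - loss_at(mn)) / (2 * eps)
      expect_equal(lg$grad_layers[[k]][[nm]][i], num,
                   tolerance = 1e-4 * (1 + abs(num)))
    }
    hn <- setdiff(names(m$head), "type")
    for (nm in hn) {
      i <- 1L
      mp <- m; mp$head[[nm]][i] <- m$head[[nm]][i] + eps
      mn <- m; mn$head[[nm]][i] <- m$head[[nm]][i] - eps
      num <- (loss_at(mp) - loss_at(mn)) / (2 * eps)
      expect_equal(lg$grad_head[[nm]][i], num,
                   tolerance = 1e-4 * (1 + abs(num)))
    }
  }
})

test_that("edge probability is the logistic of the score product", {
  expect_identical(edge_probability(0, 3), 0.5)
  expect_identical(edge_probability(5, 0), 0.5)
  expect_equal(edge_probability(1, 2), 1 / (1 + exp(-2)))
  expect_equal(round(edge_probability(1, 2), 4), 0.8808)
  expect_identical(edge_probability(1.7, -0.3), edge_probability(-0.3, 1.7))
  p <- edge_probability(runif(50, -5, 5), runif(50, -5, 5))
  expect_true(all(p > 0 & p < 1))
})

test_that("focal loss matches its definition and limits", {
  # gamma = 0, alpha = 0.5 reduces to half the cross-entropy
  p <- c(0.1, 0.5, 0.9)
  expect_equal(focal_loss(p, 1, alpha = 0.5, gamma = 0), 0.5 * (-log(p)))
  expect_equal(focal_loss(p, 0, alpha = 0.5, gamma = 0), 0.5 * (-log(1 - p)))
  expect_equal(focal_loss(0.9, 1, alpha = 0.25, gamma = 2),
               -0.25 * 0.1^2 * log(0.9))
  expect_equal(round(focal_loss(0.9, 1, alpha = 0.25, gamma = 2), 7),
               0.0002634)
  # confident correct prediction: loss tends to zero (clamped at 1e-7)
  expect_lt(focal_loss(1, 1, 0.25, 2), 1e-20)
  expect_true(is.finite(focal_loss(0, 1, 0.25, 2)))
})

test_that("the learning-rate schedule is an exact step decay", {
  lr <- lr_schedule(1:100)
  expect_true(all(lr[1:40] == 1e-3))
  expect_true(all(lr[41:80] == 1e-4))
  expect_true(all(lr[81:100] == 1e-5))
})

test_that("training is reproducible, trainable, and 0 epochs is the identity", {
  graphs <- lapply(1:3, small_labelled_graph)
  m <- sage_model(hidden = 16, seed = 3)

  fit0 <- train_gnn(graphs[1:2], graphs[3], m, train_config(epochs = 0L))
  expect_identical(fit0$model$layers, m$layers)
  expect_identical(fit0$model$head, m$head)
  expect_identical(nrow(fit0$history), 0L)

  cfg <- train_config(epochs = 3L, seed = 42)
  f1 <- train_gnn(graphs[1:2], graphs[3], m, cfg)
  f2 <- train_gnn(graphs[1:2], graphs[3], m, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$layers, f2$model$layers)
  expect_identical(f1$model$head, f2$model$head)
  cfg2 <- train_config(epochs = 3L, seed = 43)
  expect_false(identical(train_gnn(graphs[1:2], graphs[3], m, cfg2)$history,
                         f1$history))

  # on a cleanly separable tile set the loss decreases
  f10 <- train_gnn(graphs[1:2], graphs[3], m, train_config(epochs = 10L,
                                                           seed = 1))
  expect_lt(f10$history$train_loss[10], f10$history$train_loss[1])
  expect_error(train_gnn(list(build_cell_graph(generate_tissue(
    small_sim_config(), seed = 1))), list(), m, cfg), "unlabelled")
})

test_that("predictions are threshold-consistent and orientation invariant", {
  g <- small_labelled_graph(seed = 8)
  m <- sage_model(hidden = 16, seed = 9)
  fit <- train_gnn(list(g), list(), m, train_config(epochs = 5L, seed = 2))
  pred <- predict_edges(g, fit$model)
  expect_identical(pred$crossing, pred$probability >= 0.5)
  expect_true(all(predict_edges(g, fit$model, threshold = 0)$crossing))
  expect_false(any(predict_edges(g, fit$model, threshold = 1)$crossing))

  # rotating and translating the tile leaves predictions unchanged
  th <- pi / 3
  n2 <- g$nodes
  x2 <- n2$x * cos(th) - n2$y * sin(th) + 500
  y2 <- n2$x * sin(th) + n2$y * cos(th) + 200
  g2 <- cell_graph(data.frame(id = n2$id, x = x2, y = y2,
                              cell_class = n2$cell_class), g$edges)
  pred2 <- predict_edges(g2, fit$model)
  expect_equal(pred2$probability, pred$probability)
})

test_that("model checkpoints round-trip through JSON", {
  for (head in c("pair_mlp", "dot")) {
    m <- sage_model(hidden = 8, head = head, seed = 13)
    path <- withr::local_tempfile(fileext = ".json")
    save_model(m, path)
    back <- load_model(path)
    expect_equal(back$layers, m$layers)
    expect_equal(back$head, m$head)
    expect_equal(back$meta[order(names(back$meta))],
                 m$meta[order(names(m$meta))])
    g <- small_labelled_graph(seed = 2)
    expect_equal(predict_edges(g, back)$probability,
                 predict_edges(g, m)$probability)
  }
})

test_that("class-noise augmentation changes training but not determinism", {
  graphs <- lapply(1:2, small_labelled_graph)
  m <- sage_model(hidden = 8, seed = 3)
  conf <- detector_noise_config()$confusion
  cfg <- train_config(epochs = 2L, seed = 5, augment_confusion = conf)
  fa <- train_gnn(graphs[1], graphs[2], m, cfg)
  fb <- train_gnn(graphs[1], graphs[2], m, cfg)
  expect_identical(fa$model$layers, fb$model$layers)
  plain <- train_gnn(graphs[1], graphs[2], m,
                     train_config(epochs = 2L, seed = 5))
  expect_false(identical(fa$model$layers, plain$model$layers))
})
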