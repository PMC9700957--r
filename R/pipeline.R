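# End-to-end synthetic benchmark: generate tiles, build and label graphs,
# train the edge classifier, evaluate on clean and detector-corrupted input.

#' Run the full synthetic pipeline experiment
#'
#' Generates a set of synthetic mucosa tiles, builds ground-truth labelled
#' cell-graphs, trains the GraphSage edge classifier on the training tiles
#' (monitoring the validation tiles), and evaluates held-out crossing-edge
#' performance twice: on the clean test tiles, and on test tiles passed
#' through the stage-1 detector-noise simulator (graph rebuilt from the
#' corrupted detections, ground truth relabelled from the unchanged BM
#' annotation, mirroring full-pipeline evaluation against expert splines).
#'
#' @param n_train,n_val,n_test Number of tiles per partition (defaults
#'   8/2/4).
#' @param sim_config A [tissue_sim_config()].
#' @param noise A [detector_noise_config()] for the corrupted evaluation, or
#'   `NULL` to skip it.
#' @param build A [graph_build_config()].
#' @param model A [sage_model()] template; its weights are re-initialized
#'   from the experiment seed.
#' @param config A [train_config()]; its seed is re-derived from the
#'   experiment seed.
#' @param augment If `TRUE` (default) and `config$augment_confusion` is
#'   unset, training simulates stage-1 misclassification by resampling node
#'   classes from `noise$confusion` each epoch (see [train_config()]); the
#'   evaluation itself is unchanged.
#' @param seed Master seed for the whole experiment.
#' @return List with elements `f1_clean`, `f1_corrupt`, `report_clean`,
#'   `report_corrupt` ([classification_report()] objects over the edge
#'   classes), `ap_clean` (average precision of the crossing class),
#'   `history`, `model`, `crossing_fraction` (of training edges) and
#'   `n_edges_train`.
#' @export
evaluate_pipeline <- function(n_train = 8L, n_val = 2L, n_test = 4L,
                              sim_config = tissue_sim_config(),
                              noise = detector_noise_config(),
                              build = graph_build_config(),
                              model = sage_model(),
                              config = train_config(),
                              augment = TRUE,
                              seed = 1L) {
  n_tiles <- n_train + n_val + n_test
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      n_tiles + 2L + n_test))
  tile_seeds <- seeds[seq_len(n_tiles)]
  model_seed <- seeds[n_tiles + 1L]
  train_seed <- seeds[n_tiles + 2L]
  corrupt_seeds <- seeds[n_tiles + 2L + seq_len(n_test)]

  tiles <- lapply(tile_seeds, function(s) generate_tissue(sim_config, seed = s))
  graphs <- lapply(tiles, function(t) {
    label_ground_truth_edges(build_cell_graph(t, build), t$bm)
  })
  idx_train <- seq_len(n_train)
  idx_val <- n_train + seq_len(n_val)
  idx_test <- n_train + n_val + seq_len(n_test)

  model <- sage_model(hidden = model$meta$hidden,
                      layers = model$meta$n_layers,
                      sample_size = model$meta$sample_size,
                      normalize = model$meta$normalize,
                      dropout = model$meta$dropout,
                      head = model$meta$head_type,
                      input_dim = model$meta$input_dim,
                      seed = model_seed)
  config$seed <- train_seed
  if (augment && is.null(config$augment_confusion) && !is.null(noise)) {
    config$augment_confusion <- noise$confusion
  }
  fit <- train_gnn(graphs[idx_train], graphs[idx_val], model, config)

  eval_graphs <- function(gs) {
    truth <- unlist(lapply(gs, function(g) g$edges$crossing))
    preds <- lapply(gs, predict_edges, model = fit$model,
                    threshold = config$threshold)
    pred <- unlist(lapply(preds, function(p) p$crossing))
    prob <- unlist(lapply(preds, function(p) p$probability))
    lab <- function(x) ifelse(x, "crossing", "non_crossing")
    report <- classification_report(confusion_counts(
      lab(truth), lab(pred), classes = c("non_crossing", "crossing")))
    ap <- if (any(truth)) average_precision(prob, truth) else NA_real_
    list(report = report, ap = ap,
         f1 = report$per_class$f1[report$per_class$class == "crossing"])
  }

  clean <- eval_graphs(graphs[idx_test])
  corrupt <- NULL
  if (!is.null(noise)) {
    corrupted_graphs <- lapply(seq_len(n_test), function(i) {
      ct <- corrupt_detections(tiles[[idx_test[i]]], noise,
                               seed = corrupt_seeds[i])
      label_ground_truth_edges(build_cell_graph(ct, build), ct$bm)
    })
    corrupt <- eval_graphs(corrupted_graphs)
  }

  y_train <- unlist(lapply(graphs[idx_train], function(g) g$edges$crossing))
  list(
    f1_clean = clean$f1,
    f1_corrupt = if (is.null(corrupt)) NA_real_ else corrupt$f1,
    report_clean = clean$report,
    report_corrupt = if (is.null(corrupt)) NULL else corrupt$report,
    ap_clean = clean$ap,
    history = fit$history,
    model = fit$model,
    crossing_fraction = mean(y_train),
    n_edges_train = length(y_train)
  )
}
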