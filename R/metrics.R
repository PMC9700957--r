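# Evaluation metrics: per-class precision/recall/F1/support, accuracy,
# average precision and detection matching.

#' One-vs-rest confusion counts
#'
#' For each class, TP/FP/TN/FN counts of the one-vs-rest binary problem;
#' support is TP + FN.
#'
#' @param y_true,y_pred Equal-length label vectors over `classes`.
#' @param classes Class vocabulary; defaults to the union of observed labels.
#' @return Data frame with one row per class and columns `class`, `tp`,
#'   `fp`, `tn`, `fn`, `support`.
#' @export
confusion_counts <- function(y_true, y_pred,
                             classes = sort(unique(c(y_true, y_pred)))) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stopf("`y_true` and `y_pred` must have equal length")
  }
  unknown <- setdiff(unique(c(y_true, y_pred)), as.character(classes))
  if (length(unknown)) stopf("unknown label '%s'", unknown[1])
  n <- length(y_true)
  rows <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    data.frame(class = cl, tp = tp, fp = fp, tn = n - tp - fp - fn, fn = fn,
               support = tp + fn, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * P * R / (P + R)`, defined as 0 when both are 0.
#'
#' @param precision,recall Values in \[0, 1\] (vectorized).
#' @return F1 score(s).
#' @export
#' @examples
#' f1_score(0.2318, 0.6288)  # 0.3387
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Overall accuracy as support-weighted recall
#'
#' For single-label classification the overall accuracy equals the
#' support-weighted mean of the per-class recalls.
#'
#' @param recalls,supports Per-class recall values and supports.
#' @return Accuracy.
#' @export
accuracy_from_recalls <- function(recalls, supports) {
  stopifnot(length(recalls) == length(supports), sum(supports) > 0)
  sum(recalls * supports) / sum(supports)
}

#' Per-class classification report
#'
#' Precision, recall, F1 and support per class plus the overall accuracy.
#' Zero-division convention: precision (or recall) is 0 when its denominator
#' is 0, and F1 is 0 when P + R = 0. Values are kept at full precision; the
#' print method rounds to 4 decimals, mirroring the usual table layout.
#'
#' @param counts Output of [confusion_counts()], or `y_true`/`y_pred` label
#'   vectors via the `...` shortcut `classification_report(truth, pred)`.
#' @param y_pred Optional: if supplied, `counts` is interpreted as `y_true`.
#' @return An object of class `metrics_report`: list with `per_class` (data
#'   frame: class, precision, recall, f1, support) and `accuracy`.
#' @export
classification_report <- function(counts, y_pred = NULL) {
  if (!is.null(y_pred)) counts <- confusion_counts(counts, y_pred)
  stopifnot(is.data.frame(counts),
            all(c("class", "tp", "fp", "fn", "support") %in% names(counts)))
  precision <- ifelse(counts$tp + counts$fp > 0,
                      counts$tp / (counts$tp + counts$fp), 0)
  recall <- ifelse(counts$tp + counts$fn > 0,
                   counts$tp / (counts$tp + counts$fn), 0)
  per_class <- data.frame(class = counts$class, precision = precision,
                          recall = recall, f1 = f1_score(precision, recall),
                          support = counts$support, stringsAsFactors = FALSE)
  accuracy <- if (sum(counts$support) > 0) {
    sum(counts$tp) / sum(counts$support)
  } else NA_real_
  structure(list(per_class = per_class, accuracy = accuracy,
                 total_support = sum(counts$support)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  df <- x$per_class
  df$precision <- round(df$precision, digits)
  df$recall <- round(df$recall, digits)
  df$f1 <- round(df$f1, digits)
  print(df, row.names = FALSE)
  cat(sprintf("Accuracy %.*f  (support %d)\n", digits, x$accuracy,
              x$total_support))
  invisible(x)
}

#' @export
format.metrics_report <- function(x, ...) {
  utils::capture.output(print(x, ...))
}

#' Average precision
#'
#' The all-points precision-recall integral: instances are ranked by
#' decreasing score (ties grouped) and AP is the sum of precision at each
#' recall step. Invariant to positive monotone transforms of the scores.
#'
#' @param scores Numeric scores (higher = more confident positive).
#' @param labels Logical (or 0/1) ground-truth labels; at least one positive
#'   is required.
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  if (n_pos == 0L) stopf("average precision is undefined without positives")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # group tied scores: evaluate P/R after each distinct-score block
  block_end <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp_cum <- cumsum(l)[block_end]
  n_cum <- block_end
  precision <- tp_cum / n_cum
  recall <- tp_cum / n_pos
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

#' Mean average precision
#'
#' Arithmetic mean of per-image average precisions.
#'
#' @param aps Numeric vector of AP values.
#' @return mAP.
#' @export
#' @examples
#' mean_ap(c(0.0881, 0.5105, 0.6466, 0.8546))  # 0.5250
mean_ap <- function(aps) {
  stopifnot(length(aps) > 0, !anyNA(aps))
  mean(aps)
}

#' Match predicted detections to ground truth
#'
#' Greedy nearest-first one-to-one matching: candidate pairs within `radius`
#' are matched in order of increasing distance, each prediction and each
#' ground-truth point used at most once. Matched predictions are TP,
#' unmatched predictions FP, unmatched ground truth FN. The default radius
#' of 16 px is half the 32-px nucleus crop.
#'
#' @param pred_points,gt_points Two-column coordinate matrices.
#' @param radius Maximum matching distance in pixels (> 0).
#' @return List with `matches` (data frame: pred, gt, distance), `tp`, `fp`,
#'   `fn`, and logical vectors `pred_matched`, `gt_matched`.
#' @export
match_detections <- function(pred_points, gt_points, radius = 16) {
  stopifnot(radius > 0)
  pred_points <- as_xy_matrix(pred_points)
  gt_points <- as_xy_matrix(gt_points)
  np <- nrow(pred_points)
  ng <- nrow(gt_points)
  pred_matched <- rep(FALSE, np)
  gt_matched <- rep(FALSE, ng)
  matches <- data.frame(pred = integer(), gt = integer(), distance = numeric())
  if (np > 0L && ng > 0L) {
    d <- sqrt(outer(pred_points[, 1], gt_points[, 1], "-")^2 +
              outer(pred_points[, 2], gt_points[, 2], "-")^2)
    cand <- which(d <= radius, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (!pred_matched[i] && !gt_matched[j]) {
          pred_matched[i] <- TRUE
          gt_matched[j] <- TRUE
          matches[nrow(matches) + 1L, ] <- list(i, j, d[i, j])
        }
      }
    }
  }
  list(matches = matches, tp = sum(pred_matched), fp = sum(!pred_matched),
       fn = sum(!gt_matched), pred_matched = pred_matched,
       gt_matched = gt_matched)
}

as_xy_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  if (is.null(p) || length(p) == 0L) return(matrix(numeric(), 0, 2))
  stopifnot(is.matrix(p), ncol(p) == 2L)
  p
}
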