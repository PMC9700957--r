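test_that("one-vs-rest confusion counts match direct counting", {
  y <- c("a", "a", "b", "b", "b", "c")
  p <- c("a", "b", "b", "b", "c", "c")
  cc <- confusion_counts(y, p, classes = c("a", "b", "c"))
  expect_identical(cc$tp, c(1L, 2L, 1L))
  expect_identical(cc$fp, c(0L, 1L, 1L))
  expect_identical(cc$fn, c(1L, 1L, 0L))
  expect_identical(cc$support, c(2L, 3L, 1L))
  expect_true(all(cc$tp + cc$fp + cc$tn + cc$fn == length(y)))

  # binary example: truth (1,1,0,...), pred (1,0,1,0,...)
  cb <- confusion_counts(c(1, 1, rep(0, 8)), c(1, 0, 1, rep(0, 7)),
                         classes = c("0", "1"))
  pos <- cb[cb$class == "1", ]
  expect_identical(c(pos$tp, pos$fn, pos$fp, pos$tn), c(1L, 1L, 1L, 7L))

  same <- confusion_counts(y, y)
  expect_true(all(same$fp == 0L & same$fn == 0L))
  expect_error(confusion_counts(y, p, classes = c("a", "b")), "unknown")
  expect_error(confusion_counts(y, p[-1]), "length")
})

test_that("report reproduces the formula arithmetic and conventions", {
  expect_equal(round(f1_score(0.2318, 0.6288), 4), 0.3387)
  expect_identical(f1_score(0, 0), 0)
  expect_identical(f1_score(0.3, 0.7), f1_score(0.7, 0.3))
  pr <- cbind(runif(20), runif(20))
  f1 <- f1_score(pr[, 1], pr[, 2])
  expect_true(all(f1 >= pmin(pr[, 1], pr[, 2]) - 1e-12 &
                  f1 <= pmax(pr[, 1], pr[, 2]) + 1e-12))

  counts <- data.frame(class = c("neg", "pos"), tp = c(6L, 2L),
                       fp = c(1L, 1L), tn = c(2L, 6L), fn = c(1L, 1L),
                       support = c(7L, 3L))
  rep_ <- classification_report(counts)
  pos <- rep_$per_class[rep_$per_class$class == "pos", ]
  expect_equal(pos$precision, 2 / 3)
  expect_equal(pos$recall, 2 / 3)
  expect_equal(pos$f1, 2 / 3)
  expect_equal(rep_$accuracy, 0.8)

  perfect <- classification_report(c("x", "y", "x"), c("x", "y", "x"))
  expect_true(all(perfect$per_class$precision == 1 &
                  perfect$per_class$recall == 1 & perfect$per_class$f1 == 1))
  expect_identical(perfect$accuracy, 1)

  # degenerate fold: no predictions of a class -> zeros, not NaN
  degen <- classification_report(c("x", "x"), c("y", "y"))
  expect_identical(degen$per_class$f1, c(0, 0))

  # accuracy identity: support-weighted mean recall
  set.seed(14)
  yt <- sample(letters[1:4], 500, replace = TRUE)
  yp <- ifelse(runif(500) < 0.3, sample(letters[1:4], 500, replace = TRUE), yt)
  r <- classification_report(yt, yp)
  expect_equal(r$accuracy,
               accuracy_from_recalls(r$per_class$recall, r$per_class$support))
  expect_equal(r$accuracy, mean(yt == yp))
})

test_that("average precision follows the all-points PR integral", {
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(average_precision(c(0.1, 0.9, 0.8), c(TRUE, FALSE, FALSE)),
               1 / 3)
  # one positive ranked last of 100
  expect_equal(average_precision(seq(1, 0.01, length.out = 100),
                                 c(rep(0, 99), 1)), 0.01)
  # invariance to positive monotone transforms
  set.seed(3)
  s <- runif(200)
  l <- runif(200) < 0.2
  expect_equal(average_precision(s, l), average_precision(exp(3 * s), l))
  expect_equal(average_precision(s, l), average_precision(rank(s), l))
  expect_error(average_precision(s, rep(FALSE, 200)), "positive")

  expect_equal(round(mean_ap(c(0.0881, 0.5105, 0.6466, 0.8546)), 4), 0.5250)
})

test_that("detection matching is greedy nearest-first and one-to-one", {
  gt <- cbind(c(0, 10, 20), c(0, 0, 0))
  expect_identical(match_detections(gt, gt)$tp, 3L)
  far <- match_detections(gt, gt + 1000)
  expect_identical(far$tp, 0L)
  expect_identical(far$fp, 3L)
  expect_identical(far$fn, 3L)

  # two predictions near one truth point: only one matches
  pred <- rbind(c(0.5, 0), c(1, 0))
  m <- match_detections(pred, cbind(0, 0), radius = 16)
  expect_identical(m$tp, 1L)
  expect_identical(m$fp, 1L)
  expect_true(m$pred_matched[1])  # the nearer one

  # exhaustive maximum one-to-one matching oracle by recursion
  max_matching <- function(d, radius) {
    np <- nrow(d); ng <- ncol(d)
    rec <- function(i, used) {
      if (i > np) return(0L)
      best <- rec(i + 1L, used)  # leave prediction i unmatched
      for (j in seq_len(ng)) {
        if (!used[j] && d[i, j] <= radius) {
          used[j] <- TRUE
          best <- max(best, 1L + rec(i + 1L, used))
          used[j] <- FALSE
        }
      }
      best
    }
    rec(1L, rep(FALSE, ng))
  }
  set.seed(21)
  for (trial in 1:15) {
    # well-separated truths with unique nearby predictions: greedy is
    # provably optimal, so it must equal the exhaustive matching
    ng <- sample(3:4, 1)
    centers <- cbind(runif(ng, 0, 500), sample(ng) * 100)
    keep <- runif(ng) < 0.7
    p <- centers[keep, , drop = FALSE] +
      matrix(runif(2 * sum(keep), -5, 5), ncol = 2)
    if (nrow(p) == 0L) p <- centers[1, , drop = FALSE] + 3
    p <- rbind(p, cbind(runif(2, 2000, 3000), runif(2, 2000, 3000)))
    d <- sqrt(outer(p[, 1], centers[, 1], "-")^2 +
              outer(p[, 2], centers[, 2], "-")^2)
    res <- match_detections(p, centers, radius = 16)
    expect_identical(res$tp, max_matching(d, 16))
    expect_identical(res$tp + res$fp, nrow(p))
    expect_identical(res$tp + res$fn, ng)
  }
  # in general, greedy never exceeds the exhaustive optimum
  for (trial in 1:10) {
    p <- cbind(runif(4, 0, 50), runif(4, 0, 50))
    g <- cbind(runif(4, 0, 50), runif(4, 0, 50))
    d <- sqrt(outer(p[, 1], g[, 1], "-")^2 + outer(p[, 2], g[, 2], "-")^2)
    expect_lte(match_detections(p, g, radius = 20)$tp, max_matching(d, 20))
  }
})
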