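test_that("BM curve is a bounded, monotone-x polyline with the right shape", {
  cfg <- tissue_sim_config()
  flat <- tissue_sim_config(bm_amplitude = 0)
  bm0 <- generate_bm_curve(flat, seed = 1)
  expect_true(all(bm0[[1]][, 2] == flat$bm_baseline))

  set.seed(42)
  for (seed in 1:100) {
    amp <- runif(1, 0, 700)
    cfg_i <- tissue_sim_config(bm_baseline = runif(1, amp + 1, 1999 - amp),
                               bm_amplitude = amp,
                               bm_wavelength = runif(1, 200, 2000))
    s <- generate_bm_curve(cfg_i, seed = seed)[[1]]
    expect_true(all(s[, 1] >= 0 & s[, 1] <= cfg_i$width))
    expect_true(all(s[, 2] > 0 & s[, 2] < cfg_i$height))
    expect_true(all(diff(s[, 1]) > 0))
  }

  # chord error of the 25-px control spacing stays below 1 px at defaults
  s <- generate_bm_curve(cfg, seed = 7)[[1]]
  mid_x <- (s[-nrow(s), 1] + s[-1, 1]) / 2
  mid_y <- (s[-nrow(s), 2] + s[-1, 2]) / 2
  true_y <- approx(seq(0, cfg$width, by = 0.5),
                   generate_bm_curve(cfg, seed = 7)[[1]][1, 2] * 0 +
                     cfg$bm_baseline + cfg$bm_amplitude *
                     sin(2 * pi * seq(0, cfg$width, by = 0.5) /
                           cfg$bm_wavelength +
                           cellgraph:::with_seed(7, runif(1, 0, 2 * pi))),
                   xout = mid_x)$y
  expect_lt(max(abs(mid_y - true_y)), 1)
})

test_that("tissue generation respects compartments, rates and bounds", {
  cfg <- small_sim_config()
  tile <- generate_tissue(cfg, seed = 2)
  expect_s3_class(tile, "tile_record")
  expect_false(is.null(tile$bm))
  expect_true(all(tile$nodes$x >= 0 & tile$nodes$x <= cfg$width))
  expect_true(all(tile$nodes$y >= 0 & tile$nodes$y <= cfg$height))

  # epithelial strictly above the curve, fibroblast/endothelial below
  curve_y <- cellgraph:::curve_height_at(tile$bm, tile$nodes$x)
  epi <- tile$nodes$cell_class == "epithelial"
  fib <- tile$nodes$cell_class == "fibroblast_endothelial"
  expect_true(all(tile$nodes$y[epi] < curve_y[epi]))
  expect_true(all(tile$nodes$y[fib] > curve_y[fib]))

  # degenerate configurations
  none <- generate_tissue(tissue_sim_config(density_epithelial = 0,
                                            density_stromal = 0,
                                            density_inflammatory = 0,
                                            density_lymphocytic = 0), seed = 1)
  expect_identical(nrow(none$nodes), 0L)
  calm <- generate_tissue(small_sim_config(inflammation = 0), seed = 1)
  expect_false(any(calm$nodes$cell_class %in%
                     c("inflammatory", "lymphocytic")))
})

test_that("mean epithelial count matches Poisson theory", {
  cfg <- small_sim_config()
  counts <- numeric(50)
  areas <- numeric(50)
  for (s in 1:50) {
    tile <- generate_tissue(cfg, seed = 1000 + s)
    counts[s] <- sum(tile$nodes$cell_class == "epithelial")
    curve <- tile$bm[[1]]
    # area above the curve by the trapezoid rule
    areas[s] <- sum(diff(curve[, 1]) *
                      (curve[-nrow(curve), 2] + curve[-1, 2]) / 2)
  }
  expected <- cfg$density_epithelial * mean(areas)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("generation is deterministic in (config, seed)", {
  cfg <- small_sim_config()
  t1 <- generate_tissue(cfg, seed = 9)
  t2 <- generate_tissue(cfg, seed = 9)
  expect_identical(t1, t2)
  expect_false(identical(t1, generate_tissue(cfg, seed = 10)))

  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_tile(t1, f1)
  write_tile(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("detector corruption follows its configuration", {
  tile <- generate_tissue(small_sim_config(), seed = 3)
  clean <- detector_noise_config(confusion = diag(4), jitter_sd = 0,
                                 miss_rate = 0, spurious_rate = 0)
  expect_identical(corrupt_detections(tile, clean, seed = 1)$nodes,
                   tile$nodes)

  gone <- detector_noise_config(miss_rate = 1, spurious_rate = 0)
  expect_false(any(corrupt_detections(tile, gone, seed = 1)$nodes$id %in%
                     tile$nodes$id))

  noisy <- detector_noise_config()
  c1 <- corrupt_detections(tile, noisy, seed = 5)
  c2 <- corrupt_detections(tile, noisy, seed = 5)
  expect_identical(c1, c2)
  expect_identical(c1$bm, tile$bm)
  expect_true(all(c1$nodes$x >= 0 & c1$nodes$x <= tile$width))
})

test_that("empirical misclassification frequencies match the confusion row", {
  # 1e4 epithelial cells through the default confusion matrix
  n <- 10000
  tile <- tile_record("conf", 1000, 1000,
                      nodes = data.frame(id = sprintf("c%05d", 1:n),
                                         x = runif(n, 0, 1000),
                                         y = runif(n, 0, 1000),
                                         cell_class = "epithelial"))
  noise <- detector_noise_config(jitter_sd = 0, miss_rate = 0,
                                 spurious_rate = 0)
  out <- corrupt_detections(tile, noise, seed = 8)
  freq <- table(factor(out$nodes$cell_class, levels = cell_classes())) / n
  row <- noise$confusion["epithelial", ]
  se <- sqrt(row * (1 - row) / n)
  expect_true(all(abs(freq - row) <= 3 * se))
})

test_that("default synthetic tiles reproduce the edge-class skew", {
  frac <- vapply(1:3, function(s) {
    g <- small_labelled_graph(seed = s)
    mean(g$edges$crossing)
  }, numeric(1))
  expect_true(all(frac > 0))
  expect_true(all(frac < 0.15))
})
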