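# Synthetic mucosa generator: annotated tiles (cells + BM curve) and a
# stage-1 detector-noise simulator, so the full pipeline is testable without
# clinical image data.

#' Configuration for the synthetic mucosa generator
#'
#' The generator emulates a 2000 x 2000 px mucosal tile: an epithelial
#' compartment above a wavy basement-membrane (BM) interface curve and a
#' stromal (lamina propria) compartment below it. Epithelial and
#' fibroblast/endothelial cells follow homogeneous Poisson point processes
#' restricted to their compartments; inflammatory and lymphocytic cells
#' concentrate around the BM (truncated-Gaussian offset from the curve),
#' mostly on the stromal side, with an `exocytosis_fraction` migrating into
#' the epithelium. Default densities give roughly 1,200 cells per tile with
#' the strong class imbalance typical of mucosal biopsies (inflammatory cells
#' rarest), and a crossing-edge fraction of a few percent in the resulting
#' ground-truth cell-graph.
#'
#' @param width,height Tile size in pixels.
#' @param bm_baseline Mean height of the BM curve in pixels (from the top).
#' @param bm_amplitude Sinusoid amplitude in pixels; must leave the curve
#'   strictly inside the tile.
#' @param bm_wavelength Sinusoid wavelength in pixels.
#' @param density_epithelial,density_stromal Poisson intensities
#'   (cells per px^2) of the two compartment processes.
#' @param density_inflammatory,density_lymphocytic Base intensities of the
#'   peri-BM processes (cells per px^2 of tile), scaled by `inflammation`.
#' @param inflammation Dimensionless multiplier (>= 0) for the inflammatory
#'   and lymphocytic intensities.
#' @param exocytosis_fraction Proportion of inflammatory-type cells placed on
#'   the epithelial side of the curve.
#' @param bm_sigma Scale (px) of the truncated-Gaussian distance from the
#'   curve used to place inflammatory-type cells.
#' @return A list of class `tissue_sim_config`.
#' @export
tissue_sim_config <- function(width = 2000, height = 2000,
                              bm_baseline = 800, bm_amplitude = 150,
                              bm_wavelength = 900,
                              density_epithelial = 3.3e-4,
                              density_stromal = 1.8e-4,
                              density_inflammatory = 9e-6,
                              density_lymphocytic = 5.7e-5,
                              inflammation = 1,
                              exocytosis_fraction = 0.1,
                              bm_sigma = 150) {
  cfg <- list(width = width, height = height, bm_baseline = bm_baseline,
              bm_amplitude = bm_amplitude, bm_wavelength = bm_wavelength,
              density_epithelial = density_epithelial,
              density_stromal = density_stromal,
              density_inflammatory = density_inflammatory,
              density_lymphocytic = density_lymphocytic,
              inflammation = inflammation,
              exocytosis_fraction = exocytosis_fraction,
              bm_sigma = bm_sigma)
  dens <- c(cfg$density_epithelial, cfg$density_stromal,
            cfg$density_inflammatory, cfg$density_lymphocytic)
  if (any(dens < 0)) stopf("densities must be non-negative")
  if (cfg$inflammation < 0) stopf("`inflammation` must be >= 0")
  if (cfg$exocytosis_fraction < 0 || cfg$exocytosis_fraction > 1) {
    stopf("`exocytosis_fraction` must be in [0, 1]")
  }
  if (cfg$bm_amplitude < 0 || cfg$bm_amplitude >= cfg$bm_baseline ||
      cfg$bm_amplitude >= cfg$height - cfg$bm_baseline) {
    stopf("`bm_amplitude` must keep the curve strictly inside the tile")
  }
  if (cfg$bm_wavelength <= 0) stopf("`bm_wavelength` must be positive")
  structure(cfg, class = "tissue_sim_config")
}

#' Configuration for the stage-1 detector-noise simulator
#'
#' Emulates the error structure of a CNN nucleus detector: per-class
#' misclassification (row-stochastic confusion matrix), isotropic Gaussian
#' localisation jitter, missed detections and spurious detections. The
#' default matches the documented corruption setting used in the robustness
#' evaluation: 20% off-diagonal confusion mass, 2 px jitter, 5% missed and
#' 5% spurious detections.
#'
#' @param confusion 4 x 4 row-stochastic matrix over [cell_classes()]; entry
#'   (i, j) is the probability that a class-i cell is reported as class j.
#' @param jitter_sd Standard deviation (px) of the coordinate jitter.
#' @param miss_rate Probability that a true cell is dropped.
#' @param spurious_rate Expected number of spurious cells as a proportion of
#'   the true cell count.
#' @return A list of class `detector_noise_config`.
#' @export
detector_noise_config <- function(confusion = NULL, jitter_sd = 2,
                                  miss_rate = 0.05, spurious_rate = 0.05) {
  k <- length(cell_classes())
  if (is.null(confusion)) {
    confusion <- matrix(0.2 / (k - 1), k, k)
    diag(confusion) <- 0.8
  }
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(k, k)) || any(confusion < 0) ||
      any(abs(rowSums(confusion) - 1) > 1e-8)) {
    stopf("`confusion` must be a %d x %d row-stochastic matrix", k, k)
  }
  dimnames(confusion) <- list(cell_classes(), cell_classes())
  if (jitter_sd < 0) stopf("`jitter_sd` must be >= 0")
  for (r in c(miss_rate, spurious_rate)) {
    if (!is_number(r) || r < 0 || r > 1) {
      stopf("rates must be in [0, 1]")
    }
  }
  structure(list(confusion = confusion, jitter_sd = jitter_sd,
                 miss_rate = miss_rate, spurious_rate = spurious_rate),
            class = "detector_noise_config")
}

#' Generate a synthetic basement-membrane curve
#'
#' A single sinusoidal polyline spanning the full tile width with control
#' points every 25 px: `y = baseline + amplitude * sin(2 * pi * x /
#' wavelength + phase)`, the phase drawn uniformly from the seed. The 25-px
#' spacing keeps the chord deviation from the smooth sinusoid below 1 px at
#' the default amplitude/wavelength.
#'
#' @param config A [tissue_sim_config()].
#' @param seed Integer seed (determines the phase).
#' @return A [bm_annotation()] with one polyline.
#' @export
generate_bm_curve <- function(config = tissue_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "tissue_sim_config"))
  phase <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  xs <- seq(0, config$width, by = 25)
  if (xs[length(xs)] < config$width) xs <- c(xs, config$width)
  ys <- config$bm_baseline +
    config$bm_amplitude * sin(2 * pi * xs / config$bm_wavelength + phase)
  bm_annotation(list(cbind(x = xs, y = ys)))
}

# Piecewise-linear interpolation of the curve height at given x.
curve_height_at <- function(bm, x) {
  s <- bm[[1]]
  stats::approx(s[, 1], s[, 2], xout = x, rule = 2)$y
}

#' Generate a synthetic annotated mucosal tile
#'
#' See [tissue_sim_config()] for the tissue model. Output is reproducible:
#' the same configuration and seed give identical tiles.
#'
#' @param config A [tissue_sim_config()].
#' @param seed Integer seed.
#' @return A [tile_record()] with cells and an attached BM annotation.
#' @export
#' @examples
#' tile <- generate_tissue(tissue_sim_config(width = 500, height = 500,
#'                                           bm_baseline = 250,
#'                                           bm_amplitude = 50), seed = 7)
generate_tissue <- function(config = tissue_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "tissue_sim_config"))
  bm <- generate_bm_curve(config, seed = seed)
  W <- config$width
  H <- config$height
  with_seed(seed + 1L, {
    # Homogeneous Poisson processes over the tile, restricted by compartment.
    sample_compartment <- function(density, side) {
      n <- stats::rpois(1, density * W * H)
      if (n == 0L) return(cbind(x = numeric(), y = numeric()))
      x <- stats::runif(n, 0, W)
      y <- stats::runif(n, 0, H)
      keep <- if (side == "above") y < curve_height_at(bm, x)
              else y > curve_height_at(bm, x)
      cbind(x = x[keep], y = y[keep])
    }
    epi <- sample_compartment(config$density_epithelial, "above")
    str <- sample_compartment(config$density_stromal, "below")

    # Peri-BM inflammatory-type cells: truncated-Gaussian offset from the
    # curve, stromal side except for the exocytosis fraction.
    sample_peri_bm <- function(density) {
      n <- stats::rpois(1, density * config$inflammation * W * H)
      if (n == 0L) return(cbind(x = numeric(), y = numeric()))
      x <- stats::runif(n, 0, W)
      above <- stats::runif(n) < config$exocytosis_fraction
      yc <- curve_height_at(bm, x)
      lim <- ifelse(above, yc, H - yc)  # room available on the chosen side
      off <- abs(stats::rnorm(n, 0, config$bm_sigma))
      redo <- off >= lim
      for (i in which(redo)) {
        for (tries in 1:20) {
          off[i] <- abs(stats::rnorm(1, 0, config$bm_sigma))
          if (off[i] < lim[i]) break
        }
        if (off[i] >= lim[i]) off[i] <- stats::runif(1, 0, lim[i])
      }
      y <- ifelse(above, yc - off, yc + off)
      cbind(x = x, y = y)
    }
    infl <- sample_peri_bm(config$density_inflammatory)
    lymph <- sample_peri_bm(config$density_lymphocytic)

    pts <- rbind(epi, str, infl, lymph)
    cls <- rep(cell_classes(), times = c(nrow(epi), nrow(str),
                                         nrow(infl), nrow(lymph)))
    nodes <- if (nrow(pts) == 0L) NULL else
      data.frame(id = sprintf("c%04d", seq_len(nrow(pts))),
                 x = pts[, 1], y = pts[, 2], cell_class = cls,
                 stringsAsFactors = FALSE)
    tile_record(tile_id = sprintf("sim-%d", seed), width = W, height = H,
                nodes = nodes, bm = bm)
  })
}

#' Simulate stage-1 detector errors on an annotated tile
#'
#' Each cell is independently dropped with probability `miss_rate`;
#' surviving cells have their class resampled from the corresponding
#' confusion-matrix row and their position jittered by an isotropic Gaussian
#' (clamped to the tile bounds). Spurious cells are added as a Poisson count
#' with mean `spurious_rate * n`, uniform in position and class. The BM
#' annotation is left untouched. With an identity confusion matrix, zero
#' jitter and zero rates the tile is returned unchanged.
#'
#' @param tile A [tile_record()].
#' @param noise A [detector_noise_config()].
#' @param seed Integer seed.
#' @return A corrupted [tile_record()].
#' @export
corrupt_detections <- function(tile, noise = detector_noise_config(),
                               seed = 1L) {
  stopifnot(inherits(tile, "tile_record"),
            inherits(noise, "detector_noise_config"))
  nodes <- tile$nodes
  n0 <- nrow(nodes)
  with_seed(seed, {
    if (n0 > 0L) {
      if (noise$miss_rate > 0) {
        nodes <- nodes[stats::runif(n0) >= noise$miss_rate, , drop = FALSE]
      }
      n <- nrow(nodes)
      if (n > 0L) {
        cls_idx <- match(nodes$cell_class, cell_classes())
        identity_conf <- all(diag(noise$confusion) == 1)
        if (!identity_conf) {
          u <- stats::runif(n)
          cum <- t(apply(noise$confusion, 1, cumsum))
          new_idx <- integer(n)
          for (i in seq_len(n)) {
            new_idx[i] <- which(u[i] <= cum[cls_idx[i], ])[1]
          }
          nodes$cell_class <- cell_classes()[new_idx]
        }
        if (noise$jitter_sd > 0) {
          nodes$x <- clamp(nodes$x + stats::rnorm(n, 0, noise$jitter_sd),
                           0, tile$width)
          nodes$y <- clamp(nodes$y + stats::rnorm(n, 0, noise$jitter_sd),
                           0, tile$height)
        }
      }
    }
    n_sp <- if (noise$spurious_rate > 0 && n0 > 0L) {
      stats::rpois(1, noise$spurious_rate * n0)
    } else 0L
    if (n_sp > 0L) {
      sp_ids <- sprintf("sp%04d", seq_len(n_sp))
      while (any(sp_ids %in% nodes$id)) sp_ids <- paste0(sp_ids, "x")
      sp <- data.frame(
        id = sp_ids,
        x = stats::runif(n_sp, 0, tile$width),
        y = stats::runif(n_sp, 0, tile$height),
        cell_class = sample(cell_classes(), n_sp, replace = TRUE),
        stringsAsFactors = FALSE
      )
      nodes <- rbind(nodes, sp)
    }
    rownames(nodes) <- NULL
    tile_record(tile$tile_id, tile$width, tile$height, nodes = nodes,
                bm = tile$bm, scale = tile$scale)
  })
}
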