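# Independent oracles and small fixtures shared across test files.

# Poisson log-likelihood (kernel) of the 4-parameter before/after model,
# maximised by an iterated coarse-to-fine grid search; independent of the
# IRLS path under test.
grid_search_trend <- function(counts, fire_year,
                              center = c(2, 0, 0, 0),
                              half = c(2, 1, 2, 1),
                              n_grid = 7, rounds = 16) {
  x1 <- counts$year - fire_year
  x2 <- as.numeric(counts$year >= fire_year)
  X <- cbind(1, x1, x2, x1 * x2)
  y <- counts$males
  best <- center
  for (r in seq_len(rounds)) {
    g <- as.matrix(expand.grid(lapply(1:4, function(j)
      seq(best[j] - half[j], best[j] + half[j], length.out = n_grid))))
    eta <- g %*% t(X)
    score <- eta %*% y - rowSums(exp(eta))
    best <- g[which.max(score), ]
    half <- half * 2 / (n_grid - 1)
  }
  unname(best)
}

# brute-force per-cell covariate extraction (mirrors the documented rules
# with explicit loops; no shared code with extract_covariates)
brute_force_covariates <- function(lek_xy, surfaces, r) {
  g <- surfaces$elevation
  heights <- c(); unsuit <- c(); elevs <- c()
  n_keep <- 0; height_sum <- 0
  ymax <- g$ymin + nrow(g$values) * g$cell_size
  for (row in seq_len(nrow(g$values))) {
    for (col in seq_len(ncol(g$values))) {
      cx <- g$xmin + (col - 0.5) * g$cell_size
      cy <- ymax - (row - 0.5) * g$cell_size
      if (sqrt((cx - lek_xy[1])^2 + (cy - lek_xy[2])^2) > r) next
      elevs <- c(elevs, surfaces$elevation$values[row, col])
      unsuit <- c(unsuit, surfaces$cheat_unsuitable$values[row, col])
      if (!surfaces$burned$values[row, col] &&
          surfaces$sagebrush$values[row, col]) {
        n_keep <- n_keep + 1
        height_sum <- height_sum + surfaces$height_m$values[row, col]
      }
    }
  }
  c(veg_height = if (n_keep > 0) height_sum / n_keep else 0,
    cheat_frac = mean(unsuit),
    elevation = mean(elevs),
    n_cells = length(elevs))
}

# a tiny square perimeter polygon (counter-clockwise)
square_poly <- function(x0, y0, side) {
  cbind(x = c(x0, x0 + side, x0 + side, x0),
        y = c(y0, y0, y0 + side, y0 + side))
}

# hand-built toy surfaces on an n x n grid at 30 m for oracle comparisons
toy_surfaces <- function(n = 10, cell = 30, burned, height_class, veg_type,
                         elevation, cheat_cover) {
  mk <- function(v) raster_grid(v, 0, 0, cell)
  burned_g <- mk(burned)
  list(burned = burned_g,
       height_m = postfire_height(mk(height_class), mk(veg_type), burned_g),
       cheat_unsuitable = postfire_cheatgrass(mk(cheat_cover), burned_g,
                                              mk(elevation)),
       elevation = mk(elevation),
       sagebrush = mk(veg_type == VEG_CODES[["sagebrush"]]),
       fire_year = 2005)
}

# small pipeline fixture: 12 leks, 2 fires, reduced radii so the habitat
# discs fit an 18 km landscape
fixture_pipeline_config <- function(seed = 42L) {
  pipeline_config(
    synthetic = list(extent_m = c(18000, 18000), n_fires = 2,
                     fire_radius_range_m = c(900, 1600),
                     fire_year_range = c(2002, 2010),
                     n_leks = c(unburned_island = 3, fire_perimeter = 3,
                                small_buffer = 3, large_buffer = 2,
                                outside = 1),
                     survey_prob = 0.9,
                     region_inset_m = 2500),
    thresholds = list(radii_m = c(400, 800, 2400)),
    rng_seed = seed)
}
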