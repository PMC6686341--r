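#' Fire category levels
#'
#' The four fire-context categories a lek can fall in, plus `"outside"` for
#' leks farther than the large-buffer limit (excluded from analysis):
#' `unburned_island` (inside an unburned island, or within 50 m of an island
#' or fire-perimeter edge), `fire_perimeter` (inside the burned area),
#' `small_buffer` (50 m to 1.5 km outside a perimeter), `large_buffer`
#' (1.5 to 6.4 km; the control group).
#' @export
FIRE_CATEGORIES <- c("unburned_island", "fire_perimeter",
                     "small_buffer", "large_buffer", "outside")

#' Vegetation type codes used by the synthetic landscape
#'
#' 1 = sagebrush, 2 = grassland, 3 = conifer forest, 4 = juniper woodland.
#' Forest and juniper are unsuitable types whose vegetation height is zeroed
#' in the postfire habitat surfaces.
#' @export
VEG_CODES <- c(sagebrush = 1, grassland = 2, forest = 3, juniper = 4)

#' Configuration of a synthetic fire-mosaic landscape
#'
#' Defines the study conditions for the simulated landscape: a rectangular
#' planar extent gridded at 30 m (vegetation, elevation, burn mosaic) and
#' 250 m (cheatgrass cover), a set of blob-shaped fire perimeters each
#' containing unburned islands, and the year spans of the fire record and the
#' lek-count record.
#'
#' Per-fire unburned-island fractions are drawn from a lognormal distribution
#' (median 8.3\%, mean roughly 10\%) truncated to `unburned_fraction_range`;
#' a degenerate range `c(a, a)` forces every fire to fraction `a` exactly.
#'
#' @param extent_m width and height of the landscape in metres (must be whole
#'   multiples of both cell sizes).
#' @param cell_size_m fine-grid resolution (m); default 30.
#' @param cheat_cell_size_m cheatgrass-cover grid resolution (m); default 250.
#' @param n_fires number of fires to place.
#' @param unburned_fraction_range admissible range of the per-fire island
#'   fraction, within `[0, 1]`.
#' @param fire_radius_range_m range of fire base radii (m).
#' @param elevation_range_m landscape elevation range (m a.s.l.).
#' @param years inclusive span of the fire record.
#' @param fire_year_range inclusive span from which fire years are drawn
#'   (within `years`).
#' @param count_years inclusive span of the lek-count record.
#' @param layer_years years for which time-specific vegetation layers exist;
#'   leks burned outside this window are dropped from habitat analysis.
#' @param rng_seed integer seed; every stochastic step in
#'   [generate_landscape()] and [simulate_study()] flows from it.
#' @return A validated list of class `landscape_config`.
#' @export
landscape_config <- function(extent_m = c(51000, 51000),
                             cell_size_m = 30,
                             cheat_cell_size_m = 250,
                             n_fires = 10,
                             unburned_fraction_range = c(0.02, 0.78),
                             fire_radius_range_m = c(1500, 6000),
                             elevation_range_m = c(1120, 2750),
                             years = c(1984, 2014),
                             fire_year_range = c(1995, 2013),
                             count_years = c(1984, 2017),
                             layer_years = 2001:2013,
                             rng_seed = 1L) {
  cfg <- list(extent_m = as.numeric(extent_m),
              cell_size_m = cell_size_m,
              cheat_cell_size_m = cheat_cell_size_m,
              n_fires = as.integer(n_fires),
              unburned_fraction_range = as.numeric(unburned_fraction_range),
              fire_radius_range_m = as.numeric(fire_radius_range_m),
              elevation_range_m = as.numeric(elevation_range_m),
              years = as.integer(years),
              fire_year_range = as.integer(fire_year_range),
              count_years = as.integer(count_years),
              layer_years = as.integer(layer_years),
              rng_seed = as.integer(rng_seed))
  validate_landscape_config(cfg)
  class(cfg) <- "landscape_config"
  cfg
}

validate_landscape_config <- function(cfg) {
  if (length(cfg$extent_m) != 2 || any(cfg$extent_m <= 0))
    stop("extent_m must be two positive numbers (width, height)")
  for (cs in c(cfg$cell_size_m, cfg$cheat_cell_size_m)) {
    if (cs <= 0) stop("cell sizes must be positive")
    if (any(abs(cfg$extent_m / cs - round(cfg$extent_m / cs)) > 1e-9))
      stop("extent_m must divide into whole cells at every resolution")
  }
  if (cfg$n_fires < 0) stop("n_fires must be >= 0")
  ufr <- cfg$unburned_fraction_range
  if (length(ufr) != 2 || any(ufr < 0) || any(ufr > 1) || ufr[1] > ufr[2])
    stop("unburned_fraction_range must be an ordered pair within [0, 1]")
  if (diff(cfg$years) < 1) stop("the fire-record span must cover >= 2 years")
  if (cfg$fire_year_range[1] < cfg$years[1] ||
      cfg$fire_year_range[2] > cfg$years[2])
    stop("fire_year_range must lie within 'years'")
  invisible(cfg)
}

# Smooth Gaussian noise field: white noise on a coarse lattice, bilinearly
# interpolated to the fine grid. 'scale' is the correlation length in cells.
smooth_noise_field <- function(nr, nc, scale) {
  cr <- ceiling(nr / scale) + 2L
  cc <- ceiling(nc / scale) + 2L
  z <- matrix(stats::rnorm(cr * cc), cr, cc)
  ri <- (seq_len(nr) - 0.5) / scale + 1
  ci <- (seq_len(nc) - 0.5) / scale + 1
  r0 <- pmin(floor(ri), cr - 1L); c0 <- pmin(floor(ci), cc - 1L)
  fr <- ri - r0; fc <- ci - c0
  z[r0, c0] * outer(1 - fr, 1 - fc) +
    z[r0 + 1L, c0] * outer(fr, 1 - fc) +
    z[r0, c0 + 1L] * outer(1 - fr, fc) +
    z[r0 + 1L, c0 + 1L] * outer(fr, fc)
}

# Blob-shaped simple polygon around a centre: radius modulated by a few
# random Fourier harmonics, exponentiated to stay positive.
blob_polygon <- function(cx, cy, radius, n_vertices = 96L, n_harmonics = 5L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  s <- numeric(n_vertices)
  for (h in seq_len(n_harmonics)) {
    a <- stats::rnorm(1, 0, 0.25 / h)
    phi <- stats::runif(1, 0, 2 * pi)
    s <- s + a * cos(h * theta + phi)
  }
  r <- radius * exp(pmin(pmax(s, -0.9), 0.9))
  cbind(x = cx + r * cos(theta), y = cy + r * sin(theta))
}

# draw one per-fire island fraction (truncated lognormal; see vignette)
draw_island_fraction <- function(range, meanlog = log(0.083), sdlog = 0.6) {
  if (range[1] == range[2]) return(range[1])
  repeat {
    f <- stats::rlnorm(1, meanlog, sdlog)
    if (f >= range[1] && f <= range[2]) return(f)
  }
}

#' Generate a synthetic fire-mosaic landscape
#'
#' Builds the full raster stack and fire history with known ground truth:
#' blob-shaped fire perimeters (vector polygons with a fire year), a burn-year
#' raster holding the most recent burn year of each burned cell (unburned
#' islands and land outside perimeters are nodata), an unburned-island mask
#' confined to perimeter interiors, vegetation type and 0.5 m height-class
#' rasters, a smooth elevation field, and a coarse cheatgrass-cover raster
#' whose cover declines with elevation. Island cells are the highest-ranking
#' cells of a smooth within-perimeter noise field, so the achieved island
#' fraction matches the drawn target up to cell rounding.
#'
#' @param config a [landscape_config()].
#' @param seed integer seed (default `config$rng_seed`); pass `NULL` to use
#'   the caller's RNG state unchanged.
#' @return An object of class `lek_landscape`: list with [raster_grid()]
#'   layers `burn_year`, `island`, `veg_type`, `height_class`, `elevation`,
#'   `cheat_cover` (coarse grid), a `perimeters` list (each with `coords`,
#'   `fire_year`, `n_cells`, `n_island`, `island_fraction`), and `config`.
#' @export
generate_landscape <- function(config, seed = config$rng_seed) {
  validate_landscape_config(config)
  if (!is.null(seed)) set.seed(seed)
  cs <- config$cell_size_m
  nc <- as.integer(round(config$extent_m[1] / cs))
  nr <- as.integer(round(config$extent_m[2] / cs))

  ## elevation: random-direction gradient plus large-scale relief, rescaled
  ## exactly onto the configured range
  xs <- (seq_len(nc) - 0.5) / nc
  ys <- (seq_len(nr) - 0.5) / nr
  ang <- stats::runif(1, 0, 2 * pi)
  grad <- outer(ys, xs, function(y, x) cos(ang) * x + sin(ang) * y)
  ## regional gradient plus mesoscale relief (roughly quarter- and
  ## twelfth-extent wavelengths) so that interior leks span a wide
  ## elevation band rather than sitting on one contour
  relief <- 0.5 * grad +
    smooth_noise_field(nr, nc, scale = max(nr, 8) / 4) +
    0.25 * smooth_noise_field(nr, nc, scale = max(nr, 8) / 12)
  er <- config$elevation_range_m
  relief <- (relief - min(relief)) / max(diff(range(relief)), 1e-12)
  elevation <- raster_grid(er[1] + relief * diff(er), 0, 0, cs)

  ## fires: vector blob perimeters rasterised by cell-centre containment;
  ## overlapping burns keep the most recent year per cell
  burn <- matrix(NA_real_, nr, nc)
  island <- matrix(FALSE, nr, nc)
  perimeters <- list()
  if (config$n_fires > 0) {
    col_x <- grid_col_x(elevation)
    row_y <- grid_row_y(elevation)
    inset <- 0.32
    fyr <- config$fire_year_range
    for (i in seq_len(config$n_fires)) {
      cx <- stats::runif(1, config$extent_m[1] * inset,
                         config$extent_m[1] * (1 - inset))
      cy <- stats::runif(1, config$extent_m[2] * inset,
                         config$extent_m[2] * (1 - inset))
      radius <- stats::runif(1, config$fire_radius_range_m[1],
                             config$fire_radius_range_m[2])
      poly <- blob_polygon(cx, cy, radius)
      year <- if (fyr[1] == fyr[2]) fyr[1] else sample(fyr[1]:fyr[2], 1)
      cols <- which(col_x >= min(poly[, 1]) & col_x <= max(poly[, 1]))
      rows <- which(row_y >= min(poly[, 2]) & row_y <= max(poly[, 2]))
      if (!length(cols) || !length(rows)) next
      pts <- cbind(rep(col_x[cols], each = length(rows)),
                   rep(row_y[rows], times = length(cols)))
      inside <- matrix(points_in_polygon(pts, poly),
                       nrow = length(rows), ncol = length(cols))
      sub_r <- rep(rows, times = length(cols))[inside]
      sub_c <- rep(cols, each = length(rows))[inside]
      idx <- cbind(sub_r, sub_c)
      n_cells <- nrow(idx)
      if (n_cells == 0) next
      ## unburned islands: top-f fraction of a smooth noise field ranked
      ## within this fire's interior
      f <- draw_island_fraction(config$unburned_fraction_range)
      noise <- smooth_noise_field(length(rows), length(cols),
                                  scale = max(4, radius / cs / 6))
      vals <- noise[cbind(match(sub_r, rows), match(sub_c, cols))]
      n_isl <- round(f * n_cells)
      isl <- logical(n_cells)
      if (n_isl > 0) isl[order(vals, decreasing = TRUE)[seq_len(n_isl)]] <- TRUE
      ## most-recent-burn-wins for burned (non-island) cells
      burned_idx <- idx[!isl, , drop = FALSE]
      old <- burn[burned_idx]
      upd <- is.na(old) | old < year
      burn[burned_idx[upd, , drop = FALSE]] <- year
      island[idx[isl, , drop = FALSE]] <- TRUE
      perimeters[[length(perimeters) + 1L]] <-
        list(coords = poly, fire_year = year, n_cells = n_cells,
             n_island = n_isl, island_fraction = n_isl / n_cells)
    }
    ## islands never carry a burn year; a later overlapping fire may re-burn
    ## an earlier fire's island, in which case it stops being an island
    island[!is.na(burn)] <- FALSE
    burn[island] <- NA_real_
  }

  ## vegetation type: sagebrush matrix with forest/juniper at high elevation
  ## and scattered grassland patches
  elev_norm <- (elevation$values - er[1]) / max(diff(er), 1e-12)
  fn <- smooth_noise_field(nr, nc, scale = max(nr, 8) / 6)
  gn <- smooth_noise_field(nr, nc, scale = max(nr, 8) / 10)
  veg <- matrix(VEG_CODES[["sagebrush"]], nr, nc)
  veg[gn > 1.2] <- VEG_CODES[["grassland"]]
  veg[elev_norm > 0.65 & fn > 0.9] <- VEG_CODES[["juniper"]]
  veg[elev_norm > 0.80 & fn > 0.2] <- VEG_CODES[["forest"]]

  ## height classes: 0.5 m bins, class c spans ((c-1)/2, c/2] m, class 7 is
  ## the open-top ">3 m" class; shrubs sit in classes 1-4, trees higher
  hn <- smooth_noise_field(nr, nc, scale = max(nr, 8) / 8)
  hclass <- pmin(pmax(round(2.5 + 1.2 * hn), 1), 4)
  tall <- veg == VEG_CODES[["forest"]] | veg == VEG_CODES[["juniper"]]
  hclass[tall] <- pmin(pmax(round(6 + hn[tall]), 5), 7)

  ## cheatgrass cover (coarse grid): logistic decline with elevation
  ccs <- config$cheat_cell_size_m
  cnc <- as.integer(round(config$extent_m[1] / ccs))
  cnr <- as.integer(round(config$extent_m[2] / ccs))
  cheat_template <- raster_grid(matrix(0, cnr, cnc), 0, 0, ccs)
  elev_coarse <- resample_nearest(elevation, cheat_template)
  cn <- smooth_noise_field(cnr, cnc, scale = max(cnr, 4) / 12)
  lin <- -1.9 - 2.2 * (elev_coarse$values - 1800) / 400 + 1.8 * cn
  cheat <- raster_grid(100 * stats::plogis(lin), 0, 0, ccs)

  structure(list(
    burn_year = raster_grid(burn, 0, 0, cs),
    island = raster_grid(island, 0, 0, cs),
    veg_type = raster_grid(veg, 0, 0, cs),
    height_class = raster_grid(hclass, 0, 0, cs),
    elevation = elevation,
    cheat_cover = cheat,
    perimeters = perimeters,
    config = config), class = "lek_landscape")
}

#' @export
print.lek_landscape <- function(x, ...) {
  n_cells <- length(x$burn_year$values)
  n_burn <- sum(!is.na(x$burn_year$values))
  n_isl <- sum(x$island$values)
  cat(sprintf("lek_landscape: %g x %g km at %g m, %d fire(s)\n",
              x$config$extent_m[1] / 1000, x$config$extent_m[2] / 1000,
              x$config$cell_size_m, length(x$perimeters)))
  cat(sprintf("  burned: %.1f%% of landscape; islands: %.1f%% of perimeter area\n",
              100 * n_burn / n_cells,
              if (n_burn + n_isl > 0) 100 * n_isl / (n_burn + n_isl) else 0))
  invisible(x)
}

#' Achieved unburned-island fraction per fire
#'
#' @param landscape a [generate_landscape()] result.
#' @return Numeric vector: island cells / perimeter-interior cells per fire.
#' @export
island_fractions <- function(landscape) {
  vapply(landscape$perimeters, function(p) p$island_fraction, numeric(1))
}
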