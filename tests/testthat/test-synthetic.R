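small_cfg <- function(n_fires = 1, ...) {
  landscape_config(extent_m = c(9000, 9000), n_fires = n_fires,
                   fire_radius_range_m = c(1200, 2000), ...)
}

test_that("a landscape without fires has no burned cells and no islands", {
  land <- generate_landscape(small_cfg(n_fires = 0), seed = 3)
  expect_true(all(is.na(land$burn_year$values)))
  expect_false(any(land$island$values))
  expect_length(land$perimeters, 0)
})

test_that("island cells stay inside perimeters and never carry a burn year", {
  for (seed in 1:3) {
    land <- generate_landscape(small_cfg(n_fires = 2), seed = seed)
    isl <- land$island$values
    expect_false(any(isl & !is.na(land$burn_year$values)))
    # every island cell lies inside at least one perimeter polygon
    idx <- which(isl, arr.ind = TRUE)
    if (nrow(idx)) {
      pts <- cbind(grid_col_x(land$island)[idx[, 2]],
                   grid_row_y(land$island)[idx[, 1]])
      inside <- Reduce(`|`, lapply(land$perimeters, function(p)
        lekfire:::points_in_polygon(pts, p$coords)))
      expect_true(all(inside))
    }
  }
})

test_that("a degenerate 10% island-fraction range is achieved within 2 points", {
  fr <- vapply(1:10, function(seed) {
    land <- generate_landscape(
      small_cfg(unburned_fraction_range = c(0.10, 0.10)), seed = seed)
    mean(island_fractions(land))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.10), 0.02)
  # and the per-fire target is hit almost exactly (cell rounding only)
  expect_true(all(abs(fr - 0.10) < 0.02))
})

test_that("the same seed reproduces the landscape bit for bit", {
  a <- generate_landscape(small_cfg(), seed = 11)
  b <- generate_landscape(small_cfg(), seed = 11)
  expect_identical(a$burn_year$values, b$burn_year$values)
  expect_identical(a$island$values, b$island$values)
  expect_identical(a$elevation$values, b$elevation$values)
  expect_identical(lapply(a$perimeters, `[[`, "coords"),
                   lapply(b$perimeters, `[[`, "coords"))
})

test_that("landscape configuration rejects impossible inputs", {
  expect_error(landscape_config(extent_m = c(0, 9000)), "positive")
  expect_error(landscape_config(n_fires = -1), "n_fires")
  expect_error(landscape_config(unburned_fraction_range = c(0.5, 1.2)),
               "within \\[0, 1\\]")
  expect_error(landscape_config(extent_m = c(9010, 9000)), "whole cells")
})

test_that("simulated counts follow the before/after log-linear Poisson model", {
  set.seed(42)
  # constant rate: mean of many draws near exp(beta0)
  cnt <- simulate_lek_counts(log(50), 0, 0, 0, fire_year = 2000,
                             survey_years = rep(1981:2010, length.out = 30))
  many <- replicate(400, sum(simulate_lek_counts(log(50), 0, 0, 0, 2000,
                                                 1986:2010)$males))
  expect_lt(abs(mean(many) / 25 - 50), 1)

  # direct evaluation of the linear predictor four years after fire
  set.seed(1)
  draws <- replicate(4000, simulate_lek_counts(3, 0.05, -1, -0.2,
                                               fire_year = 0,
                                               survey_years = 4)$males)
  mu <- exp(3 + 0.05 * 4 - 1 - 0.2 * 4)
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(mu / 4000))

  # dispersion: variance/mean ratio compatible with Poisson
  set.seed(2)
  y <- replicate(2000, simulate_lek_counts(log(30), 0, 0, 0, 2000,
                                           1999)$males)
  ratio <- var(y) / mean(y)
  se <- sqrt(2 / (length(y) - 1))
  expect_lt(abs(ratio - 1), 3 * se)
})

test_that("count simulation refuses an exploding linear predictor", {
  expect_error(simulate_lek_counts(log(30), 2, 0, 0, fire_year = 2000,
                                   survey_years = 1950:2010),
               "linear predictor out of range")
})

test_that("a slope change cancelling the prefire slope flattens the postfire mean", {
  set.seed(8)
  cnt <- simulate_lek_counts(log(200), 0.15, 0, -0.15, fire_year = 0,
                             survey_years = c(0, 20))
  # expected log-mean identical at both postfire years
  expect_lt(abs(log(cnt$males[2] / cnt$males[1])), 0.3)
  fits <- replicate(300, {
    d <- simulate_lek_counts(log(100), 0.1, 0, -0.1, 0, -10:10)
    lek_trend(d, 0)$post_slope
  })
  expect_lt(abs(mean(fits)), 0.005)
})

test_that("a simulated study plants leks in every fire category", {
  cfg <- landscape_config(extent_m = c(18000, 18000), n_fires = 2,
                          fire_radius_range_m = c(900, 1600),
                          rng_seed = 5)
  study <- simulate_study(cfg, n_leks = c(unburned_island = 2,
                                          fire_perimeter = 2,
                                          small_buffer = 2, large_buffer = 2,
                                          outside = 1),
                          region_inset_m = 2500)
  expect_equal(nrow(study$leks), 9)
  expect_setequal(unique(study$leks$category_true), FIRE_CATEGORIES)
  expect_true(all(study$counts$males >= 0))
  expect_true(all(table(study$counts$lek_id) >= 4))
})
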