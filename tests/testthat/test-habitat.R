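test_that("the burn window is inclusive at 17 years and excludes older fires", {
  by <- raster_grid(matrix(c(1984, 1983, 2001, NA, 1990, 2002), 2, 3), 0, 0, 30)
  m <- delineate_burned(by, fire_year = 2001)
  expect_identical(m$values,
                   matrix(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE), 2, 3))
  # no fires on record: all-false mask
  m0 <- delineate_burned(raster_grid(matrix(NA_real_, 2, 2), 0, 0, 30), 2001)
  expect_false(any(m0$values))
})

test_that("postfire height uses class midpoints and zeroes burned/unsuitable cells", {
  hc <- raster_grid(matrix(c(1, 3, 7, 2), 2, 2), 0, 0, 30)
  vt <- raster_grid(matrix(c(1, 1, 1, 4), 2, 2), 0, 0, 30)  # [2,2] juniper
  burned <- raster_grid(matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2), 0, 0, 30)
  h <- postfire_height(hc, vt, burned)
  expect_equal(h$values[1, 1], 0.25)  # class 0-0.5 m -> midpoint
  expect_equal(h$values[2, 1], 0)     # burned sagebrush
  expect_equal(h$values[1, 2], 3.25)  # open-top class
  expect_equal(h$values[2, 2], 0)     # juniper woodland
})

test_that("cheatgrass rules: burn overrides observation below 2000 m only", {
  cover <- raster_grid(matrix(c(2, 40, 5, 30), 2, 2), 0, 0, 30)
  elev <- raster_grid(matrix(c(1500, 2400, 1600, 2000), 2, 2), 0, 0, 30)
  burned <- raster_grid(matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2), 0, 0, 30)
  u <- postfire_cheatgrass(cover, burned, elev)
  expect_true(u$values[1, 1])    # burned, 1500 m, 2% cover -> unsuitable
  expect_false(u$values[2, 1])   # burned, 2400 m, 40% cover -> suitable
  expect_false(u$values[1, 2])   # unburned, 5% <= 8% -> suitable
  expect_false(u$values[2, 2])   # exactly 2000 m follows the >= rule
  expect_error(postfire_cheatgrass(raster_grid(matrix(150, 2, 2), 0, 0, 30),
                                   burned, elev), "within \\[0, 100\\]")
})

test_that("extraction limits: fully burned low disc; constant elevation plane", {
  n <- 11
  surf <- toy_surfaces(
    burned = matrix(TRUE, n, n),
    height_class = matrix(2, n, n),
    veg_type = matrix(1, n, n),
    elevation = matrix(1600, n, n),
    cheat_cover = matrix(1, n, n))
  cv <- extract_covariates(c(165, 165), surf, radii_m = 150)
  expect_equal(cv$veg_height, 0)
  expect_equal(cv$cheat_frac, 1)
  expect_equal(cv$elevation, 1600)
})

test_that("a known 40/60 burned split yields cheat_frac 0.40", {
  n <- 10
  burned <- matrix(FALSE, n, n)
  burned[1:4, ] <- TRUE  # 40 of 100 cells burned
  surf <- toy_surfaces(
    burned = burned,
    height_class = matrix(2, n, n),
    veg_type = matrix(1, n, n),
    elevation = matrix(1700, n, n),       # below threshold
    cheat_cover = matrix(5, n, n))        # unburned cells suitable
  # radius covering the whole square grid (farthest cell centre ~191 m)
  cv <- extract_covariates(c(150, 150), surf, radii_m = 250,
                           require_inside = FALSE)
  expect_equal(cv$n_cells, 100)
  expect_equal(cv$cheat_frac, 0.40)
  # and a disc that leaves the raster is refused by default
  expect_error(extract_covariates(c(150, 150), surf, radii_m = 250),
               "beyond the raster extent")
})

test_that("extraction equals the brute-force per-cell oracle on random grids", {
  set.seed(61)
  for (i in 1:5) {
    n <- 10
    surf <- toy_surfaces(
      burned = matrix(runif(n^2) < 0.3, n, n),
      height_class = matrix(sample(1:7, n^2, TRUE), n, n),
      veg_type = matrix(sample(1:4, n^2, TRUE, prob = c(0.6, 0.2, 0.1, 0.1)),
                        n, n),
      elevation = matrix(runif(n^2, 1300, 2500), n, n),
      cheat_cover = matrix(runif(n^2, 0, 30), n, n))
    lek <- c(runif(1, 120, 180), runif(1, 120, 180))
    r <- runif(1, 60, 110)
    cv <- extract_covariates(lek, surf, radii_m = r)
    oracle <- brute_force_covariates(lek, surf, r)
    expect_equal(cv$veg_height, unname(oracle["veg_height"]), tolerance = 1e-12)
    expect_equal(cv$cheat_frac, unname(oracle["cheat_frac"]), tolerance = 1e-12)
    expect_equal(cv$elevation, unname(oracle["elevation"]), tolerance = 1e-12)
    expect_equal(cv$n_cells, unname(oracle["n_cells"]))
  }
})

test_that("burning more low-elevation cells never decreases cheat_frac", {
  n <- 10
  elevation <- matrix(1700, n, n)
  cover <- matrix(5, n, n)
  burned <- matrix(FALSE, n, n)
  prev <- -Inf
  for (rows in 0:n) {
    b <- burned
    if (rows > 0) b[seq_len(rows), ] <- TRUE
    surf <- toy_surfaces(burned = b, height_class = matrix(2, n, n),
                         veg_type = matrix(1, n, n), elevation = elevation,
                         cheat_cover = cover)
    cf <- extract_covariates(c(150, 150), surf, radii_m = 250,
                             require_inside = FALSE)$cheat_frac
    expect_gte(cf, prev)
    prev <- cf
  }
})

test_that("fire years map to the nearest earlier vegetation layer or drop out", {
  yrs <- 2001:2013
  expect_equal(match_layer_year(c(2005, 2001, 2013), yrs), c(2005L, 2001L, 2013L))
  expect_equal(match_layer_year(2007, c(2001, 2006, 2010)), 2006L)
  expect_true(is.na(match_layer_year(2000, yrs)))
  expect_true(is.na(match_layer_year(2014, yrs)))
  expect_true(is.na(match_layer_year(NA, yrs)))
})

test_that("habitat covariates assemble per lek and drop out-of-window fires", {
  cfg <- landscape_config(extent_m = c(12000, 12000), n_fires = 1,
                          fire_radius_range_m = c(1500, 2500),
                          fire_year_range = c(2005, 2005), rng_seed = 2)
  land <- generate_landscape(cfg)
  ctr <- 6000
  leks <- data.frame(lek_id = c("in", "early"), x = ctr, y = ctr,
                     fire_year = c(2005L, 1999L))
  expect_message(
    hv <- habitat_covariates(leks, land, radii_m = c(400, 800)),
    "outside the vegetation-layer window")
  expect_equal(hv$lek_id, "in")
  expect_equal(ncol(hv), 3 + 6)  # id, fire_year, layer_year + 2 radii x 3 vars
  expect_true(all(hv$cheat_frac_0.4km >= 0 & hv$cheat_frac_0.4km <= 1))
})
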