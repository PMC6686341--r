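#' Simulate yearly peak male counts at one lek
#'
#' Draws Poisson counts from the log-linear before/after trend model
#' \eqn{E(\ln Y) = \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_3 X_1 X_2},
#' where \eqn{X_1} is the survey year centred on the fire year and
#' \eqn{X_2} the postfire indicator. \eqn{\beta_1} is therefore the prefire
#' log-linear trend per year and \eqn{\beta_1 + \beta_3} the postfire trend.
#'
#' @param beta0 intercept (log count at the fire year, prefire level).
#' @param beta1 prefire slope (log scale, per year).
#' @param beta2 postfire level shift (default 0).
#' @param beta3 slope change after fire; postfire slope is `beta1 + beta3`.
#' @param fire_year calendar year of the fire.
#' @param survey_years integer vector of surveyed years (need not be
#'   contiguous).
#' @param fire_year_is_post logical; if `TRUE` (default) counts in the fire
#'   year itself are treated as postfire.
#' @return `data.frame(year, males)` sorted by year.
#' @export
simulate_lek_counts <- function(beta0, beta1, beta2 = 0, beta3 = 0,
                                fire_year, survey_years,
                                fire_year_is_post = TRUE) {
  if (!length(survey_years)) stop("survey_years must be nonempty")
  year <- sort(unique(as.integer(survey_years)))
  x1 <- year - fire_year
  x2 <- as.numeric(if (fire_year_is_post) year >= fire_year
                   else year > fire_year)
  eta <- beta0 + beta1 * x1 + beta2 * x2 + beta3 * x1 * x2
  if (any(abs(eta) > 30))
    stop(sprintf(
      "linear predictor out of range (|eta| up to %.1f > 30); %s",
      max(abs(eta)),
      "check slopes against the survey-year span"))
  data.frame(year = year, males = stats::rpois(length(year), exp(eta)))
}

# default per-category distributions of the true trend parameters
# (log-scale means/sds; see the methods vignette for the rationale)
default_trend_params <- function() list(
  unburned_island = list(beta0 = c(log(35), 0.40), beta1 = c(0.02, 0.02),
                         beta2 = c(0.00, 0.10), beta3 = c(0.00, 0.04)),
  fire_perimeter  = list(beta0 = c(log(35), 0.40), beta1 = c(0.01, 0.02),
                         beta2 = c(-0.50, 0.25), beta3 = c(-0.22, 0.07)),
  small_buffer    = list(beta0 = c(log(30), 0.40), beta1 = c(0.01, 0.02),
                         beta2 = c(-0.10, 0.10), beta3 = c(-0.06, 0.04)),
  large_buffer    = list(beta0 = c(log(30), 0.40), beta1 = c(0.00, 0.02),
                         beta2 = c(0.00, 0.05), beta3 = c(0.00, 0.03)),
  outside         = list(beta0 = c(log(30), 0.40), beta1 = c(0.00, 0.02),
                         beta2 = c(0.00, 0.05), beta3 = c(0.00, 0.03)))

# rejection-sample a point in [box] whose distance relations to the fire
# perimeters satisfy 'accept(d_signed_min)'; d_signed_min is the signed
# distance to the nearest perimeter (negative inside)
sample_point <- function(box, perimeters, accept, max_tries = 20000L) {
  for (i in seq_len(max_tries)) {
    px <- stats::runif(1, box[1], box[2])
    py <- stats::runif(1, box[3], box[4])
    d <- vapply(perimeters, function(p)
      signed_dist_polygon(px, py, p$coords), numeric(1))
    if (accept(d)) return(c(px, py))
  }
  stop("could not place a lek with the requested fire context; ",
       "enlarge the landscape or reduce lek numbers")
}

# signed distance of a point to every perimeter
perimeter_distances <- function(px, py, perimeters) {
  vapply(perimeters, function(p)
    signed_dist_polygon(px, py, p$coords), numeric(1))
}

#' Simulate a complete lek-count study on a synthetic landscape
#'
#' Generates a landscape with [generate_landscape()], plants leks with known
#' fire context in all four fire categories (plus a few beyond the
#' large-buffer limit), assigns each lek the fire year of its containing or
#' nearest perimeter, draws per-lek trend parameters from category-specific
#' distributions, and simulates yearly peak male counts with incomplete
#' survey coverage. Leks are confined to the landscape interior so that
#' habitat discs up to `region_inset_m` never leave the raster.
#'
#' @param config a [landscape_config()].
#' @param n_leks named integer vector of leks to plant per category; the
#'   default (9, 8, 5, 17 analysed-category leks plus 3 outside) mirrors the
#'   composition of a typical refugia study.
#' @param trend_params per-category list of `c(mean, sd)` pairs for
#'   beta0..beta3 (see `default_trend_params`).
#' @param survey_prob probability that a lek is surveyed in any given year.
#' @param region_inset_m inset of the lek-placement box from the landscape
#'   edge (default 18000 m, the largest habitat radius).
#' @param seed integer seed (default `config$rng_seed`).
#' @return An object of class `lek_study`: list with `landscape`, `leks`
#'   (data.frame of true placements and parameters) and `counts`
#'   (long data.frame `lek_id, x, y, year, males`).
#' @export
simulate_study <- function(config = landscape_config(),
                           n_leks = c(unburned_island = 9, fire_perimeter = 8,
                                      small_buffer = 5, large_buffer = 17,
                                      outside = 3),
                           trend_params = default_trend_params(),
                           survey_prob = 0.85,
                           region_inset_m = 18000,
                           seed = config$rng_seed) {
  if (!is.null(seed)) set.seed(seed)
  land <- generate_landscape(config, seed = NULL)
  if (!length(land$perimeters))
    stop("the landscape contains no fires; leks cannot be given fire context")
  box <- c(region_inset_m, config$extent_m[1] - region_inset_m,
           region_inset_m, config$extent_m[2] - region_inset_m)
  if (box[1] >= box[2] || box[3] >= box[4])
    stop("extent too small for the requested region inset")

  isl_idx <- which(land$island$values, arr.ind = TRUE)
  isl_x <- grid_col_x(land$island)[isl_idx[, 2]]
  isl_y <- grid_row_y(land$island)[isl_idx[, 1]]
  in_box <- isl_x >= box[1] & isl_x <= box[2] &
    isl_y >= box[3] & isl_y <= box[4]
  min_isl_dist <- function(px, py) {
    if (!length(isl_x)) return(Inf)
    min(sqrt((isl_x - px)^2 + (isl_y - py)^2))
  }

  leks <- list()
  for (cat in names(n_leks)) {
    k <- n_leks[[cat]]
    if (k == 0) next
    for (j in seq_len(k)) {
      if (cat == "unburned_island") {
        cand <- which(in_box)
        if (!length(cand))
          stop("no unburned-island cells inside the lek-placement region")
        pick <- cand[sample.int(length(cand), 1)]
        pt <- c(isl_x[pick], isl_y[pick])
      } else if (cat == "fire_perimeter") {
        # burned interior, clear of every perimeter edge (including edges of
        # overlapping fires) and of islands (a lek < 50 m from an island or
        # edge would classify as unburned_island)
        tries <- 0L
        repeat {
          pt <- sample_point(box, land$perimeters, function(d)
            min(d) < -80 && min(abs(d)) > 60)
          tries <- tries + 1L
          if (min_isl_dist(pt[1], pt[2]) >= 90 || tries >= 200L) break
        }
      } else if (cat == "small_buffer") {
        pt <- sample_point(box, land$perimeters, function(d)
          all(d > 0) && min(d) >= 100 && min(d) <= 1400)
      } else if (cat == "large_buffer") {
        pt <- sample_point(box, land$perimeters, function(d)
          all(d > 0) && min(d) >= 1700 && min(d) <= 6200)
      } else {  # outside: excluded before habitat extraction, so these may
                # sit anywhere in the landscape, not just the inset region
        outer_box <- c(1000, config$extent_m[1] - 1000,
                       1000, config$extent_m[2] - 1000)
        pt <- sample_point(outer_box, land$perimeters, function(d)
          all(d > 6600))
      }
      d <- perimeter_distances(pt[1], pt[2], land$perimeters)
      nearest <- which(abs(d) == min(abs(d)))
      yrs <- vapply(land$perimeters[nearest], `[[`, numeric(1), "fire_year")
      fire_year <- as.integer(min(yrs))  # ties: earliest disturbance
      tp <- trend_params[[cat]]
      leks[[length(leks) + 1L]] <- data.frame(
        lek_id = sprintf("L%03d", length(leks) + 1L),
        x = pt[1], y = pt[2], category_true = cat,
        fire_year = if (cat == "outside") NA_integer_ else fire_year,
        beta0 = stats::rnorm(1, tp$beta0[1], tp$beta0[2]),
        beta1 = stats::rnorm(1, tp$beta1[1], tp$beta1[2]),
        beta2 = stats::rnorm(1, tp$beta2[1], tp$beta2[2]),
        beta3 = stats::rnorm(1, tp$beta3[1], tp$beta3[2]))
    }
  }
  leks <- do.call(rbind, leks)

  cy <- config$count_years
  counts <- vector("list", nrow(leks))
  for (i in seq_len(nrow(leks))) {
    all_years <- cy[1]:cy[2]
    surveyed <- all_years[stats::runif(length(all_years)) < survey_prob]
    if (length(surveyed) < 4) surveyed <- sort(sample(all_years, 6))
    fy <- leks$fire_year[i]
    if (is.na(fy)) fy <- land$perimeters[[1]]$fire_year  # outside leks: nominal
    cnt <- simulate_lek_counts(leks$beta0[i], leks$beta1[i], leks$beta2[i],
                               leks$beta3[i], fire_year = fy,
                               survey_years = surveyed)
    counts[[i]] <- data.frame(lek_id = leks$lek_id[i],
                              x = leks$x[i], y = leks$y[i], cnt)
  }
  structure(list(landscape = land, leks = leks,
                 counts = do.call(rbind, counts)),
            class = "lek_study")
}

#' @export
print.lek_study <- function(x, ...) {
  cat(sprintf("lek_study: %d leks, %d counts, %d fire(s)\n",
              nrow(x$leks), nrow(x$counts), length(x$landscape$perimeters)))
  print(table(x$leks$category_true))
  invisible(x)
}
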