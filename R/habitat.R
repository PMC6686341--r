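#' Delineate the burned area relevant to a fire year
#'
#' A cell counts as burned if its most recent burn year falls in the window
#' `[fire_year - lookback, fire_year]` (both bounds inclusive). The default
#' 17-year lookback reflects that sagebrush recovers over 35-120 years, so
#' any area burned within the preceding 17 years is still unsuitable, and it
#' spans the gap between the start of the fire record (1984) and the earliest
#' analysed lek fire (2001).
#'
#' @param burn_year_raster [raster_grid()] of most recent burn years (NA =
#'   never burned).
#' @param fire_year the lek's fire year.
#' @param lookback years before `fire_year` still counted as burned
#'   (default 17).
#' @return Logical-valued [raster_grid()].
#' @export
delineate_burned <- function(burn_year_raster, fire_year, lookback = 17) {
  by <- burn_year_raster$values
  burned <- !is.na(by) & by >= fire_year - lookback & by <= fire_year
  raster_grid(burned, burn_year_raster$xmin, burn_year_raster$ymin,
              burn_year_raster$cell_size)
}

# midpoint height (m) of a 0.5 m height class; the open-top class (>3 m,
# class 7) is assigned 3.25 m
height_class_midpoint <- function(class, top_class = 7L,
                                  top_midpoint = 3.25) {
  mid <- (class - 0.5) * 0.5
  mid[class >= top_class] <- top_midpoint
  mid
}

#' Postfire vegetation height surface
#'
#' Converts a height-class raster to metres using class midpoints (0.25 m for
#' the 0-0.5 m class, and so on; the open-top class is 3.25 m), then zeroes
#' burned cells and unsuitable vegetation types (anything other than
#' sagebrush, i.e. grassland, forest and juniper woodland), since sagebrush
#' stands typically burn completely.
#'
#' @param height_class_raster [raster_grid()] of 0.5 m height classes
#'   (integers >= 1).
#' @param veg_type_raster [raster_grid()] of [VEG_CODES] values.
#' @param burned_mask logical [raster_grid()] from [delineate_burned()].
#' @return Numeric [raster_grid()] of heights in metres.
#' @export
postfire_height <- function(height_class_raster, veg_type_raster,
                            burned_mask) {
  h <- height_class_midpoint(height_class_raster$values)
  h[veg_type_raster$values != VEG_CODES[["sagebrush"]]] <- 0
  h[burned_mask$values] <- 0
  raster_grid(h, height_class_raster$xmin, height_class_raster$ymin,
              height_class_raster$cell_size)
}

#' Postfire cheatgrass-unsuitability surface
#'
#' Classifies each cell of the analysis grid as having unsuitable cheatgrass
#' cover (> `cover_threshold` percent). Burned cells below
#' `elevation_threshold_m` are unsuitable regardless of the observed cover
#' (burned low-elevation sagebrush is highly susceptible to cheatgrass
#' invasion); burned cells at or above the threshold are suitable (cheatgrass
#' does not establish at high elevation); unburned cells keep their observed
#' cover, thresholded. The coarse cover raster is first carried onto the
#' analysis grid by nearest-neighbour resampling so cover values are
#' preserved exactly.
#'
#' @param cheat_cover_raster [raster_grid()] of percent cover (0-100),
#'   typically at 250 m.
#' @param burned_mask logical [raster_grid()] on the analysis grid.
#' @param elevation_raster numeric [raster_grid()] on the analysis grid (m).
#' @param cover_threshold percent cover above which habitat is unsuitable
#'   (default 8).
#' @param elevation_threshold_m elevation separating the burned-cell rules
#'   (default 2000; cells at exactly the threshold follow the high-elevation,
#'   suitable rule).
#' @return Logical-valued [raster_grid()]: TRUE = unsuitable cover.
#' @export
postfire_cheatgrass <- function(cheat_cover_raster, burned_mask,
                                elevation_raster, cover_threshold = 8,
                                elevation_threshold_m = 2000) {
  cover <- resample_nearest(cheat_cover_raster, burned_mask)$values
  if (any(cover < 0 | cover > 100, na.rm = TRUE))
    stop("cheatgrass cover must be within [0, 100] percent")
  burned <- burned_mask$values
  low <- elevation_raster$values < elevation_threshold_m
  unsuitable <- ifelse(burned, low, cover > cover_threshold)
  raster_grid(unsuitable, burned_mask$xmin, burned_mask$ymin,
              burned_mask$cell_size)
}

#' Build the postfire habitat surfaces for one fire year
#'
#' Convenience wrapper running [delineate_burned()], [postfire_height()] and
#' [postfire_cheatgrass()] on a landscape's layers.
#'
#' @param landscape a [generate_landscape()] result (or any list with the
#'   same layer names).
#' @param fire_year the lek's fire year.
#' @param lookback,cover_threshold,elevation_threshold_m see the stage
#'   functions.
#' @return List of [raster_grid()] layers: `burned`, `height_m`,
#'   `cheat_unsuitable`, `elevation`, `sagebrush` (logical), plus
#'   `fire_year`.
#' @export
postfire_surfaces <- function(landscape, fire_year, lookback = 17,
                              cover_threshold = 8,
                              elevation_threshold_m = 2000) {
  burned <- delineate_burned(landscape$burn_year, fire_year, lookback)
  list(burned = burned,
       height_m = postfire_height(landscape$height_class,
                                  landscape$veg_type, burned),
       cheat_unsuitable = postfire_cheatgrass(landscape$cheat_cover, burned,
                                              landscape$elevation,
                                              cover_threshold,
                                              elevation_threshold_m),
       elevation = landscape$elevation,
       sagebrush = raster_grid(
         landscape$veg_type$values == VEG_CODES[["sagebrush"]],
         landscape$veg_type$xmin, landscape$veg_type$ymin,
         landscape$veg_type$cell_size),
       fire_year = fire_year)
}

#' Extract multiscale habitat covariates around a lek
#'
#' For each radius, computes within the cell-centre-in-circle disc around the
#' lek: the mean postfire vegetation height over unburned sagebrush cells
#' (0 if no such cell remains), the fraction of disc cells with unsuitable
#' cheatgrass cover, and the mean elevation over all disc cells. An error is
#' raised if any disc extends beyond the raster.
#'
#' @param lek_xy numeric length-2 vector `(x, y)` in metres.
#' @param surfaces output of [postfire_surfaces()].
#' @param radii_m disc radii in metres (default 800, 6400, 18000,
#'   i.e. roughly 2, 129 and 1018 square km).
#' @param require_inside error when a disc extends beyond the raster
#'   (default TRUE; set FALSE only for toy grids that a disc deliberately
#'   covers whole).
#' @return data.frame with one row per radius: `radius_m`, `veg_height`,
#'   `cheat_frac`, `elevation`, `n_cells`.
#' @export
extract_covariates <- function(lek_xy, surfaces,
                               radii_m = c(800, 6400, 18000),
                               require_inside = TRUE) {
  out <- lapply(radii_m, function(r) {
    win <- disc_window(surfaces$elevation, lek_xy[1], lek_xy[2], r,
                       require_inside = require_inside)
    height <- disc_values(surfaces$height_m, win)
    burned <- disc_values(surfaces$burned, win)
    sage <- disc_values(surfaces$sagebrush, win)
    unsuit <- disc_values(surfaces$cheat_unsuitable, win)
    elev <- disc_values(surfaces$elevation, win)
    keep <- !burned & sage
    data.frame(radius_m = r,
               veg_height = if (any(keep)) mean(height[keep]) else 0,
               cheat_frac = mean(unsuit),
               elevation = mean(elev),
               n_cells = length(elev))
  })
  do.call(rbind, out)
}

#' Match a fire year to the available vegetation-layer years
#'
#' Time-specific vegetation layers exist only for `layer_years`; a lek is
#' matched to the layer of its fire year, or failing that to the nearest
#' earlier layer year. Leks burned before the first or after the last layer
#' year have no valid layer and return `NA` (such leks are dropped from the
#' habitat analysis, mirroring the exclusion of leks burned outside the
#' vegetation-data window).
#'
#' @param fire_year integer (vectorised).
#' @param layer_years sorted integer vector of available layer years.
#' @return Integer vector of matched layer years, `NA` where unmatched.
#' @export
match_layer_year <- function(fire_year, layer_years) {
  layer_years <- sort(unique(as.integer(layer_years)))
  vapply(as.integer(fire_year), function(fy) {
    if (is.na(fy) || fy < layer_years[1] ||
        fy > layer_years[length(layer_years)])
      return(NA_integer_)
    candidates <- layer_years[layer_years <= fy]
    candidates[length(candidates)]
  }, integer(1))
}

#' Habitat covariates for every analysed lek
#'
#' Groups leks by fire year, builds the postfire surfaces once per unique
#' year, and extracts the three covariates at the three radii for each lek.
#' Leks whose fire year falls outside the vegetation-layer window are dropped
#' with a message.
#'
#' @param leks data.frame with `lek_id`, `x`, `y`, `fire_year`.
#' @param landscape a [generate_landscape()] result.
#' @param radii_m disc radii (m).
#' @param layer_years available vegetation-layer years (default taken from
#'   `landscape$config$layer_years`).
#' @param ... passed to [postfire_surfaces()].
#' @return data.frame keyed by `lek_id` with `fire_year`, `layer_year` and
#'   nine covariate columns `veg_height_*`, `cheat_frac_*`, `elevation_*`
#'   (suffixes `0.8km`, `6.4km`, `18km` for the default radii).
#' @export
habitat_covariates <- function(leks, landscape,
                               radii_m = c(800, 6400, 18000),
                               layer_years = landscape$config$layer_years,
                               ...) {
  leks$layer_year <- match_layer_year(leks$fire_year, layer_years)
  dropped <- is.na(leks$layer_year)
  if (any(dropped))
    message(sum(dropped), " lek(s) burned outside the vegetation-layer ",
            "window dropped from habitat analysis: ",
            paste(leks$lek_id[dropped], collapse = ", "))
  leks <- leks[!dropped, , drop = FALSE]
  suffix <- sprintf("%gkm", radii_m / 1000)
  rows <- list()
  for (fy in sort(unique(leks$fire_year))) {
    surf <- postfire_surfaces(landscape, fy, ...)
    sub <- leks[leks$fire_year == fy, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      cv <- extract_covariates(c(sub$x[i], sub$y[i]), surf, radii_m)
      row <- data.frame(lek_id = sub$lek_id[i], fire_year = fy,
                        layer_year = sub$layer_year[i])
      for (j in seq_along(radii_m)) {
        row[[paste0("veg_height_", suffix[j])]] <- cv$veg_height[j]
        row[[paste0("cheat_frac_", suffix[j])]] <- cv$cheat_frac[j]
        row[[paste0("elevation_", suffix[j])]] <- cv$elevation[j]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
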