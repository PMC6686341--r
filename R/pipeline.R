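default_thresholds <- function() list(
  island_dist_m = 50, small_buffer_m = 1500, large_buffer_m = 6400,
  radii_m = c(800, 6400, 18000), cover_threshold = 8,
  elevation_threshold_m = 2000, lookback_years = 17, min_survey_years = 6)

#' Pipeline configuration
#'
#' Collects every fixed constant of the analysis in one auditable place: the
#' classification distances (50 m island/edge rule, 1.5 km and 6.4 km
#' buffers), the habitat radii triple, the 8 percent cheatgrass-cover and
#' 2,000 m elevation thresholds, the 17-year burn lookback and the minimum
#' survey effort, plus either a synthetic-study block or paths to input
#' files. Unknown keys anywhere are rejected.
#'
#' @param synthetic optional list of arguments for [simulate_study()] /
#'   [landscape_config()] (keys: any [landscape_config()] argument plus
#'   `n_leks`, `survey_prob`); mutually exclusive with `paths`.
#' @param paths optional list of input files: `counts` (CSV),
#'   `perimeters` (GeoJSON), and ASCII grids `island`, `burn_year`,
#'   `veg_type`, `height_class`, `elevation`, `cheat_cover`.
#' @param thresholds named list overriding entries of the default threshold
#'   set.
#' @param rng_seed integer seed for the synthetic branch.
#' @param averaging `"full"` or `"conditional"` coefficient averaging.
#' @param fire_year_is_post treat fire-year counts as postfire (default
#'   TRUE).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = list(), paths = NULL,
                            thresholds = list(), rng_seed = 1L,
                            averaging = c("full", "conditional"),
                            fire_year_is_post = TRUE) {
  averaging <- match.arg(averaging)
  th <- default_thresholds()
  unknown <- setdiff(names(thresholds), names(th))
  if (length(unknown))
    stop("unknown threshold key(s): ", paste(unknown, collapse = ", "))
  th[names(thresholds)] <- thresholds
  scalars <- unlist(th[setdiff(names(th), "radii_m")])
  if (any(scalars <= 0)) stop("all thresholds must be positive")
  if (length(th$radii_m) < 1 || any(diff(th$radii_m) <= 0) ||
      any(th$radii_m <= 0))
    stop("radii_m must be positive and strictly increasing")
  if (!is.null(paths) && !length(paths)) paths <- NULL  # JSON round trip
  if (!is.null(paths)) {
    need <- c("counts", "perimeters", "island", "burn_year", "veg_type",
              "height_class", "elevation", "cheat_cover")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop("paths lacks entries: ", paste(miss, collapse = ", "))
  }
  syn_ok <- c(names(formals(landscape_config)), "n_leks", "survey_prob",
              "region_inset_m")
  unknown <- setdiff(names(synthetic), syn_ok)
  if (length(unknown))
    stop("unknown synthetic key(s): ", paste(unknown, collapse = ", "))
  # serialisation formats hand named vectors back as named lists
  if (!is.null(synthetic$n_leks)) synthetic$n_leks <- unlist(synthetic$n_leks)
  structure(list(synthetic = synthetic, paths = paths, thresholds = th,
                 rng_seed = as.integer(rng_seed), averaging = averaging,
                 fire_year_is_post = fire_year_is_post),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML or JSON)
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @param config a [pipeline_config()].
#' @return `read_pipeline_config()` returns a validated
#'   [pipeline_config()]; `write_pipeline_config()` returns `path`
#'   invisibly. Configurations round-trip unchanged.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stripped <- unclass(config)
  # keep category names through serialisation (YAML drops names of
  # named atomic vectors)
  if (!is.null(stripped$synthetic$n_leks))
    stripped$synthetic$n_leks <- as.list(stripped$synthetic$n_leks)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(stripped, path)
  else jsonlite::write_json(stripped, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full fire-refugia analysis pipeline
#'
#' Executes the stages in order — classify leks by fire context, apply the
#' inclusion criteria, fit the per-lek before/after Poisson trend models,
#' compare pre/post trend distributions per category, extract multiscale
#' postfire habitat covariates, and model-average the habitat effects — and
#' writes each stage's table to `out_dir` along with a machine-readable run
#' manifest (seed, configuration checksum, per-stage record counts). Output
#' is deterministic: rerunning with the same configuration and seed yields
#' byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `assignments`, `filters`, `trends`,
#'   `comparisons`, `covariates`, `modavg`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds

  ## inputs: synthetic study or files
  if (is.null(config$paths)) {
    syn <- config$synthetic
    lc_args <- syn[intersect(names(syn), names(formals(landscape_config)))]
    lc_args$rng_seed <- config$rng_seed
    lcfg <- do.call(landscape_config, lc_args)
    study_args <- list(config = lcfg)
    for (k in c("n_leks", "survey_prob", "region_inset_m"))
      if (!is.null(syn[[k]]))
      study_args[[k]] <- syn[[k]]
    study <- do.call(simulate_study, study_args)
    landscape <- study$landscape
    counts <- study$counts
    perimeters <- landscape$perimeters
  } else {
    counts <- read_lek_counts(config$paths$counts)
    perimeters <- read_perimeters_geojson(config$paths$perimeters)
    landscape <- list(
      island = read_ascii_grid(config$paths$island),
      burn_year = read_ascii_grid(config$paths$burn_year),
      veg_type = read_ascii_grid(config$paths$veg_type),
      height_class = read_ascii_grid(config$paths$height_class),
      elevation = read_ascii_grid(config$paths$elevation),
      cheat_cover = read_ascii_grid(config$paths$cheat_cover),
      perimeters = perimeters,
      config = list(layer_years = 2001:2013))
    cells <- vapply(landscape[c("island", "burn_year", "veg_type",
                                "height_class", "elevation")],
                    function(g) paste(dim(g$values), g$cell_size,
                                      collapse = "x"), character(1))
    if (length(unique(cells)) != 1L)
      stop("input rasters are not on a common grid; reprojection is not ",
           "performed silently")
  }

  leks <- unique(counts[, c("lek_id", "x", "y")])

  ## 1. classify
  assignments <- classify_leks(leks, perimeters, landscape$island,
                               island_dist_m = th$island_dist_m,
                               small_buffer_m = th$small_buffer_m,
                               large_buffer_m = th$large_buffer_m)
  write_lek_counts(counts, file.path(out_dir, "counts.csv"))
  utils::write.csv(assignments, file.path(out_dir, "assignments.csv"),
                   row.names = FALSE)

  ## 2. filter
  filters <- filter_leks(counts, assignments,
                         min_years = th$min_survey_years,
                         fire_year_is_post = config$fire_year_is_post)
  utils::write.csv(filters, file.path(out_dir, "filters.csv"),
                   row.names = FALSE)
  for (i in which(!filters$included))
    message(sprintf("lek %s excluded (criterion %s)", filters$lek_id[i],
                    filters$reason[i]))

  ## 3. trend fits
  trends <- withCallingHandlers(
    lek_trends(counts, filters,
               fire_year_is_post = config$fire_year_is_post),
    warning = function(w) {
      message("trend stage: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  trends_tab <- trends
  attr(trends_tab, "fits") <- NULL
  utils::write.csv(trends_tab, file.path(out_dir, "trends.csv"),
                   row.names = FALSE)

  ## 4. category comparison
  comparisons <- suppressMessages(compare_categories(trends))
  utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)

  ## 5. habitat covariates (analysed leks only)
  lek_info <- merge(leks, filters[filters$included,
                                  c("lek_id", "fire_year")], by = "lek_id")
  covariates <- suppressMessages(
    habitat_covariates(lek_info, landscape, radii_m = th$radii_m,
                       lookback = th$lookback_years,
                       cover_threshold = th$cover_threshold,
                       elevation_threshold_m = th$elevation_threshold_m))
  utils::write.csv(covariates, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)

  ## 6. multimodel inference on postfire slopes
  suffix <- sprintf("%gkm", th$radii_m / 1000)
  dat <- merge(covariates,
               trends[is.finite(trends$post_slope),
                      c("lek_id", "post_slope")], by = "lek_id")
  ma <- aicc_average(dat$post_slope,
                     dat[, grep("^(veg_height|cheat_frac|elevation)_",
                                names(dat)), drop = FALSE],
                     scales = suffix, averaging = config$averaging)
  utils::write.csv(ma$average, file.path(out_dir, "averaged_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(ma$models, file.path(out_dir, "model_table.csv"),
                   row.names = FALSE)

  ## manifest: seed, config checksum, per-stage record counts
  cfg_path <- file.path(out_dir, "config.json")
  write_pipeline_config(config, cfg_path)
  manifest <- list(
    seed = config$rng_seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = list(classified = nrow(assignments),
                  filtered_in = sum(filters$included),
                  trend_fits = nrow(trends),
                  comparisons = if (is.null(comparisons)) 0L
                                else nrow(comparisons),
                  habitat_leks = nrow(covariates),
                  candidate_models = nrow(ma$models)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(assignments = assignments, filters = filters,
                 trends = trends, comparisons = comparisons,
                 covariates = covariates, modavg = ma, manifest = manifest))
}
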