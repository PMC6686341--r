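#' Read and write lek count tables
#'
#' The interchange format is a plain CSV with columns
#' `lek_id, x, y, year, males` (coordinates in metres of the shared planar
#' CRS).
#'
#' @param path CSV file path.
#' @param counts data.frame in that layout.
#' @return `read_lek_counts()` returns the data.frame; `write_lek_counts()`
#'   returns `path` invisibly.
#' @export
read_lek_counts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lek_id", "x", "y", "year", "males")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("lek count CSV lacks column(s): ", paste(miss, collapse = ", "))
  d
}

#' @rdname read_lek_counts
#' @export
write_lek_counts <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' Write / read fire perimeters as GeoJSON
#'
#' Perimeters travel as a GeoJSON FeatureCollection of Polygon features, one
#' per fire, each with a `fire_year` property. Coordinates are planar metres
#' (no geographic CRS handling).
#'
#' @param perimeters list of perimeter records (`coords` m x 2 matrix,
#'   `fire_year`).
#' @param path file path.
#' @return `write_perimeters_geojson()` returns `path` invisibly;
#'   `read_perimeters_geojson()` returns the perimeter list.
#' @export
write_perimeters_geojson <- function(perimeters, path) {
  features <- lapply(perimeters, function(p) {
    ring <- close_ring(unname(as.matrix(p$coords)))
    list(type = "Feature",
         properties = list(fire_year = p$fire_year),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_perimeters_geojson
#' @export
read_perimeters_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection")
  lapply(g$features, function(f) {
    if (is.null(f$properties$fire_year))
      stop("perimeter feature lacks a fire_year property")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(xy) as.numeric(unlist(xy))))
    list(coords = ring[-nrow(ring), , drop = FALSE],
         fire_year = as.integer(f$properties$fire_year))
  })
}

#' Read deposited per-lek slopes or habitat covariates
#'
#' Readers for user-supplied archived analysis tables (for instance a data
#' deposit accompanying a published refugia study). `read_dryad_slopes()`
#' expects a CSV with at least `lek_id`, `category`, `pre_slope`,
#' `post_slope`; `read_dryad_covariates()` expects `lek_id`, `post_slope`
#' and the nine `veg_height_*`/`cheat_frac_*`/`elevation_*` columns. Place
#' such files under `inst/extdata/dryad/` to reproduce published statistics
#' with [compare_pre_post()] and [aicc_average()].
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_dryad_slopes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lek_id", "category", "pre_slope", "post_slope")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("slope CSV lacks column(s): ", paste(miss, collapse = ", "))
  d
}

#' @rdname read_dryad_slopes
#' @export
read_dryad_covariates <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("lek_id", "post_slope",
            as.vector(outer(c("veg_height", "cheat_frac", "elevation"),
                            c("0.8km", "6.4km", "18km"), paste, sep = "_")))
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("covariate CSV lacks column(s): ", paste(miss, collapse = ", "))
  d
}
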