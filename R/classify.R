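#' Classify leks by fire context
#'
#' Assigns each lek to one of the four fire categories using planar vector
#' distances to fire-perimeter edges plus the unburned-island mask, with the
#' precedence:
#' \enumerate{
#'   \item inside an unburned island, or within `island_dist_m` (50 m) of an
#'     island or of a perimeter edge: `unburned_island`;
#'   \item else inside a perimeter: `fire_perimeter`;
#'   \item else 50 m up to (exclusive) `small_buffer_m` (1.5 km) from the
#'     nearest perimeter: `small_buffer`;
#'   \item else up to and including `large_buffer_m` (6.4 km):
#'     `large_buffer`;
#'   \item else `outside` (excluded from analysis downstream).
#' }
#' The 50 m clause uses the unsigned distance to the perimeter edge, so a lek
#' marginally inside the burned edge is also treated as `unburned_island`,
#' matching the stated rule for leks "close" to a perimeter. The burn year
#' recorded is the fire year of the containing perimeter, or otherwise of the
#' nearest perimeter within the large-buffer limit; ties go to the earliest
#' fire (the earliest disturbance drives habitat state).
#'
#' Island proximity is measured to unburned-island cell centres; a lek inside
#' an island cell is at most half a cell diagonal from its centre, so cell
#' membership is implied by the distance rule at 30 m resolution.
#'
#' @param leks data.frame with columns `lek_id`, `x`, `y` (metres).
#' @param perimeters list of perimeter records, each a list with `coords`
#'   (m x 2 matrix) and `fire_year` (e.g. `landscape$perimeters`).
#' @param island_mask logical-valued [raster_grid()] of unburned islands.
#' @param island_dist_m,small_buffer_m,large_buffer_m category thresholds in
#'   metres (defaults 50, 1500, 6400).
#' @return data.frame, one row per lek: `lek_id`, `category` (factor with
#'   levels [FIRE_CATEGORIES]), `burn_year`, `dist_to_perimeter_m` (signed;
#'   negative inside), `dist_to_island_m` (NA when no islands exist).
#' @export
classify_leks <- function(leks, perimeters, island_mask,
                          island_dist_m = 50, small_buffer_m = 1500,
                          large_buffer_m = 6400) {
  if (!length(perimeters)) stop("no fire perimeters supplied")
  if (any(vapply(perimeters, function(p) is.null(p$fire_year), logical(1))))
    stop("every perimeter needs a fire_year")
  ext <- grid_extent(island_mask)
  if (any(leks$x < ext["xmin"] | leks$x > ext["xmax"] |
          leks$y < ext["ymin"] | leks$y > ext["ymax"]))
    stop("lek coordinates fall outside the raster extent")

  isl_idx <- which(island_mask$values == TRUE, arr.ind = TRUE)
  isl_x <- grid_col_x(island_mask)[isl_idx[, 2]]
  isl_y <- grid_row_y(island_mask)[isl_idx[, 1]]

  out <- vector("list", nrow(leks))
  for (i in seq_len(nrow(leks))) {
    px <- leks$x[i]; py <- leks$y[i]
    d_signed <- vapply(perimeters, function(p)
      signed_dist_polygon(px, py, p$coords), numeric(1))
    years <- vapply(perimeters, function(p) as.numeric(p$fire_year),
                    numeric(1))
    d_island <- if (nrow(isl_idx))
      min(sqrt((isl_x - px)^2 + (isl_y - py)^2)) else NA_real_
    inside <- d_signed < 0
    d_edge_min <- min(abs(d_signed))
    # relevant fire: containing perimeter(s) first, else nearest edge
    rel <- if (any(inside)) which(inside) else which(abs(d_signed) == d_edge_min)
    burn_year <- as.integer(min(years[rel]))

    category <-
      if ((!is.na(d_island) && d_island < island_dist_m) ||
          d_edge_min < island_dist_m) "unburned_island"
      else if (any(inside)) "fire_perimeter"
      else if (d_edge_min < small_buffer_m) "small_buffer"
      else if (d_edge_min <= large_buffer_m) "large_buffer"
      else "outside"
    if (category == "outside") burn_year <- NA_integer_

    out[[i]] <- data.frame(
      lek_id = leks$lek_id[i], category = category, burn_year = burn_year,
      dist_to_perimeter_m = if (any(inside)) -min(abs(d_signed[inside]))
                            else d_edge_min,
      dist_to_island_m = d_island)
  }
  res <- do.call(rbind, out)
  res$category <- factor(res$category, levels = FIRE_CATEGORIES)
  res
}
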