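#' Planar raster grid
#'
#' Minimal single-band raster on a regular planar grid in metres. Values are
#' held in a matrix whose first row is the northernmost row of cells, the row
#' order used by the ESRI ASCII grid interchange format
#' (see [write_ascii_grid()]). All layers of a landscape share one planar
#' origin so cells line up across layers without resampling.
#'
#' @param values numeric (or logical/integer) matrix; row 1 = north.
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param cell_size cell edge length in metres (default 30, the resolution of
#'   standard vegetation and burn-mosaic products).
#' @return An object of class `raster_grid`: a list with elements `values`,
#'   `xmin`, `ymin`, `cell_size`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cell_size = 30) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("'cell_size' must be a positive number")
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cell_size = cell_size),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  ext <- grid_extent(x)
  cat(sprintf("raster_grid: %d rows x %d cols @ %g m\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] m\n",
              ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"]))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  values: min %g, max %g\n", min(v), max(v)))
  invisible(x)
}

#' Extent of a raster grid
#'
#' @param g a [raster_grid()].
#' @return Named numeric vector `xmin, xmax, ymin, ymax` (m).
#' @export
grid_extent <- function(g) {
  c(xmin = g$xmin,
    xmax = g$xmin + ncol(g$values) * g$cell_size,
    ymin = g$ymin,
    ymax = g$ymin + nrow(g$values) * g$cell_size)
}

# x coordinates of column centres / y coordinates of row centres (row 1 north)
grid_col_x <- function(g) g$xmin + (seq_len(ncol(g$values)) - 0.5) * g$cell_size
grid_row_y <- function(g) {
  ymax <- g$ymin + nrow(g$values) * g$cell_size
  ymax - (seq_len(nrow(g$values)) - 0.5) * g$cell_size
}

# row/col of the cell containing point(s); NA outside the grid
cell_index <- function(g, x, y) {
  ext <- grid_extent(g)
  col <- floor((x - g$xmin) / g$cell_size) + 1
  row <- floor((ext["ymax"] - y) / g$cell_size) + 1
  bad <- x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"]
  # points exactly on the top/right edge belong to the last cell
  col[!bad & col > ncol(g$values)] <- ncol(g$values)
  row[!bad & row > nrow(g$values)] <- nrow(g$values)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# raster value at point(s)
value_at <- function(g, x, y) {
  idx <- cell_index(g, x, y)
  out <- rep(NA, length(x))
  ok <- !is.na(idx[, 1])
  out[ok] <- g$values[idx[ok, , drop = FALSE]]
  out
}

#' Cells of a circular disc around a point
#'
#' Disc membership is by cell-centre-in-circle: a cell belongs to the disc of
#' radius `r` iff the Euclidean distance from its centre to `(x, y)` is
#' `<= r`. Returns a rectangular window plus a logical mask so large-radius
#' extractions touch only the necessary rows/columns.
#'
#' @param g a [raster_grid()].
#' @param x,y disc centre (m).
#' @param r radius (m).
#' @param require_inside error if the disc's bounding box extends beyond the
#'   grid (default TRUE; extractions must not silently truncate).
#' @return List with integer vectors `rows`, `cols` and logical matrix `mask`
#'   (same dimensions as the window).
#' @export
disc_window <- function(g, x, y, r, require_inside = TRUE) {
  ext <- grid_extent(g)
  if (require_inside &&
      (x - r < ext["xmin"] || x + r > ext["xmax"] ||
       y - r < ext["ymin"] || y + r > ext["ymax"]))
    stop(sprintf(
      "disc of radius %g m around (%g, %g) extends beyond the raster extent",
      r, x, y))
  cx <- grid_col_x(g); cy <- grid_row_y(g)
  cols <- which(cx >= x - r & cx <= x + r)
  rows <- which(cy >= y - r & cy <= y + r)
  dx <- cx[cols] - x
  dy <- cy[rows] - y
  d2 <- outer(dy^2, dx^2, `+`)
  list(rows = rows, cols = cols, mask = d2 <= r^2)
}

# values of g inside a disc window, as a vector aligned with win$mask
disc_values <- function(g, win) {
  g$values[win$rows, win$cols, drop = FALSE][win$mask]
}

#' Nearest-neighbour resampling onto another grid
#'
#' Re-grids `src` onto the geometry of `template` by nearest-neighbour lookup
#' of the template cell centres, preserving the source values exactly (used to
#' carry coarse cheatgrass-cover rasters onto the 30 m analysis grid before
#' thresholding).
#'
#' @param src source [raster_grid()].
#' @param template [raster_grid()] supplying the target geometry.
#' @return A [raster_grid()] with `template`'s geometry and `src`'s values.
#' @export
resample_nearest <- function(src, template) {
  tx <- grid_col_x(template)
  ty <- grid_row_y(template)
  scol <- pmin(pmax(floor((tx - src$xmin) / src$cell_size) + 1, 1L),
               ncol(src$values))
  sext <- grid_extent(src)
  srow <- pmin(pmax(floor((sext["ymax"] - ty) / src$cell_size) + 1, 1L),
               nrow(src$values))
  raster_grid(src$values[srow, scol, drop = FALSE],
              xmin = template$xmin, ymin = template$ymin,
              cell_size = template$cell_size)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values from north to south. `NA` is stored as the nodata value.
#'
#' @param g a [raster_grid()].
#' @param path file path.
#' @param nodata nodata sentinel written for `NA` (default -9999).
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a [raster_grid()].
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  v <- g$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", nodata)), con)
  writeLines(apply(v, 1L, function(r) paste(format(r, trim = TRUE,
                                                   digits = 15),
                                            collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  body <- scan(path, skip = 6L, quiet = TRUE)
  v <- matrix(body, nrow = val[["nrows"]], ncol = val[["ncols"]],
              byrow = TRUE)
  v[v == val[["nodata_value"]]] <- NA
  raster_grid(v, xmin = val[["xllcorner"]], ymin = val[["yllcorner"]],
              cell_size = val[["cellsize"]])
}
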