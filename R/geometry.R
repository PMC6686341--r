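# Planar vector geometry for lek classification.
# Perimeters are simple polygons: an m x 2 coordinate matrix (metres), not
# necessarily closed; the closing edge last->first is implied.

# close a polygon ring (repeat first vertex) for mgcv::in.out
close_ring <- function(poly) {
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

# logical: is each point strictly inside the polygon
points_in_polygon <- function(pts, poly) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  mgcv::in.out(close_ring(as.matrix(poly)), pts)
}

# minimum Euclidean distance from one point to the polygon boundary (edges)
dist_point_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(poly[-1, 1], poly[1, 1]); y2 <- c(poly[-1, 2], poly[1, 2])
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ((px - x1) * dx + (py - y1) * dy) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  qx <- x1 + t * dx; qy <- y1 + t * dy
  sqrt(min((px - qx)^2 + (py - qy)^2))
}

# signed distance: negative when the point lies inside the polygon
signed_dist_polygon <- function(px, py, poly) {
  d <- dist_point_polygon(px, py, poly)
  if (points_in_polygon(c(px, py), poly)) -d else d
}
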