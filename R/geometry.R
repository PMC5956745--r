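# Planar geometry helpers for EM annotations. Polygons are n x 2 matrices
# (nm), implicitly closed; polylines are n x 2 matrices, open.

polygon_area_nm2 <- function(poly) {
  abs(pracma::polyarea(poly[, 1], poly[, 2]))
}

points_in_polygon <- function(x, y, poly, boundary = TRUE) {
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = boundary)
}

check_polygon <- function(poly, what = "polygon") {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2 || nrow(poly) < 3 || anyNA(poly)) {
    abort(paste0("Degenerate ", what, ": need >= 3 finite (x, y) vertices."))
  }
  if (polygon_area_nm2(poly) <= 0) {
    abort(paste0("Degenerate ", what, ": zero area."))
  }
  poly
}

polyline_length_nm <- function(line) {
  line <- as.matrix(line)
  if (nrow(line) < 2) return(0)
  sum(sqrt(rowSums(diff(line)^2)))
}

# minimum distance from points (x, y) to the segment a-b
dist_points_segment <- function(x, y, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((x - ax)^2 + (y - ay)^2))
  t <- pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / len2))
  sqrt((x - ax - t * dx)^2 + (y - ay - t * dy)^2)
}

# minimum distance from each point to an open polyline
dist_points_polyline <- function(x, y, line) {
  line <- as.matrix(line)
  if (nrow(line) < 2) abort("Zero-length active-zone polyline.")
  if (polyline_length_nm(line) <= 0) abort("Zero-length active-zone polyline.")
  d <- rep(Inf, length(x))
  for (k in seq_len(nrow(line) - 1)) {
    d <- pmin(d, dist_points_segment(x, y, line[k, 1], line[k, 2],
                                     line[k + 1, 1], line[k + 1, 2]))
  }
  d
}

orient2 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# strict (proper) crossing of segments p1-p2 and p3-p4
segments_cross <- function(p1, p2, p3, p4) {
  d1 <- orient2(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- orient2(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- orient2(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- orient2(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

poly_edges <- function(poly) {
  n <- nrow(poly)
  cbind(seq_len(n), c(seq_len(n)[-1], 1))
}

# TRUE when an axis-aligned square [x0, x0+s] x [y0, y0+s] lies fully
# inside `poly` (boundary contact allowed)
square_inside_polygon <- function(x0, y0, s, poly) {
  cx <- c(x0, x0 + s, x0 + s, x0)
  cy <- c(y0, y0, y0 + s, y0 + s)
  if (!all(points_in_polygon(cx, cy, poly, boundary = TRUE))) return(FALSE)
  sq <- cbind(cx, cy)
  ed <- poly_edges(poly)
  for (k in seq_len(nrow(ed))) {
    a <- poly[ed[k, 1], ]
    b <- poly[ed[k, 2], ]
    for (j in 1:4) {
      p <- sq[j, ]
      q <- sq[if (j == 4) 1 else j + 1, ]
      if (segments_cross(a, b, p, q)) return(FALSE)
    }
  }
  TRUE
}

# TRUE when the square has any overlap with `poly`
square_intersects_polygon <- function(x0, y0, s, poly) {
  cx <- c(x0, x0 + s, x0 + s, x0)
  cy <- c(y0, y0, y0 + s, y0 + s)
  if (any(points_in_polygon(cx, cy, poly, boundary = FALSE))) return(TRUE)
  inside_sq <- poly[, 1] > x0 & poly[, 1] < x0 + s &
    poly[, 2] > y0 & poly[, 2] < y0 + s
  if (any(inside_sq)) return(TRUE)
  sq <- cbind(cx, cy)
  ed <- poly_edges(poly)
  for (k in seq_len(nrow(ed))) {
    a <- poly[ed[k, 1], ]
    b <- poly[ed[k, 2], ]
    for (j in 1:4) {
      p <- sq[j, ]
      q <- sq[if (j == 4) 1 else j + 1, ]
      if (segments_cross(a, b, p, q)) return(TRUE)
    }
  }
  # square entirely within the polygon also counts as intersecting
  square_inside_polygon(x0, y0, s, poly)
}
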