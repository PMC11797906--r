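# Internal polygon primitives shared by the geometry, evaluation and
# synthetic modules.  Polygons are n x 2 numeric matrices (columns x, y),
# vertices in order, implicitly closed.  Coordinates are 0-based pixel
# centers, origin top-left, x rightward, y downward.

as_poly_matrix <- function(points) {
  m <- as.matrix(points)
  if (!is.numeric(m) || ncol(m) != 2L) {
    stop("polygon points must be an n x 2 numeric matrix", call. = FALSE)
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}

#' Signed and absolute polygon area
#'
#' Shoelace area of a simple polygon. The sign encodes vertex orientation
#' (positive for counter-clockwise in a y-down raster frame).
#'
#' @param points An n x 2 matrix of vertices (columns x, y), n >= 3.
#' @return A single number; `polygon_area()` is the absolute value.
#' @export
polygon_area <- function(points) {
  abs(polygon_area_signed(points))
}

polygon_area_signed <- function(points) {
  p <- as_poly_matrix(points)
  n <- nrow(p)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]) / 2
}

#' Polygon centroid
#'
#' Area centroid of a simple polygon; falls back to the vertex mean for
#' degenerate (zero-area) inputs.
#'
#' @inheritParams polygon_area
#' @return Length-2 numeric vector (x, y).
#' @export
polygon_centroid <- function(points) {
  p <- as_poly_matrix(points)
  a <- polygon_area_signed(p)
  if (abs(a) < 1e-12) return(colMeans(p))
  n <- nrow(p)
  j <- c(2:n, 1L)
  cr <- p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]
  c(sum((p[, 1L] + p[j, 1L]) * cr), sum((p[, 2L] + p[j, 2L]) * cr)) / (6 * a)
}

# Second-order area moments about the centroid (covariance of the uniform
# distribution over the polygon interior), via the standard shoelace
# integrals.  Returns a 2x2 matrix.
polygon_covariance <- function(points) {
  p <- as_poly_matrix(points)
  ctr <- polygon_centroid(p)
  q <- sweep(p, 2L, ctr)
  n <- nrow(q)
  j <- c(2:n, 1L)
  cr <- q[, 1L] * q[j, 2L] - q[j, 1L] * q[, 2L]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(stats::cov(q))
  ixx <- sum(cr * (q[, 2L]^2 + q[, 2L] * q[j, 2L] + q[j, 2L]^2)) / 12
  iyy <- sum(cr * (q[, 1L]^2 + q[, 1L] * q[j, 1L] + q[j, 1L]^2)) / 12
  ixy <- sum(cr * (q[, 1L] * q[j, 2L] + 2 * q[, 1L] * q[, 2L] +
                     2 * q[j, 1L] * q[j, 2L] + q[j, 1L] * q[, 2L])) / 24
  matrix(c(iyy, ixy, ixy, ixx), 2L, 2L) / a
}

# Drop duplicate consecutive vertices (incl. closing duplicate).
poly_clean <- function(points) {
  p <- as_poly_matrix(points)
  n <- nrow(p)
  if (n > 1L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  n <- nrow(p)
  if (n < 2L) return(p)
  j <- c(2:n, 1L)
  dup <- rowSums(abs(p - p[j, , drop = FALSE])) < 1e-9
  p[!dup, , drop = FALSE]
}

seg_intersects <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

# Simplicity check: no two non-adjacent edges properly intersect.
poly_is_simple <- function(points) {
  p <- as_poly_matrix(points)
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  j <- c(2:n, 1L)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      if (b == a + 1L || (a == 1L && b == n)) next
      if (seg_intersects(p[a, ], p[j[a], ], p[b, ], p[j[b], ])) return(FALSE)
    }
  }
  TRUE
}

# Exact intersection area of two simple polygons (polyclip clipping).
poly_intersection_area <- function(a, b) {
  a <- as_poly_matrix(a); b <- as_poly_matrix(b)
  pieces <- polyclip::polyclip(
    list(list(x = a[, 1L], y = a[, 2L])),
    list(list(x = b[, 1L], y = b[, 2L])),
    op = "intersection"
  )
  if (length(pieces) == 0L) return(0)
  sum(vapply(pieces, function(pc) polygon_area(cbind(pc$x, pc$y)), numeric(1)))
}

# TRUE for points (n x 2) inside or on the boundary of the polygon.
points_in_polygon <- function(points, poly) {
  poly <- as_poly_matrix(poly)
  pts <- matrix(as.numeric(points), ncol = 2L)
  sp::point.in.polygon(pts[, 1L], pts[, 2L], poly[, 1L], poly[, 2L]) > 0L
}

# Validate + repair an annotation polygon per package policy: drop
# duplicate consecutive vertices; still non-simple -> error.
validate_polygon <- function(points, context = "polygon") {
  p <- poly_clean(points)
  if (nrow(p) < 3L) {
    stop(sprintf("%s has fewer than 3 distinct vertices", context), call. = FALSE)
  }
  if (!poly_is_simple(p)) {
    stop(sprintf("%s is self-intersecting after cleanup", context), call. = FALSE)
  }
  p
}
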