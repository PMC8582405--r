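# Polygon primitives shared by the morphometry, detection and synthesis code.
# All polygons are plain N x 2 numeric matrices of (x, y) vertices in
# micrometres, stored in image convention (x right, y down, origin top-left).
# "Counter-clockwise" means positive signed shoelace area in that frame.

as_polygon_matrix <- function(xy) {
  if (is.data.frame(xy)) xy <- as.matrix(xy[, 1:2])
  if (!is.matrix(xy) || ncol(xy) != 2 || !is.numeric(xy)) {
    abort("A polygon must be an N x 2 numeric matrix of (x, y) vertices.")
  }
  storage.mode(xy) <- "double"
  # drop a duplicated closing vertex
  n <- nrow(xy)
  if (n > 1 && all(xy[1, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  xy
}

polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area, perimeter and centroid
#'
#' Shoelace area (absolute value, square micrometres), total Euclidean edge
#' length, and area centroid of a simple closed polygon given as an N x 2
#' matrix of (x, y) vertices.
#'
#' @param xy N x 2 numeric matrix of polygon vertices; the closing edge from
#'   the last to the first vertex is implicit.
#' @return `polygon_area()` and `polygon_perimeter()` return a scalar;
#'   `polygon_centroid()` a length-2 numeric vector.
#' @export
polygon_area <- function(xy) {
  xy <- as_polygon_matrix(xy)
  abs(polygon_signed_area(xy))
}

#' @rdname polygon_area
#' @export
polygon_perimeter <- function(xy) {
  xy <- as_polygon_matrix(xy)
  d <- xy[c(2:nrow(xy), 1), ] - xy
  sum(sqrt(rowSums(d^2)))
}

#' @rdname polygon_area
#' @export
polygon_centroid <- function(xy) {
  xy <- as_polygon_matrix(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) {
    return(colMeans(xy))
  }
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Second central moments of the uniform density over the polygon interior,
# normalised by area: mu_xx = E[(x - cx)^2] etc. Closed-form edge sums.
polygon_second_moments <- function(xy) {
  xy <- as_polygon_matrix(xy)
  xy <- ensure_ccw(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (a <= 0) abort("Polygon has non-positive area; cannot compute moments.")
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  list(mu_xx = ixx / a - cx^2,
       mu_yy = iyy / a - cy^2,
       mu_xy = ixy / a - cx * cy,
       area = a, centroid = c(cx, cy))
}

ensure_ccw <- function(xy) {
  if (polygon_signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  else xy
}

is_convex_polygon <- function(xy) {
  xy <- ensure_ccw(as_polygon_matrix(xy))
  n <- nrow(xy)
  p <- xy
  q <- xy[c(2:n, 1), , drop = FALSE]
  r <- xy[c(3:n, 1, 2), , drop = FALSE]
  cr <- (q[, 1] - p[, 1]) * (r[, 2] - p[, 2]) -
        (q[, 2] - p[, 2]) * (r[, 1] - p[, 1])
  all(cr >= -1e-12 * max(abs(xy)))
}

#' Validate and normalise a nuclear contour
#'
#' Checks that a contour is a finite, simple (non-self-intersecting) closed
#' polygon with at least three vertices and positive area, and normalises
#' its winding to counter-clockwise.
#'
#' @inheritParams polygon_area
#' @return The validated polygon matrix, counter-clockwise.
#' @export
validate_contour <- function(xy) {
  xy <- as_polygon_matrix(xy)
  if (nrow(xy) < 3) abort("A contour needs at least 3 vertices.")
  if (!all(is.finite(xy))) abort("Contour vertices must be finite.")
  if (cpp_self_intersects(xy)) abort("Contour is self-intersecting.")
  if (polygon_area(xy) <= 0) abort("Contour encloses zero area.")
  ensure_ccw(xy)
}

#' Resample a polygon boundary at equal arc-length spacing
#'
#' Places `n_vertices` points equally spaced by arc length along the closed
#' polygonal boundary, starting at the first vertex. Resampling never
#' increases the perimeter and changes the enclosed area by well under 1%
#' for smooth contours at 64+ vertices; the irregularity statistic is
#' computed on a resampled boundary so it does not depend on annotation
#' vertex density.
#'
#' @inheritParams polygon_area
#' @param n_vertices Number of output vertices (>= 8).
#' @return `n_vertices` x 2 matrix.
#' @export
resample_boundary <- function(xy, n_vertices = 64L) {
  xy <- as_polygon_matrix(xy)
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 8L) abort("n_vertices must be at least 8.")
  n <- nrow(xy)
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                       closed[-(n + 1), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[n + 1]
  if (total <= 0) abort("Degenerate boundary of zero length.")
  s <- seq(0, total, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > n] <- n
  t <- (s - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  p0 <- closed[idx, , drop = FALSE]
  p1 <- closed[idx + 1L, , drop = FALSE]
  p0 + t * (p1 - p0)
}

# Regular n-gon, CCW, centred at `center`, with polygon area exactly `area`.
# Used as the "concentric circle" in the circularity measure: matching the
# n-gon area to the nucleus area removes the inscribed-polygon bias.
regular_ngon <- function(center, area, n = 64L) {
  r <- sqrt(2 * area / (n * sin(2 * pi / n)))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

#' Intersection area and IoU of two simple polygons
#'
#' Exact Sutherland-Hodgman clipping when at least one polygon is convex;
#' otherwise a fine-grid rasterisation of the joint bounding box (default
#' 512 cells along its longer side). Intended for nucleus-scale geometry
#' where both routes agree to well under 1%.
#'
#' @param a,b N x 2 polygon matrices.
#' @param raster_n Grid resolution for the non-convex fallback.
#' @return Scalar area (um^2) or IoU in \[0, 1\].
#' @export
polygon_intersection_area <- function(a, b, raster_n = 512L) {
  a <- ensure_ccw(as_polygon_matrix(a))
  b <- ensure_ccw(as_polygon_matrix(b))
  if (is_convex_polygon(b)) {
    out <- cpp_clip_convex(a, b)
    if (nrow(out) < 3) return(0)
    return(polygon_area(out))
  }
  if (is_convex_polygon(a)) {
    out <- cpp_clip_convex(b, a)
    if (nrow(out) < 3) return(0)
    return(polygon_area(out))
  }
  # rasterisation fallback for two non-convex polygons
  lo <- pmax(apply(a, 2, min), apply(b, 2, min))
  hi <- pmin(apply(a, 2, max), apply(b, 2, max))
  if (any(hi <= lo)) return(0)
  step <- max(hi - lo) / raster_n
  gx <- seq(lo[1] + step / 2, hi[1], by = step)
  gy <- seq(lo[2] + step / 2, hi[2], by = step)
  ina <- cpp_grid_in_polygon(gx, gy, a)
  inb <- cpp_grid_in_polygon(gx, gy, b)
  sum(ina & inb) * step^2
}

#' @rdname polygon_intersection_area
#' @export
polygon_iou <- function(a, b, raster_n = 512L) {
  ia <- polygon_intersection_area(a, b, raster_n = raster_n)
  ua <- polygon_area(a) + polygon_area(b) - ia
  if (ua <= 0) return(0)
  ia / ua
}
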