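# The seven per-nucleus attributes. All take a single contour (N x 2 matrix
# of vertices in micrometres) except the entropy, which also needs the
# intensity patch the nucleus was segmented from.

#' Axis ratio and orientation of the equivalent ellipse
#'
#' The "longest over second-longest axis" of a nucleus is measured on the
#' area-equivalent ellipse of the polygon interior: the ellipse with the
#' same second central moments as the uniform density over the polygon.
#' The axis ratio is the major/minor axis ratio (>= 1); the orientation is
#' the angle of the major axis from the +x axis, in radians in \[0, pi).
#' Isotropic shapes (relative eigenvalue gap below `isotropy_tol`) return
#' axis ratio 1 and orientation 0, flagged via the `"isotropic"` attribute.
#'
#' @param xy N x 2 contour matrix (micrometres).
#' @param isotropy_tol Relative moment-eigenvalue gap below which a shape is
#'   treated as isotropic.
#' @return Scalar; `nucleus_orientation()` carries attribute `"isotropic"`.
#' @export
axis_ratio <- function(xy, isotropy_tol = 1e-9) {
  e <- moment_axes(xy, isotropy_tol)
  if (e$isotropic) return(1)
  r <- sqrt(e$lambda[1] / e$lambda[2])
  if (!is.finite(r)) abort("Degenerate polygon: zero minor axis.")
  r
}

#' @rdname axis_ratio
#' @export
nucleus_orientation <- function(xy, isotropy_tol = 1e-9) {
  e <- moment_axes(xy, isotropy_tol)
  if (e$isotropic) {
    return(structure(0, isotropic = TRUE))
  }
  structure(e$theta, isotropic = FALSE)
}

moment_axes <- function(xy, isotropy_tol = 1e-9) {
  m <- polygon_second_moments(xy)
  tr <- m$mu_xx + m$mu_yy
  disc <- sqrt(((m$mu_xx - m$mu_yy) / 2)^2 + m$mu_xy^2)
  lambda <- c(tr / 2 + disc, tr / 2 - disc)
  if (lambda[2] <= 0) abort("Degenerate polygon: zero minor axis.")
  iso <- disc <= isotropy_tol * max(tr / 2, .Machine$double.eps)
  theta <- atan2(2 * m$mu_xy, m$mu_xx - m$mu_yy) / 2
  theta <- theta %% pi
  if (pi - theta < 1e-9) theta <- 0 # fold the circular boundary
  list(lambda = lambda, theta = theta, isotropic = iso)
}

#' Circularity of a nucleus
#'
#' Overlap between the nucleus and its concentric equal-area circle: the
#' area of intersection between the polygon and a disk centred at the
#' polygon centroid whose area equals the polygon area, divided by the
#' polygon area. Equals 1 for a disk and decreases with elongation or
#' boundary irregularity. The disk is represented as a regular `n_circle`-gon
#' of exactly matching area and the intersection is computed by exact convex
#' clipping.
#'
#' @inheritParams axis_ratio
#' @param n_circle Number of vertices of the disk polygon.
#' @return Scalar in (0, 1\] (up to discretisation tolerance).
#' @export
circularity <- function(xy, n_circle = 64L) {
  xy <- ensure_ccw(as_polygon_matrix(xy))
  a <- polygon_area(xy)
  if (a <= 0) abort("Contour encloses zero area.")
  disk <- regular_ngon(polygon_centroid(xy), a, n = n_circle)
  clp <- cpp_clip_convex(xy, disk)
  if (nrow(clp) < 3) return(0)
  min(polygon_area(clp) / a, 1)
}

#' Nuclear area and perimeter
#'
#' Area is the shoelace area of the contour in square micrometres.
#' Perimeter is the total Euclidean edge length of the boundary resampled
#' to `n_vertices` equal arc-length steps (resolution-independent analogue
#' of counting boundary pixels).
#'
#' @inheritParams axis_ratio
#' @param n_vertices Resampling density for the perimeter.
#' @return Scalar, um^2 or um.
#' @export
nucleus_area <- function(xy) polygon_area(as_polygon_matrix(xy))

#' @rdname nucleus_area
#' @export
nucleus_perimeter <- function(xy, n_vertices = 64L) {
  polygon_perimeter(resample_boundary(xy, n_vertices))
}

#' Boundary irregularity of a nucleus
#'
#' Population variance of the distances from the polygon centroid to each
#' vertex of the boundary resampled at `n_vertices` equal arc-length steps,
#' in square micrometres. Near zero for a disk; grows with lobulation and
#' radial spread. Resampling makes the statistic independent of the
#' annotation vertex density.
#'
#' @inheritParams nucleus_area
#' @return Scalar, um^2.
#' @export
irregularity <- function(xy, n_vertices = 64L) {
  xy <- as_polygon_matrix(xy)
  ctr <- polygon_centroid(xy)
  rb <- resample_boundary(xy, n_vertices)
  d <- sqrt((rb[, 1] - ctr[1])^2 + (rb[, 2] - ctr[2])^2)
  mean(d^2) - mean(d)^2
}

#' Intensity entropy of a nucleus
#'
#' Shannon entropy (base 2) of the 256-bin histogram of 8-bit intensities of
#' the patch pixels whose centres fall inside the contour. Constant interiors
#' give 0 bits; an interior uniform over all 256 levels approaches 8 bits.
#'
#' @inheritParams axis_ratio
#' @param patch A [calibrated_patch()] covering the contour.
#' @param bins Number of histogram bins over \[0, 255\].
#' @return Entropy in bits.
#' @export
intensity_entropy <- function(xy, patch, bins = 256L) {
  xy <- as_polygon_matrix(xy)
  if (!inherits(patch, "calibrated_patch")) {
    abort("`patch` must be a calibrated_patch.")
  }
  v <- interior_pixels(xy, patch)
  if (length(v) == 0) {
    abort("No pixel centre falls inside the contour; nucleus too small for the patch resolution.")
  }
  idx <- pmin(pmax(floor(v / 256 * bins), 0), bins - 1L)
  p <- tabulate(idx + 1L, nbins = bins)
  p <- p[p > 0] / length(v)
  -sum(p * log2(p))
}

# Intensities of pixels whose centres fall inside the polygon.
interior_pixels <- function(xy, patch) {
  ps <- patch$pixel_size
  nr <- nrow(patch$intensities); nc <- ncol(patch$intensities)
  # pixel-centre coordinates: origin + index * pixel_size (0-based)
  jx <- (xy[, 1] - patch$origin[1]) / ps
  iy <- (xy[, 2] - patch$origin[2]) / ps
  j0 <- max(0L, floor(min(jx))); j1 <- min(nc - 1L, ceiling(max(jx)))
  i0 <- max(0L, floor(min(iy))); i1 <- min(nr - 1L, ceiling(max(iy)))
  if (j1 < j0 || i1 < i0) return(numeric(0))
  js <- j0:j1; is <- i0:i1
  inside <- cpp_grid_in_polygon(patch$origin[1] + js * ps,
                                patch$origin[2] + is * ps, xy)
  sub <- patch$intensities[is + 1L, js + 1L, drop = FALSE]
  # sub is rows = y, cols = x; `inside` varies x fastest
  as.vector(t(sub))[inside]
}

#' Compute the seven morphometric attributes for a set of nuclei
#'
#' Tidy front end over the per-attribute functions: takes a contour table
#' (as produced by [read_label_mask()], [read_polygon_annotations()] or the
#' synthetic generator) and returns one row per nucleus with the seven
#' attributes in canonical order, plus the isotropy flag. Entropy requires
#' intensities: pass one shared `patch`, or a `patch` list-column on
#' `contours`; with neither, entropy is `NA` (geometry-only mode, warned
#' once).
#'
#' @param contours Tibble with a `polygon` list-column (plus optional
#'   `nucleus_id`, `hpf_id`, `patch` columns), or a single N x 2 matrix.
#' @param patch Optional shared [calibrated_patch()] for all nuclei.
#' @param n_vertices Boundary resampling density for irregularity and
#'   perimeter.
#' @param isotropy_tol Isotropy threshold for orientation.
#' @return Tibble: `nucleus_id`, `hpf_id`, `axis_ratio`, `circularity`,
#'   `entropy`, `area`, `irregularity`, `perimeter`, `orientation`,
#'   `isotropic`.
#' @export
compute_morphometrics <- function(contours, patch = NULL, n_vertices = 64L,
                                  isotropy_tol = 1e-9) {
  if (is.matrix(contours)) {
    contours <- new_contour_table(1L, NA_character_, list(contours))
  }
  if (!is.data.frame(contours) || !"polygon" %in% names(contours)) {
    abort("`contours` must be a contour table with a `polygon` list-column.")
  }
  n <- nrow(contours)
  patches <- if (!is.null(patch)) {
    rep(list(patch), n)
  } else if ("patch" %in% names(contours)) {
    contours$patch
  } else {
    if (n > 0) warn("No intensity patch supplied; entropy will be NA.")
    rep(list(NULL), n)
  }
  ids <- contours$nucleus_id %||% seq_len(n)
  hpfs <- contours$hpf_id %||% rep(NA_character_, n)
  out <- matrix(NA_real_, n, 7,
                dimnames = list(NULL, morphometric_attributes()))
  iso <- logical(n)
  for (k in seq_len(n)) {
    xy <- tryCatch(validate_contour(contours$polygon[[k]]),
                   error = function(e) {
                     abort(sprintf("Nucleus %s: %s", ids[[k]],
                                   conditionMessage(e)))
                   })
    ax <- moment_axes(xy, isotropy_tol)
    ctr <- polygon_centroid(xy)
    rb <- resample_boundary(xy, n_vertices)
    d2 <- (rb[, 1] - ctr[1])^2 + (rb[, 2] - ctr[2])^2
    d <- sqrt(d2)
    dd <- rb[c(2:nrow(rb), 1), ] - rb
    ent <- if (is.null(patches[[k]])) NA_real_ else {
      intensity_entropy(xy, patches[[k]])
    }
    out[k, ] <- c(
      if (ax$isotropic) 1 else sqrt(ax$lambda[1] / ax$lambda[2]),
      circularity(xy),
      ent,
      polygon_area(xy),
      mean(d2) - mean(d)^2,
      sum(sqrt(rowSums(dd^2))),
      if (ax$isotropic) 0 else ax$theta)
    iso[k] <- ax$isotropic
  }
  res <- dplyr::bind_cols(
    tibble(nucleus_id = ids, hpf_id = hpfs),
    as_tibble(out),
    tibble(isotropic = iso))
  # configuration echo so downstream reports can state how the attributes
  # were computed
  attr(res, "config") <- list(n_resample_vertices = as.integer(n_vertices),
                              entropy_bins = 256L,
                              isotropy_tolerance = isotropy_tol)
  res
}
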