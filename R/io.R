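# Readers and writers: instance label masks, GeoJSON polygon annotations,
# case manifests and the frozen 28-column feature tables.

#' Construct a calibrated intensity patch
#'
#' A grayscale patch on the 8-bit scale \[0, 255\] with its pixel size
#' (micrometres per pixel) and the (x, y) offset of its top-left pixel in
#' field coordinates (micrometres). Rows index y (down), columns index x
#' (right); the centre of pixel `[i, j]` (0-based) sits at
#' `origin + c(j, i) * pixel_size`.
#'
#' @param intensities Numeric matrix of intensities in \[0, 255\].
#' @param pixel_size Micrometres per pixel (> 0).
#' @param origin Length-2 (x, y) offset in micrometres.
#' @return An object of class `calibrated_patch`.
#' @export
calibrated_patch <- function(intensities, pixel_size = hpf_pixel_size(),
                             origin = c(0, 0)) {
  if (!is.matrix(intensities) || !is.numeric(intensities) ||
      any(dim(intensities) < 1L)) {
    abort("`intensities` must be a numeric matrix of at least 1 x 1.")
  }
  if (!all(is.finite(intensities))) abort("Patch intensities must be finite.")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    abort("`pixel_size` must be a positive scalar (um per pixel).")
  }
  structure(list(intensities = intensities,
                 pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "calibrated_patch")
}

#' @export
print.calibrated_patch <- function(x, ...) {
  cat(sprintf("<calibrated_patch> %d x %d px, %.4f um/px, origin (%g, %g) um\n",
              nrow(x$intensities), ncol(x$intensities),
              x$pixel_size, x$origin[1], x$origin[2]))
  invisible(x)
}

new_contour_table <- function(nucleus_id, hpf_id, polygon) {
  tibble(nucleus_id = nucleus_id, hpf_id = hpf_id, polygon = polygon)
}

read_mask_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    rlang::check_installed("tiff")
    m <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    rlang::check_installed("png")
    m <- png::readPNG(path)
    # readPNG rescales to [0, 1]; recover integer labels (16-bit assumed
    # when 8-bit rounding does not give integers)
    m8 <- m * 255
    m <- if (max(abs(m8 - round(m8))) < 1e-9) round(m8) else round(m * 65535)
  } else {
    abort("Label masks must be TIFF or PNG files, or an integer matrix.")
  }
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' Read nuclear contours from an instance label mask
#'
#' Traces the boundary of every positive integer label in an instance mask
#' (background 0) and returns one contour per nucleus, in micrometres.
#' Boundaries run through the centres of boundary pixels, so a k x k square
#' label yields a polygon of area (k - 1)^2 in pixel units; pixel `[i, j]`
#' (0-based) maps to `(j, i) * pixel_size` micrometres. Labels tracing to
#' fewer than three boundary points are skipped and counted in the
#' `"skipped"` attribute.
#'
#' @param mask Integer matrix (rows = y, columns = x), or path to a
#'   TIFF/PNG instance mask.
#' @param pixel_size Micrometres per pixel; defaults to the high-power-field
#'   calibration [hpf_pixel_size()] (logged via a message when defaulted).
#' @param hpf_id Optional field identifier attached to every contour.
#' @return Tibble with columns `nucleus_id`, `hpf_id` and a `polygon`
#'   list-column of N x 2 matrices; attribute `"skipped"` holds the skipped
#'   label ids.
#' @export
read_label_mask <- function(mask, pixel_size = NULL, hpf_id = NA_character_) {
  if (is.character(mask)) mask <- read_mask_file(mask)
  if (!is.matrix(mask) || !is.numeric(mask)) {
    abort("`mask` must be an integer matrix or a mask file path.")
  }
  if (max(abs(mask - round(mask))) > 1e-9) {
    abort("`mask` is not an integer label image.")
  }
  if (is.null(pixel_size)) {
    pixel_size <- hpf_pixel_size()
    message(sprintf("read_label_mask: defaulting pixel_size to %.5f um/px",
                    pixel_size))
  }
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  mask <- round(mask)
  storage.mode(mask) <- "integer"
  labels <- sort(setdiff(unique(as.vector(mask)), 0L))
  if (length(labels) == 0) {
    warn("Mask contains no positive labels; returning an empty contour table.")
    out <- new_contour_table(integer(), rep(hpf_id, 0), list())
    attr(out, "skipped") <- integer()
    return(out)
  }
  # EBImage::ocontour traces boundary-pixel centres, 0-based, first matrix
  # dimension first -- with rows = y that is (y, x)
  oc <- EBImage::ocontour(mask)
  ids <- as.integer(names(oc))
  polys <- vector("list", length(labels))
  keep <- logical(length(labels))
  skipped <- integer()
  for (k in seq_along(labels)) {
    lab <- labels[k]
    ctr <- oc[[match(lab, ids)]]
    if (is.null(ctr) || nrow(ctr) < 3) {
      skipped <- c(skipped, lab)
      next
    }
    polys[[k]] <- cbind(ctr[, 2], ctr[, 1]) * pixel_size
    keep[k] <- TRUE
  }
  if (length(skipped)) {
    warn(sprintf("Skipped %d label(s) with fewer than 3 boundary points: %s",
                 length(skipped), paste(skipped, collapse = ", ")))
  }
  out <- new_contour_table(labels[keep], rep(hpf_id, sum(keep)),
                           lapply(polys[keep], ensure_ccw))
  attr(out, "skipped") <- skipped
  out
}

#' Read polygon annotations from a GeoJSON file
#'
#' Reads a QuPath-compatible GeoJSON `FeatureCollection` of `Polygon`
#' features. Pixel coordinates are scaled to micrometres by the calibration,
#' which must be present as a top-level `pixel_size_um` property (or be
#' supplied). Winding is normalised to counter-clockwise; self-intersecting
#' polygons are rejected (ids recorded in the `"rejected"` attribute) while
#' the remaining polygons are still returned.
#'
#' @param path Path to a GeoJSON file.
#' @param pixel_size Micrometres per pixel; overrides the file calibration.
#' @param hpf_id Optional field identifier.
#' @return Contour tibble as in [read_label_mask()], with attribute
#'   `"rejected"`.
#' @export
read_polygon_annotations <- function(path, pixel_size = NULL,
                                     hpf_id = NA_character_) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    abort("Annotation file is not a GeoJSON FeatureCollection.")
  }
  pixel_size <- pixel_size %||% gj$pixel_size_um %||%
    gj$properties$pixel_size_um
  if (is.null(pixel_size)) {
    abort("No pixel-size calibration: supply `pixel_size` or a top-level `pixel_size_um` property.")
  }
  pixel_size <- as.numeric(pixel_size)
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` must be a positive number.")
  }
  feats <- gj$features
  ids <- character(0); polys <- list(); rejected <- character(0)
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    id <- as.character(f$id %||% f$properties$name %||% k)
    if (!identical(f$geometry$type, "Polygon")) {
      rejected <- c(rejected, id)
      next
    }
    ring <- f$geometry$coordinates[[1]] # exterior ring
    xy <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
    xy <- as_polygon_matrix(xy) * pixel_size
    ok <- tryCatch({
      validate_contour(xy)
    }, error = function(e) NULL)
    if (is.null(ok)) {
      rejected <- c(rejected, id)
      next
    }
    ids <- c(ids, id)
    polys <- c(polys, list(ok))
  }
  if (length(rejected)) {
    warn(sprintf("Rejected %d invalid polygon(s): %s",
                 length(rejected), paste(rejected, collapse = ", ")))
  }
  out <- new_contour_table(ids, rep(hpf_id, length(ids)), polys)
  attr(out, "rejected") <- rejected
  out
}

#' Write and read the frozen 28-column feature table
#'
#' Feature tables carry one row per high-power field (or per case) with the
#' 28 moment features in the canonical order of [feature_names()], plus any
#' leading identifier columns. Values round-trip at full double precision.
#'
#' @param rows Data frame containing all 28 feature columns.
#' @param path Output CSV path.
#' @return `write_feature_table()` returns `rows` invisibly;
#'   `read_feature_table()` a tibble.
#' @export
write_feature_table <- function(rows, path) {
  rows <- as_tibble(rows)
  miss <- setdiff(feature_names(), names(rows))
  if (length(miss)) {
    abort(paste0("Feature table is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  id_cols <- setdiff(names(rows), feature_names())
  rows <- rows[, c(id_cols, feature_names())]
  # %.17g guarantees binary round-trip for doubles (plain column text
  # formatting stops at 15 significant digits)
  out <- dplyr::mutate(rows, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path)
  invisible(rows)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  # base read.csv: its double parser is correctly rounded, so the
  # %.17g-formatted values reproduce bit for bit
  out <- as_tibble(utils::read.csv(path, check.names = FALSE))
  miss <- setdiff(feature_names(), names(out))
  if (length(miss)) {
    abort(paste0("File is not a feature table; missing: ",
                 paste(miss, collapse = ", ")))
  }
  out
}

#' Read and validate a case manifest
#'
#' A manifest has one row per case: `case_id`, `diagnosis` (one of
#' `MEITL`, `ITCL-NOS`, `borderline`), and CD8/CD56 immunohistochemistry
#' status (`+`, `-` or `unknown`).
#'
#' @param x Path to a CSV manifest, or a data frame to validate.
#' @return Validated tibble.
#' @export
read_case_manifest <- function(x) {
  m <- if (is.character(x)) {
    readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  } else {
    as_tibble(x)
  }
  req <- c("case_id", "diagnosis", "cd8", "cd56")
  miss <- setdiff(req, names(m))
  if (length(miss)) {
    abort(paste0("Manifest is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(m$case_id)) abort("Case ids must be unique.")
  bad <- setdiff(unique(m$diagnosis), c("MEITL", "ITCL-NOS", "borderline"))
  if (length(bad)) {
    abort(paste0("Unknown diagnosis label(s): ", paste(bad, collapse = ", ")))
  }
  for (col in c("cd8", "cd56")) {
    bad <- setdiff(unique(m[[col]]), c("+", "-", "unknown"))
    if (length(bad)) {
      abort(sprintf("Column `%s` must be '+', '-' or 'unknown'.", col))
    }
  }
  m
}
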