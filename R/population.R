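# Population moment features: per-field 28-vectors and case-level profiles.

#' Four population moments of a numeric vector
#'
#' Mean, population variance (divide by n), standardised skewness (g1) and
#' standardised, non-excess kurtosis (a normal population gives 3). For a
#' zero-variance population the skewness and kurtosis are undefined; they
#' are reported with the documented sentinels 0 and 3 and `degenerate =
#' TRUE` so downstream aggregation is not poisoned.
#'
#' @param x Numeric vector.
#' @return Named list: `mean`, `variance`, `skewness`, `kurtosis`,
#'   `degenerate`.
#' @export
moment_stats <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) abort("No finite values to summarise.")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0) {
    return(list(mean = m, variance = 0, skewness = 0, kurtosis = 3,
                degenerate = TRUE))
  }
  list(mean = m,
       variance = m2,
       skewness = mean(d^3) / m2^1.5,
       kurtosis = mean(d^4) / m2^2,
       degenerate = FALSE)
}

#' Per-field moment feature vector
#'
#' Characterises the whole nuclear population of one high-power field by the
#' four moments of each of the seven attributes: 28 features named
#' `{attribute}_{mean|variance|skewness|kurtosis}` in the frozen order of
#' [feature_names()]. Fields with fewer than `min_nuclei` nuclei are
#' returned flagged (`flagged = TRUE`, feature values `NA`) and are excluded
#' from case aggregation.
#'
#' @param morph Per-nucleus morphometrics tibble from
#'   [compute_morphometrics()] (one field).
#' @param min_nuclei Minimum population size for meaningful moments.
#' @param hpf_id Field identifier; defaults to the one in `morph`.
#' @return One-row tibble: `hpf_id`, `n_nuclei`, the 28 features, `flagged`,
#'   and `degenerate` (comma-separated attributes whose skewness/kurtosis
#'   hit the zero-variance sentinel).
#' @export
hpf_moments <- function(morph, min_nuclei = 8L, hpf_id = NULL) {
  attrs <- morphometric_attributes()
  miss <- setdiff(attrs, names(morph))
  if (length(miss)) {
    abort(paste0("Missing attribute columns: ", paste(miss, collapse = ", ")))
  }
  hpf_id <- hpf_id %||%
    (if (nrow(morph) > 0) as.character(morph$hpf_id[[1]]) else NA_character_)
  n <- nrow(morph)
  vals <- rep(NA_real_, 28)
  names(vals) <- feature_names()
  degen <- character(0)
  flagged <- n < min_nuclei
  if (!flagged) {
    for (a in attrs) {
      ms <- moment_stats(morph[[a]])
      vals[paste(a, c("mean", "variance", "skewness", "kurtosis"),
                 sep = "_")] <-
        c(ms$mean, ms$variance, ms$skewness, ms$kurtosis)
      if (ms$degenerate) degen <- c(degen, a)
    }
    if (any(!is.finite(vals))) {
      abort("Non-finite moment feature computed; check input attributes.")
    }
  }
  dplyr::bind_cols(
    tibble(hpf_id = hpf_id, n_nuclei = n),
    as_tibble(as.list(vals)),
    tibble(flagged = flagged,
           degenerate = paste(degen, collapse = ",")))
}

#' Aggregate per-field features into case profiles
#'
#' Element-wise unweighted arithmetic mean of the 28-feature vectors over
#' each case's unflagged fields, with the diagnosis label and CD8/CD56
#' status carried over from the manifest. Cases whose fields are all
#' flagged are excluded and listed in the `"excluded_cases"` attribute.
#'
#' @param hpf_features Tibble of per-field rows (from [hpf_moments()]),
#'   with a `case_id` column.
#' @param manifest Case manifest (see [read_case_manifest()]).
#' @return Tibble with one row per case: `case_id`, `diagnosis`, `cd8`,
#'   `cd56`, `n_hpf` (used), `n_flagged`, and the 28 features.
#' @export
aggregate_cases <- function(hpf_features, manifest) {
  manifest <- read_case_manifest(manifest)
  if (!"case_id" %in% names(hpf_features)) {
    abort("`hpf_features` needs a `case_id` column.")
  }
  fn <- feature_names()
  counts <- hpf_features |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(n_input = dplyr::n(),
                     n_flagged = sum(.data$flagged), .groups = "drop")
  used <- hpf_features |> dplyr::filter(!.data$flagged)
  prof <- used |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(n_hpf = dplyr::n(),
                     dplyr::across(dplyr::all_of(fn), mean),
                     .groups = "drop")
  excluded <- setdiff(counts$case_id, prof$case_id)
  if (length(excluded)) {
    warn(sprintf("Excluded case(s) with no usable field: %s",
                 paste(excluded, collapse = ", ")))
  }
  out <- manifest |>
    dplyr::select("case_id", "diagnosis", "cd8", "cd56") |>
    dplyr::inner_join(prof, by = "case_id") |>
    dplyr::left_join(dplyr::select(counts, "case_id", "n_flagged"),
                     by = "case_id") |>
    dplyr::relocate("n_flagged", .after = "n_hpf")
  attr(out, "excluded_cases") <- excluded
  out
}

#' Build the case-level feature matrix for classification
#'
#' Rows are cases, columns the 28 morphometric features plus, optionally,
#' two binary immunohistochemistry columns (`cd8_pos`, `cd56_pos`).
#' Labels are MEITL = 0, ITCL-NOS = 1. Borderline cases are removed from
#' the labelled matrix by default and retained separately for
#' prediction-only use.
#'
#' @param cases Case profiles from [aggregate_cases()].
#' @param include_ihc Add the CD8/CD56 indicator columns.
#' @param exclude_borderline Hold borderline cases out of the labelled rows.
#' @return Object of class `feature_matrix`: list with `x` (numeric
#'   matrix), `labels` (0/1), `case_ids`, `feature_names`, and
#'   `borderline` (held-out rows as a matrix, possibly 0-row).
#' @export
build_feature_matrix <- function(cases, include_ihc = FALSE,
                                 exclude_borderline = TRUE) {
  fn <- feature_names()
  miss <- setdiff(c(fn, "case_id", "diagnosis"), names(cases))
  if (length(miss)) {
    abort(paste0("`cases` is missing columns: ", paste(miss, collapse = ", ")))
  }
  cols <- fn
  cases <- as_tibble(cases)
  if (include_ihc) {
    unk <- cases$case_id[cases$cd8 == "unknown" | cases$cd56 == "unknown"]
    if (length(unk)) {
      abort(paste0("include_ihc = TRUE but IHC status unknown for: ",
                   paste(unk, collapse = ", ")))
    }
    cases$cd8_pos <- as.numeric(cases$cd8 == "+")
    cases$cd56_pos <- as.numeric(cases$cd56 == "+")
    cols <- c(fn, "cd8_pos", "cd56_pos")
  }
  is_bl <- cases$diagnosis == "borderline"
  labelled <- if (exclude_borderline) cases[!is_bl, ] else cases
  if (!exclude_borderline && any(is_bl)) {
    abort("Borderline cases carry no binary label; keep exclude_borderline = TRUE to train.")
  }
  x <- as.matrix(labelled[, cols])
  rownames(x) <- labelled$case_id
  if (anyNA(x)) abort("Feature matrix contains missing values.")
  bl <- cases[is_bl & exclude_borderline, ]
  xb <- as.matrix(bl[, cols])
  rownames(xb) <- bl$case_id
  structure(list(
    x = x,
    labels = as.integer(labelled$diagnosis == "ITCL-NOS"),
    case_ids = labelled$case_id,
    feature_names = cols,
    borderline = xb),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d cases x %d features (%d MEITL, %d ITCL-NOS), %d borderline held out\n",
              nrow(x$x), ncol(x$x), sum(x$labels == 0), sum(x$labels == 1),
              nrow(x$borderline)))
  invisible(x)
}
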