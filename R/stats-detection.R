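# Detection evaluation: greedy IoU matching of scored predictions to
# ground-truth instances, precision/recall, and average precision as the
# area under the stepwise precision-recall curve.

as_geometry_list <- function(x, what = "geometry") {
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x)) abort(sprintf("`%s` must be a list of polygon matrices.", what))
  lapply(x, function(g) {
    g <- as_polygon_matrix(g)
    if (polygon_area(g) <= 0) abort("Negative or zero-area geometry.")
    g
  })
}

#' Average precision of a detector at an IoU threshold
#'
#' Matches scored predicted instances to ground-truth instances greedily in
#' descending score order (score ties broken by input order); a prediction
#' matches the unmatched truth of highest IoU provided IoU >= `iou`, and
#' each truth can be used once. Precision and recall are accumulated over
#' the score sweep and AP is the area under the stepwise precision-recall
#' curve using all-points interpolation (precision envelope); an 11-point
#' alternative is available.
#'
#' @param predictions List of polygon matrices (micrometres), one per
#'   detected instance.
#' @param scores Numeric confidence scores, one per prediction.
#' @param truth List of ground-truth polygon matrices.
#' @param iou IoU threshold in (0, 1).
#' @param interpolation `"all_points"` (default) or `"eleven_point"`.
#' @return Object of class `detection_eval`: `ap`, `precision`, `recall`
#'   (at the full prediction set), the threshold `curve` tibble and the
#'   `matches` tibble.
#' @export
detection_ap <- function(predictions, scores, truth, iou = 0.5,
                         interpolation = c("all_points", "eleven_point")) {
  interpolation <- match.arg(interpolation)
  if (iou <= 0 || iou >= 1) abort("`iou` must lie in (0, 1).")
  predictions <- as_geometry_list(predictions, "predictions")
  truth <- as_geometry_list(truth, "truth")
  if (length(scores) != length(predictions)) {
    abort("One score per prediction is required.")
  }
  np <- length(predictions); nt <- length(truth)
  if (np == 0) {
    out <- list(ap = 0, precision = NA_real_, recall = 0,
                curve = tibble(score = numeric(), tp = integer(),
                               fp = integer(), precision = numeric(),
                               recall = numeric()),
                matches = tibble(prediction = integer(), truth = integer(),
                                 iou = numeric(), score = numeric()),
                iou_threshold = iou)
    return(structure(out, class = "detection_eval"))
  }
  ord <- order(-scores) # stable: ties keep input order
  used <- logical(nt)
  tp <- integer(np)
  match_rows <- list()
  # bounding boxes let non-overlapping pairs skip the IoU computation
  bbox <- function(p) c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2]))
  bb_p <- lapply(predictions, bbox)
  bb_t <- lapply(truth, bbox)
  for (k in seq_len(np)) {
    i <- ord[k]
    best_j <- 0L; best_iou <- -1
    for (j in seq_len(nt)) {
      if (used[j]) next
      if (bb_p[[i]][1] > bb_t[[j]][2] || bb_p[[i]][2] < bb_t[[j]][1] ||
          bb_p[[i]][3] > bb_t[[j]][4] || bb_p[[i]][4] < bb_t[[j]][3]) next
      v <- polygon_iou(predictions[[i]], truth[[j]])
      if (v >= iou && v > best_iou) {
        best_iou <- v; best_j <- j
      }
    }
    if (best_j > 0L) {
      used[best_j] <- TRUE
      tp[k] <- 1L
      match_rows[[length(match_rows) + 1L]] <-
        tibble(prediction = i, truth = best_j, iou = best_iou,
               score = scores[i])
    }
  }
  ctp <- cumsum(tp)
  cfp <- seq_len(np) - ctp
  prec <- ctp / (ctp + cfp)
  rec <- if (nt > 0) ctp / nt else rep(0, np)
  ap <- if (nt == 0) 0 else average_precision(prec, rec, interpolation)
  out <- list(ap = ap,
              precision = prec[np], recall = rec[np],
              curve = tibble(score = scores[ord], tp = tp,
                             fp = 1L - tp, precision = prec, recall = rec),
              matches = dplyr::bind_rows(match_rows),
              iou_threshold = iou)
  structure(out, class = "detection_eval")
}

average_precision <- function(precision, recall, interpolation) {
  # precision envelope: running maximum from the right
  mrec <- c(0, recall)
  mpre <- c(precision[1], precision)
  mpre <- rev(cummax(rev(mpre)))
  if (interpolation == "eleven_point") {
    r <- seq(0, 1, by = 0.1)
    p <- vapply(r, function(t) {
      i <- which(mrec >= t)
      if (length(i) == 0) 0 else max(mpre[i])
    }, numeric(1))
    return(mean(p))
  }
  sum(diff(mrec) * mpre[-1])
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("Detection at IoU >= %.2f: AP = %.4f, precision = %.4f, recall = %.4f (%d matches)\n",
              x$iou_threshold, x$ap, x$precision, x$recall, nrow(x$matches)))
  invisible(x)
}

#' @export
tidy.detection_eval <- function(x, ...) x$curve

#' @export
glance.detection_eval <- function(x, ...) {
  tibble(ap = x$ap, precision = x$precision, recall = x$recall,
         iou_threshold = x$iou_threshold, n_matched = nrow(x$matches))
}

#' @export
autoplot.detection_eval <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("AP = %.3f at IoU %.2f",
                                  object$ap, object$iou_threshold)) +
    ggplot2::theme_minimal()
}
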