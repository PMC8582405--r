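# ROC/AUC with DeLong structural-component variance, and the paired DeLong
# test for comparing two correlated AUCs.

# psi(x, y): 1 if x > y, 0.5 if tied, 0 otherwise (Mann-Whitney kernel).
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  # midrank formulation of the structural components
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi),   # one per positive
       v01 = colMeans(psi),   # one per negative
       auc = mean(psi), m = m, n = n)
}

#' ROC area with DeLong variance
#'
#' AUC by the Mann-Whitney statistic with midrank tie handling, the DeLong
#' structural-component variance estimate, and a Wald 95% confidence
#' interval (clipped to \[0, 1\]). Scores are oriented so that higher
#' values indicate the positive class (label 1).
#'
#' @param scores Numeric scores or probabilities, one per case.
#' @param labels Binary labels (0/1 or logical); both classes must be
#'   present.
#' @param conf_level Confidence level for the Wald interval.
#' @return Object of class `roc_result`: `auc`, `var`, `ci`, the score and
#'   label vectors, and the structural components.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have the same length.")
  }
  if (!all(labels %in% c(0L, 1L))) abort("`labels` must be binary 0/1.")
  if (length(unique(labels)) < 2) {
    abort("Both classes must be present to compute an ROC.")
  }
  cmp <- delong_components(scores, labels)
  v <- (if (cmp$m > 1) var(cmp$v10) / cmp$m else 0) +
       (if (cmp$n > 1) var(cmp$v01) / cmp$n else 0)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(cmp$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  structure(list(auc = cmp$auc, var = v, ci = ci,
                 scores = scores, labels = labels,
                 v10 = cmp$v10, v01 = cmp$v01,
                 conf_level = conf_level),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC AUC = %.4f (%d%% CI %.4f-%.4f), DeLong var = %.3g\n",
              x$auc, round(100 * x$conf_level), x$ci[1], x$ci[2], x$var))
  invisible(x)
}

#' DeLong test comparing two AUCs
#'
#' Two-sided z-test for the difference of two AUCs. For paired inputs
#' (both ROC results computed on the same cases and labels, the usual
#' model-comparison setting) the covariance of the structural components is
#' subtracted; for unpaired inputs the covariance is set to zero with a
#' warning.
#'
#' @param a,b `roc_result` objects from [roc_auc()].
#' @param paired Are the two score sets computed on the identical case set?
#' @return Tibble: `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
delong_test <- function(a, b, paired = TRUE) {
  if (!inherits(a, "roc_result") || !inherits(b, "roc_result")) {
    abort("`a` and `b` must be roc_result objects.")
  }
  if (paired) {
    if (length(a$labels) != length(b$labels) ||
        !all(a$labels == b$labels)) {
      abort("Paired comparison requires identical case sets and labels.")
    }
    cv <- (if (length(a$v10) > 1) stats::cov(a$v10, b$v10) / length(a$v10) else 0) +
          (if (length(a$v01) > 1) stats::cov(a$v01, b$v01) / length(a$v01) else 0)
  } else {
    warn("Unpaired comparison: DeLong covariance set to 0.")
    cv <- 0
  }
  delta <- a$auc - b$auc
  se <- sqrt(max(a$var + b$var - 2 * cv, 0))
  z <- if (delta == 0) 0 else if (se == 0) sign(delta) * Inf else delta / se
  tibble(auc_a = a$auc, auc_b = b$auc, delta = delta, z = z,
         p_value = if (is.infinite(z)) 0 else 2 * pnorm(-abs(z)))
}

#' @export
tidy.roc_result <- function(x, ...) {
  ord <- order(x$scores, decreasing = TRUE)
  s <- x$scores[ord]; l <- x$labels[ord]
  # one ROC point per distinct threshold (last index of each tied block)
  last <- rev(!duplicated(rev(s)))
  tibble(threshold = s[last],
         tpr = cumsum(l)[last] / sum(l),
         fpr = cumsum(1 - l)[last] / sum(1 - l))
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, var = x$var,
         ci_low = x$ci[1], ci_high = x$ci[2],
         n_pos = sum(x$labels == 1), n_neg = sum(x$labels == 0))
}

#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- tidy(object)
  pts <- dplyr::bind_rows(tibble(threshold = Inf, tpr = 0, fpr = 0), pts)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f (%.3f-%.3f)",
                                  object$auc, object$ci[1], object$ci[2])) +
    ggplot2::theme_minimal()
}
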