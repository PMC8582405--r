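# Repeated-measures comparison of per-field feature scores between disease
# subtypes: a two-level nested ANOVA (disease type fixed; cases random
# within type; field replicates within case). The group F-statistic uses
# the case-within-group mean square as its denominator, so field-to-field
# sampling noise does not masquerade as a subtype effect.

#' Nested ANOVA F-test for a subtype effect on one feature
#'
#' Models a per-field feature score as overall mean + disease-type effect +
#' random case effect + residual. For balanced designs (equal replicates
#' per case) the group effect is tested with `F = MS_group /
#' MS_case_within_group` on (g - 1, N_cases - g) degrees of freedom, fitted
#' via `aov()` with a case error stratum. Unbalanced designs fall back to a
#' random-intercept mixed model with Satterthwaite degrees of freedom
#' (`lmerTest`), flagged in the result as an extension.
#'
#' @param data Data frame with one row per field.
#' @param value,group,case Column names (strings) of the feature score, the
#'   disease-type factor, and the case identifier.
#' @return Object of class `nested_anova`: tibble row with group means, F,
#'   degrees of freedom, p-value, variance components for case and
#'   residual, and flags `degenerate` and `method`.
#' @export
nested_anova_f <- function(data, value = "value", group = "group",
                           case = "case") {
  d <- tibble(y = as.numeric(data[[value]]),
              grp = factor(data[[group]]),
              case = factor(data[[case]]))
  if (anyNA(d)) abort("Missing values in the ANOVA input.")
  g <- nlevels(d$grp)
  if (g < 2) abort("Need at least two groups.")
  cases_per_group <- d |>
    dplyr::distinct(.data$grp, .data$case) |>
    dplyr::count(.data$grp)
  if (any(cases_per_group$n < 2)) {
    abort("Each group needs at least 2 cases (denominator df would be zero).")
  }
  reps <- d |> dplyr::count(.data$case)
  if (any(reps$n < 2)) abort("Each case needs at least 2 field replicates.")
  means <- tapply(d$y, d$grp, mean)
  n_cases <- nlevels(d$case)
  if (var(d$y) == 0) {
    res <- tibble(group_means = list(means), f = NA_real_,
                  df1 = g - 1L, df2 = n_cases - g,
                  p_value = NA_real_, sigma2_case = 0, sigma2_resid = 0,
                  degenerate = TRUE, method = "balanced")
    return(structure(res, class = c("nested_anova", class(res))))
  }
  balanced <- length(unique(reps$n)) == 1
  if (balanced) {
    fit <- aov(y ~ grp + Error(case), data = d)
    s <- summary(fit)
    tab_case <- s[["Error: case"]][[1]]
    tab_within <- s[["Error: Within"]][[1]]
    f <- tab_case["grp", "F value"]
    df1 <- tab_case["grp", "Df"]
    df2 <- tab_case["Residuals", "Df"]
    p <- tab_case["grp", "Pr(>F)"]
    ms_case <- tab_case["Residuals", "Mean Sq"]
    ms_within <- tab_within["Residuals", "Mean Sq"]
    n_rep <- reps$n[1]
    res <- tibble(group_means = list(means), f = f, df1 = df1, df2 = df2,
                  p_value = p,
                  sigma2_case = max((ms_case - ms_within) / n_rep, 0),
                  sigma2_resid = ms_within,
                  degenerate = FALSE, method = "balanced")
  } else {
    fit <- lmerTest::lmer(y ~ grp + (1 | case), data = d)
    at <- stats::anova(fit, ddf = "Satterthwaite")
    vc <- as.data.frame(lme4::VarCorr(fit))
    res <- tibble(group_means = list(means),
                  f = at["grp", "F value"],
                  df1 = at["grp", "NumDF"], df2 = at["grp", "DenDF"],
                  p_value = at["grp", "Pr(>F)"],
                  sigma2_case = vc$vcov[vc$grp == "case"],
                  sigma2_resid = vc$vcov[vc$grp == "Residual"],
                  degenerate = FALSE, method = "satterthwaite")
  }
  structure(res, class = c("nested_anova", class(res)))
}

#' Per-feature subtype comparison table
#'
#' Runs the nested ANOVA of [nested_anova_f()] for each of the 28 moment
#' features over per-field feature rows, and summarises each feature as
#' case-level group means with SD, the F statistic and p-value -- the
#' standard per-feature comparison table for a two-subtype cohort. An
#' optional multiplicity correction over the 28 tests is available but off
#' by default.
#'
#' @param hpf_features Per-field feature tibble with `case_id` plus the 28
#'   feature columns.
#' @param manifest Case manifest; borderline cases are excluded.
#' @param features Feature columns to test (default all 28).
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (`"none"`, `"bonferroni"`, `"BH"`, ...).
#' @return Tibble: one row per feature with group means +- SD (over case
#'   averages), F, degrees of freedom and p-value.
#' @export
feature_anova <- function(hpf_features, manifest, features = feature_names(),
                          p_adjust = "none") {
  manifest <- read_case_manifest(manifest)
  keep <- manifest[manifest$diagnosis != "borderline", ]
  d <- dplyr::inner_join(hpf_features,
                         dplyr::select(keep, "case_id", "diagnosis"),
                         by = "case_id")
  if (any(d$flagged %||% FALSE)) d <- d[!d$flagged, ]
  rows <- purrr::map(features, function(f) {
    an <- nested_anova_f(d, value = f, group = "diagnosis", case = "case_id")
    by_case <- d |>
      dplyr::group_by(.data$case_id, .data$diagnosis) |>
      dplyr::summarise(v = mean(.data[[f]]), .groups = "drop")
    cm <- by_case |>
      dplyr::group_by(.data$diagnosis) |>
      dplyr::summarise(mean = mean(.data$v), sd = sd(.data$v),
                       .groups = "drop")
    tibble(feature = f,
           mean_meitl = cm$mean[cm$diagnosis == "MEITL"],
           sd_meitl = cm$sd[cm$diagnosis == "MEITL"],
           mean_itcl = cm$mean[cm$diagnosis == "ITCL-NOS"],
           sd_itcl = cm$sd[cm$diagnosis == "ITCL-NOS"],
           f_statistic = an$f, df1 = an$df1, df2 = an$df2,
           p_value = an$p_value, degenerate = an$degenerate)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' @export
tidy.nested_anova <- function(x, ...) {
  tibble(term = "group",
         statistic = x$f, df1 = x$df1, df2 = x$df2, p.value = x$p_value,
         sigma2_case = x$sigma2_case, sigma2_resid = x$sigma2_resid,
         method = x$method)
}
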