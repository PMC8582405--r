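# Case-level MEITL vs ITCL-NOS classification: gradient-boosted trees with
# iterative split-weight ("weight by Gini") feature selection, random-search
# hyper-parameter tuning, and 3-fold cross-validation stratified by class at
# the case level (so fields of one case can never straddle folds).

xgb_fit <- function(x, y, params, nrounds, nthread = 1L) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = nthread)
  xgboost::xgb.train(
    params = c(params, list(objective = "binary:logistic",
                            eval_metric = "logloss",
                            nthread = nthread)),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

# Split-level importance parsed from the model dump. xgb.importance() in
# the installed xgboost errors on boosters whose forest uses a single
# feature, so gain/cover/weight are aggregated from xgb.dump() text, which
# is stable across versions. Gains and covers are normalised to sum to 1,
# matching the conventional importance table.
dump_importance <- function(booster) {
  txt <- xgboost::xgb.dump(booster, with_stats = TRUE)
  splits <- grep("gain=", txt, value = TRUE)
  if (length(splits) == 0) {
    return(tibble(feature = character(), gain = numeric(),
                  cover = numeric(), frequency = numeric()))
  }
  feat <- sub("^.*\\[([^<]+)<.*$", "\\1", splits)
  gain <- as.numeric(sub("^.*gain=([-0-9.eE+]+).*$", "\\1", splits))
  cover <- as.numeric(sub("^.*cover=([-0-9.eE+]+).*$", "\\1", splits))
  agg <- tibble(feature = feat, gain = gain, cover = cover) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(gain = sum(.data$gain), cover = sum(.data$cover),
                     frequency = dplyr::n(), .groups = "drop")
  agg$gain <- agg$gain / sum(agg$gain)
  agg$cover <- agg$cover / sum(agg$cover)
  agg$frequency <- agg$frequency / sum(agg$frequency)
  agg
}

xgb_logloss <- function(model, x, y) {
  p <- pmin(pmax(predict(model, xgboost::xgb.DMatrix(x, nthread = 1L)),
                 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# min_child_weight is lowered from its usual default because case-level
# cohorts are tiny (a fold's training split can hold under a dozen cases);
# at the logistic loss a leaf of 4 cases carries hessian ~1, exactly the
# stock threshold, which silences all splits. Column subsampling during
# the selection fits makes elimination target genuinely dead features
# rather than everything shadowed by the single greediest one: each tree
# sees a feature subset, so informative-but-correlated features keep a
# nonzero split weight while uninformative ones still drop.
default_selection_params <- function() {
  list(max_depth = 3, eta = 0.1, subsample = 1, colsample_bytree = 0.7,
       min_child_weight = 0.5)
}

#' Iterative split-weight feature selection
#'
#' Repeatedly fits a boosted-tree model with binary cross-entropy loss on
#' the current feature set and drops every feature with zero split weight
#' (never used in any tree), until the set is stable or `max_iter` is
#' reached. This parameter-free elimination thins out redundant features:
#' once one of a collinear pair carries the splits, the other's weight
#' drops to zero.
#'
#' @param x Numeric matrix (cases x features) or a `feature_matrix`.
#' @param y Binary labels (ignored when `x` is a `feature_matrix`).
#' @param max_iter Maximum elimination rounds.
#' @param params Booster parameters used during selection.
#' @param nrounds Boosting rounds per selection fit.
#' @return Character vector of selected feature names (attribute
#'   `"n_iter"` records the rounds used).
#' @export
iterative_gini_selection <- function(x, y = NULL, max_iter = 10L,
                                     params = default_selection_params(),
                                     nrounds = 100L) {
  if (inherits(x, "feature_matrix")) {
    y <- x$labels
    x <- x$x
  }
  if (ncol(x) < 1) abort("Need at least one feature.")
  if (min(table(y)) < 2) abort("Need at least 2 cases per class.")
  features <- colnames(x)
  if (ncol(x) == 1) {
    return(structure(features, n_iter = 0L))
  }
  for (it in seq_len(max_iter)) {
    fit <- xgb_fit(x[, features, drop = FALSE], y, params, nrounds)
    used <- dump_importance(fit)$feature
    if (length(used) == 0) {
      abort("All features eliminated: no split was made (degenerate data).")
    }
    if (setequal(used, features) || length(used) <= 1) {
      features <- used
      return(structure(features, n_iter = it))
    }
    features <- used
  }
  structure(features, n_iter = max_iter)
}

#' Random-search hyper-parameter draws
#'
#' The documented search space for the booster: `max_depth` in 2..6,
#' learning rate log-uniform on \[0.01, 0.3\], `nrounds` in 50..400,
#' `subsample` uniform on \[0.6, 1\], `colsample_bytree` uniform on
#' \[0.5, 1\]. Draws come from the current RNG state.
#'
#' @param n_draws Number of configurations to draw.
#' @return Tibble of configurations.
#' @export
random_search_grid <- function(n_draws = 50L) {
  tibble(
    max_depth = sample(2:6, n_draws, replace = TRUE),
    eta = 10^runif(n_draws, log10(0.01), log10(0.3)),
    nrounds = sample(50:400, n_draws, replace = TRUE),
    subsample = runif(n_draws, 0.6, 1),
    colsample_bytree = runif(n_draws, 0.5, 1))
}

# Stratified assignment of case indices to folds.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Stratified inner split: TRUE = inner-train, FALSE = inner-validation.
stratified_split <- function(labels, frac = 0.75) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    k <- max(1L, min(length(idx) - 1L, round(frac * length(idx))))
    train[idx[seq_len(k)]] <- TRUE
  }
  train
}

tune_one_split <- function(x, y, grid, val_frac = 0.25) {
  inner <- stratified_split(y, frac = 1 - val_frac)
  losses <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    fit <- xgb_fit(x[inner, , drop = FALSE], y[inner],
                   params = list(max_depth = g$max_depth, eta = g$eta,
                                 subsample = g$subsample,
                                 colsample_bytree = g$colsample_bytree,
                                 min_child_weight = 0.5),
                   nrounds = g$nrounds)
    xgb_logloss(fit, x[!inner, , drop = FALSE], y[!inner])
  }, numeric(1))
  grid[which.min(losses), ]
}

#' Tune and cross-validate the subtype classifier
#'
#' Outer 3-fold cross-validation stratified by class at the case level.
#' Within each training split the feature set is reduced by
#' [iterative_gini_selection()], then a random search over
#' [random_search_grid()] picks the configuration minimising binary
#' cross-entropy on an inner stratified validation split; the tuned model
#' is refit on the whole training split and scores the held-out fold. The
#' out-of-fold probabilities are pooled into a single ROC with a DeLong
#' confidence interval. A final model (same selection + tuning protocol on
#' all labelled cases) is kept for importance reporting and borderline
#' prediction. All randomness is governed by `seed`: folds, search draws
#' and therefore all recorded probabilities are reproducible.
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()].
#' @param seed Integer seed.
#' @param n_folds Number of outer folds.
#' @param n_draws Random-search budget per training split.
#' @param select Apply iterative feature selection within each training
#'   split.
#' @return Object of class `subtype_model`: out-of-fold prediction tibble,
#'   `roc` (a `roc_result`), per-fold selected features and tuned
#'   configurations, the final fitted booster with its feature set, and the
#'   configuration echo.
#' @export
tune_and_crossvalidate <- function(fm, seed = 1L, n_folds = 3L,
                                   n_draws = 50L, select = TRUE) {
  if (!inherits(fm, "feature_matrix")) {
    abort("`fm` must be a feature_matrix (see build_feature_matrix()).")
  }
  x <- fm$x; y <- fm$labels
  set.seed(seed)
  fold <- stratified_folds(y, n_folds)
  for (f in seq_len(n_folds)) {
    if (length(unique(y[fold != f])) < 2 || length(unique(y[fold == f])) < 2) {
      abort(sprintf(
        "Fold %d is missing a class; use a different stratification seed or fewer folds.", f))
    }
  }
  oof <- rep(NA_real_, length(y))
  fold_info <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    feats <- colnames(x)
    if (select) {
      feats <- iterative_gini_selection(x[tr, , drop = FALSE], y[tr])
    }
    grid <- random_search_grid(n_draws)
    best <- tune_one_split(x[tr, feats, drop = FALSE], y[tr], grid)
    fit <- xgb_fit(x[tr, feats, drop = FALSE], y[tr],
                   params = list(max_depth = best$max_depth, eta = best$eta,
                                 subsample = best$subsample,
                                 colsample_bytree = best$colsample_bytree,
                                 min_child_weight = 0.5),
                   nrounds = best$nrounds)
    oof[!tr] <- predict(fit, xgboost::xgb.DMatrix(
      x[!tr, feats, drop = FALSE], nthread = 1L))
    fold_info[[f]] <- list(features = feats, config = best, fit = fit)
  }
  roc <- roc_auc(oof, y)
  # final model on all labelled cases, same protocol
  feats_final <- colnames(x)
  if (select) feats_final <- iterative_gini_selection(x, y)
  best_final <- tune_one_split(x[, feats_final, drop = FALSE], y,
                               random_search_grid(n_draws))
  fit_final <- xgb_fit(x[, feats_final, drop = FALSE], y,
                       params = list(max_depth = best_final$max_depth,
                                     eta = best_final$eta,
                                     subsample = best_final$subsample,
                                     colsample_bytree = best_final$colsample_bytree,
                                     min_child_weight = 0.5),
                       nrounds = best_final$nrounds)
  structure(list(
    oof = tibble(case_id = fm$case_ids, label = y, fold = fold,
                 probability = oof),
    roc = roc,
    folds = fold_info,
    model = fit_final,
    features = feats_final,
    final_config = best_final,
    feature_matrix = fm,
    config = list(seed = seed, n_folds = n_folds, n_draws = n_draws,
                  select = select)),
    class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("<subtype_model> %d cases, %d-fold case-level CV\n",
              nrow(x$oof), x$config$n_folds))
  cat(sprintf("  out-of-fold AUC = %.4f (95%% CI %.4f-%.4f)\n",
              x$roc$auc, x$roc$ci[1], x$roc$ci[2]))
  cat(sprintf("  final feature set: %d features\n", length(x$features)))
  invisible(x)
}

#' Predict held-out borderline cases
#'
#' Scores borderline cases (excluded from every training fold) with the
#' final model: the probability of the ITCL-NOS class per case, plus the
#' hard label at threshold 0.5. Probabilities are always retained.
#'
#' @param model A `subtype_model`.
#' @param borderline Matrix of borderline profiles with the training
#'   columns; defaults to the borderline rows held in the model's feature
#'   matrix.
#' @param threshold Hard-label cutoff.
#' @return Tibble: `case_id`, `probability` (ITCL-NOS), `predicted`.
#' @export
predict_borderline <- function(model, borderline = NULL, threshold = 0.5) {
  if (!inherits(model, "subtype_model")) {
    abort("`model` must be a subtype_model.")
  }
  borderline <- borderline %||% model$feature_matrix$borderline
  if (is.data.frame(borderline)) {
    ids <- borderline$case_id %||% as.character(seq_len(nrow(borderline)))
    borderline <- as.matrix(
      borderline[, intersect(names(borderline), model$feature_matrix$feature_names)])
    rownames(borderline) <- ids
  }
  if (nrow(borderline) == 0) {
    return(tibble(case_id = character(), probability = numeric(),
                  predicted = character()))
  }
  miss <- setdiff(model$features, colnames(borderline))
  if (length(miss)) {
    abort(paste0("Borderline profiles lack training feature(s): ",
                 paste(miss, collapse = ", ")))
  }
  p <- predict(model$model, xgboost::xgb.DMatrix(
    borderline[, model$features, drop = FALSE], nthread = 1L))
  tibble(case_id = rownames(borderline) %||%
           as.character(seq_len(nrow(borderline))),
         probability = p,
         predicted = ifelse(p >= threshold, "ITCL-NOS", "MEITL"))
}

#' Gain-based feature importance
#'
#' Features ranked by total gain (the loss reduction attributed to splits
#' on the feature, summed over all trees), descending, ties broken
#' lexicographically. For a `subtype_model` the normalised gains are
#' averaged over the cross-validation fold models and the final refit --
#' ensemble-averaged importance is a lower-variance estimate than any
#' single booster's table, which matters with only a few dozen cases.
#' A model with no splits yields an empty table.
#'
#' @param model A `subtype_model` or a fitted `xgb.Booster`.
#' @return Tibble: `feature`, `gain`, `cover`, `frequency`, `rank`.
#' @export
feature_importance_gain <- function(model) {
  if (inherits(model, "subtype_model")) {
    boosters <- c(lapply(model$folds, `[[`, "fit"), list(model$model))
    boosters <- boosters[!vapply(boosters, is.null, logical(1))]
    tabs <- lapply(boosters, dump_importance)
    imp <- dplyr::bind_rows(tabs) |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(gain = sum(.data$gain) / length(tabs),
                       cover = sum(.data$cover) / length(tabs),
                       frequency = sum(.data$frequency) / length(tabs),
                       .groups = "drop")
    if (nrow(imp) == 0) {
      return(tibble(feature = character(), gain = numeric(),
                    cover = numeric(), frequency = numeric(),
                    rank = integer()))
    }
    out <- dplyr::arrange(imp, dplyr::desc(.data$gain), .data$feature)
    out$rank <- seq_len(nrow(out))
    return(out)
  }
  booster <- model
  if (!inherits(booster, "xgb.Booster")) {
    abort("`model` must be a fitted subtype_model or xgb.Booster.")
  }
  imp <- dump_importance(booster)
  if (nrow(imp) == 0) {
    return(tibble(feature = character(), gain = numeric(),
                  cover = numeric(), frequency = numeric(),
                  rank = integer()))
  }
  out <- dplyr::arrange(imp, dplyr::desc(.data$gain), .data$feature)
  out$rank <- seq_len(nrow(out))
  out
}

#' @export
tidy.subtype_model <- function(x, ...) x$oof

#' @export
glance.subtype_model <- function(x, ...) {
  tibble(auc = x$roc$auc, ci_low = x$roc$ci[1], ci_high = x$roc$ci[2],
         n_cases = nrow(x$oof), n_folds = x$config$n_folds,
         n_features_final = length(x$features),
         seed = x$config$seed)
}

#' @export
autoplot.subtype_model <- function(object, ...) {
  autoplot(object$roc) +
    ggplot2::labs(subtitle = sprintf(
      "%d-fold case-level cross-validation, %d cases",
      object$config$n_folds, nrow(object$oof)))
}
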