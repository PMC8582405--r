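# Small labelled matrices for classifier unit tests are simulated directly;
# the synthetic cohort is exercised in test-cohort.R and the acceptance
# suite.
sim_matrix <- function(n0 = 12, n1 = 10, p = 10, sep = 3, seed = 1) {
  set.seed(seed)
  n <- n0 + n1
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("c%02d", 1:n), paste0("f", 1:p)))
  y <- c(rep(0L, n0), rep(1L, n1))
  x[, 1] <- x[, 1] + sep * y
  structure(list(x = x, labels = y, case_ids = rownames(x),
                 feature_names = colnames(x),
                 borderline = x[0, , drop = FALSE]),
            class = "feature_matrix")
}

test_that("iterative selection keeps the separating feature and drops dead ones", {
  fm <- sim_matrix(sep = 4)
  set.seed(2)
  sel <- iterative_gini_selection(fm)
  expect_true("f1" %in% sel)
  expect_lt(length(sel), 10L)

  # single-feature floor
  one <- fm; one$x <- one$x[, 1, drop = FALSE]
  expect_identical(as.character(iterative_gini_selection(one)), "f1")

  # a constant column carries no split and is always dropped
  fm2 <- fm
  fm2$x <- cbind(fm2$x, constant = 1)
  set.seed(3)
  sel2 <- iterative_gini_selection(fm2)
  expect_false("constant" %in% sel2)
})

test_that("selection reaches a fixpoint with duplicated informative features", {
  fm <- sim_matrix(sep = 4)
  fm$x <- cbind(fm$x, f1_copy = fm$x[, "f1"])
  set.seed(4)
  sel1 <- iterative_gini_selection(fm)
  set.seed(4)
  sel2 <- iterative_gini_selection(fm)
  expect_identical(sel1, sel2)
  expect_true(any(c("f1", "f1_copy") %in% sel1))
  # rerunning selection on its own output can only thin the set further
  # (column subsampling makes marginal features stochastic) and always
  # retains the informative pair
  fm3 <- fm; fm3$x <- fm$x[, sel1, drop = FALSE]
  set.seed(4)
  sel3 <- iterative_gini_selection(fm3)
  expect_true(all(sel3 %in% sel1))
  expect_true(any(c("f1", "f1_copy") %in% sel3))
})

test_that("cross-validation partitions cases and is seed-reproducible", {
  fm <- sim_matrix(n0 = 12, n1 = 9, sep = 3)
  m1 <- tune_and_crossvalidate(fm, seed = 7, n_draws = 5)
  m2 <- tune_and_crossvalidate(fm, seed = 7, n_draws = 5)
  # every case appears in exactly one validation fold
  expect_identical(sort(m1$oof$case_id), sort(fm$case_ids))
  expect_true(all(table(m1$oof$fold) >= 2))
  expect_true(all(!is.na(m1$oof$probability)))
  expect_true(all(m1$oof$probability >= 0 & m1$oof$probability <= 1))
  # bit-for-bit reproducibility under the seed
  expect_identical(m1$oof$probability, m2$oof$probability)
  expect_identical(m1$roc$auc, m2$roc$auc)
  # strong separation is recovered out of fold
  expect_gte(m1$roc$auc, 0.9)
})

test_that("permuted labels give chance-level AUC", {
  fm <- sim_matrix(n0 = 12, n1 = 9, sep = 3)
  set.seed(9)
  aucs <- replicate(25, {
    fmp <- fm
    fmp$labels <- sample(fmp$labels)
    tune_and_crossvalidate(fmp, seed = sample.int(1e6, 1), n_draws = 2,
                           select = FALSE)$roc$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("borderline cases are scored by the final model only", {
  fm <- sim_matrix(sep = 4)
  # hold out two synthetic borderline profiles mid-way between the classes
  bl <- rbind(colMeans(fm$x[fm$labels == 0, , drop = FALSE]),
              colMeans(fm$x[fm$labels == 1, , drop = FALSE]))
  rownames(bl) <- c("B_meitl_like", "B_itcl_like")
  fm$borderline <- bl
  m <- tune_and_crossvalidate(fm, seed = 5, n_draws = 5)
  out <- predict_borderline(m)
  expect_identical(out$case_id, c("B_meitl_like", "B_itcl_like"))
  expect_true(all(out$probability >= 0 & out$probability <= 1))
  # class-centroid profiles land on their class side
  expect_lt(out$probability[1], 0.5)
  expect_gt(out$probability[2], 0.5)
  expect_identical(out$predicted, c("MEITL", "ITCL-NOS"))

  # empty borderline set is vacuously fine
  m$feature_matrix$borderline <- fm$x[0, , drop = FALSE]
  expect_identical(nrow(predict_borderline(m)), 0L)

  # feature mismatch is an error
  bl_wrong <- bl
  colnames(bl_wrong) <- paste0("g", seq_len(ncol(bl_wrong)))
  expect_error(predict_borderline(m, bl_wrong), "lack training feature")
})

test_that("gain importance ranks the informative feature first", {
  fm <- sim_matrix(sep = 5)
  set.seed(6)
  fit <- nucmorph:::xgb_fit(fm$x, fm$labels,
                            nucmorph:::default_selection_params(), 100L)
  imp <- feature_importance_gain(fit)
  expect_identical(imp$feature[1], "f1")
  expect_true(all(imp$gain >= 0 & is.finite(imp$gain)))
  expect_identical(imp$rank, seq_len(nrow(imp)))
  # a splitless model (constant feature) yields an empty table
  xc <- matrix(1, nrow(fm$x), 1, dimnames = list(rownames(fm$x), "const"))
  fit0 <- nucmorph:::xgb_fit(xc, fm$labels,
                             nucmorph:::default_selection_params(), 10L)
  expect_identical(nrow(feature_importance_gain(fit0)), 0L)
})

test_that("degenerate fold layouts are rejected with advice", {
  fm <- sim_matrix(n0 = 12, n1 = 2, sep = 3)
  expect_error(tune_and_crossvalidate(fm, seed = 1, n_draws = 2),
               "missing a class")
})
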