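two_pass_moments <- function(x) {
  # naive sum-based oracle, written independently of moment_stats()
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  c(mean = m, variance = m2, skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

test_that("population moments match the two-pass oracle on random populations", {
  set.seed(31)
  for (n in c(8, 50, 400, 2000)) {
    x <- rlnorm(n, 1, 0.6)
    ms <- moment_stats(x)
    o <- two_pass_moments(x)
    expect_equal(ms$mean, o[["mean"]], tolerance = 1e-9)
    expect_equal(ms$variance, o[["variance"]], tolerance = 1e-9)
    expect_equal(ms$skewness, o[["skewness"]], tolerance = 1e-9)
    expect_equal(ms$kurtosis, o[["kurtosis"]], tolerance = 1e-9)
  }
})

test_that("normal populations give skewness 0 and non-excess kurtosis 3", {
  set.seed(32)
  x <- rnorm(1e5)
  ms <- moment_stats(x)
  expect_equal(ms$skewness, 0, tolerance = 0.05)
  expect_equal(ms$kurtosis, 3, tolerance = 0.05)
})

test_that("degenerate populations hit the documented sentinels", {
  ms <- moment_stats(rep(2.5, 20))
  expect_identical(ms$variance, 0)
  expect_identical(ms$skewness, 0)
  expect_identical(ms$kurtosis, 3)
  expect_true(ms$degenerate)
})

fake_morph <- function(n, hpf_id = "h1", constant = FALSE) {
  vals <- if (constant) matrix(1, n, 7) else matrix(rlnorm(7 * n), n, 7)
  colnames(vals) <- morphometric_attributes()
  dplyr::bind_cols(tibble::tibble(nucleus_id = seq_len(n), hpf_id = hpf_id),
                   tibble::as_tibble(vals))
}

test_that("per-field vectors have exactly the 28 frozen features", {
  set.seed(33)
  v <- hpf_moments(fake_morph(40))
  expect_identical(names(v)[3:30], feature_names())
  expect_false(v$flagged)
  expect_identical(v$n_nuclei, 40L)

  # identical nuclei: zero variances, flagged skew/kurt sentinels
  vc <- hpf_moments(fake_morph(12, constant = TRUE))
  expect_true(all(vc[paste0(morphometric_attributes(), "_variance")] == 0))
  expect_true(all(strsplit(vc$degenerate, ",")[[1]] %in%
                  morphometric_attributes()))

  # small populations are flagged, not summarised
  vf <- hpf_moments(fake_morph(5))
  expect_true(vf$flagged)
  expect_true(all(is.na(vf[feature_names()])))
})

test_that("case aggregation is the unweighted mean over unflagged fields", {
  set.seed(34)
  manifest <- tibble::tibble(case_id = c("A", "B"),
                             diagnosis = c("MEITL", "ITCL-NOS"),
                             cd8 = c("+", "-"), cd56 = c("+", "-"))
  rows <- dplyr::bind_rows(
    dplyr::mutate(hpf_moments(fake_morph(30, "A1")), case_id = "A"),
    dplyr::mutate(hpf_moments(fake_morph(30, "A2")), case_id = "A"),
    dplyr::mutate(hpf_moments(fake_morph(30, "B1")), case_id = "B"),
    dplyr::mutate(hpf_moments(fake_morph(4, "B2")), case_id = "B"))
  out <- aggregate_cases(rows, manifest)
  expect_identical(out$n_hpf, c(2L, 1L))
  expect_identical(out$n_flagged, c(0L, 1L))
  # column-mean oracle
  fn <- feature_names()
  expect_equal(unlist(out[out$case_id == "A", fn]),
               colMeans(as.matrix(rows[rows$case_id == "A", fn])),
               tolerance = 1e-12)
  # single-field case equals that field's vector
  expect_equal(unlist(out[out$case_id == "B", fn]),
               unlist(rows[3, fn]), tolerance = 1e-12)
  # bookkeeping: inputs = used + flagged
  expect_identical(out$n_hpf + out$n_flagged, c(2L, 2L))

  # all fields flagged -> case excluded with a warning
  rows2 <- dplyr::mutate(hpf_moments(fake_morph(3, "B1")), case_id = "B")
  expect_warning(out2 <- aggregate_cases(dplyr::bind_rows(rows[1:2, ], rows2),
                                         manifest),
                 "Excluded")
  expect_identical(out2$case_id, "A")
})

test_that("feature matrix shapes follow the cohort disposition", {
  set.seed(35)
  n_cases <- 40L
  diagnosis <- c(rep("MEITL", 26), rep("ITCL-NOS", 10), rep("borderline", 4))
  fn <- feature_names()
  cases <- dplyr::bind_cols(
    tibble::tibble(case_id = sprintf("T%02d", 1:n_cases),
                   diagnosis = diagnosis,
                   cd8 = "+", cd56 = "-",
                   n_hpf = 10L, n_flagged = 0L),
    tibble::as_tibble(matrix(rnorm(n_cases * 28), n_cases, 28,
                             dimnames = list(NULL, fn))))
  fm <- build_feature_matrix(cases)
  expect_identical(dim(fm$x), c(36L, 28L))
  expect_identical(nrow(fm$borderline), 4L)
  expect_identical(sum(fm$labels == 0), 26L)
  expect_identical(sum(fm$labels == 1), 10L)

  fm2 <- build_feature_matrix(cases, include_ihc = TRUE)
  expect_identical(ncol(fm2$x), 30L)

  unk <- cases; unk$cd8[3] <- "unknown"
  expect_error(build_feature_matrix(unk, include_ihc = TRUE), "T03")
})

test_that("aggregation commutes with feature permutation", {
  set.seed(36)
  manifest <- tibble::tibble(case_id = "A", diagnosis = "MEITL",
                             cd8 = "+", cd56 = "+")
  rows <- dplyr::bind_rows(
    dplyr::mutate(hpf_moments(fake_morph(20, "A1")), case_id = "A"),
    dplyr::mutate(hpf_moments(fake_morph(20, "A2")), case_id = "A"))
  perm <- sample(feature_names())
  out1 <- aggregate_cases(rows, manifest)
  out2 <- aggregate_cases(rows[, c("case_id", "hpf_id", "n_nuclei", perm,
                                   "flagged", "degenerate")], manifest)
  expect_equal(out1[, feature_names()], out2[, feature_names()],
               tolerance = 1e-12)
})
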