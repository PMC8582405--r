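unit_square <- function(x = 0, y = 0, side = 1) {
  rbind(c(x, y), c(x + side, y), c(x + side, y + side), c(x, y + side))
}

test_that("a perfect detector scores precision = recall = AP = 1", {
  truth <- list(unit_square(0, 0), unit_square(5, 0), unit_square(10, 0))
  ev <- detection_ap(truth, c(0.2, 0.9, 0.5), truth)
  expect_identical(ev$precision, 1)
  expect_identical(ev$recall, 1)
  expect_identical(ev$ap, 1)
})

test_that("zero predictions give recall 0 and AP 0", {
  ev <- detection_ap(list(), numeric(0), list(unit_square()))
  expect_identical(ev$recall, 0)
  expect_identical(ev$ap, 0)
})

test_that("AP matches the brute-force precision-recall enumeration", {
  # 3 truths; 4 predictions: exact match (0.9), half-shifted (IoU 1/3, 0.8),
  # far away (0.7), exact match (0.6). At tau = 0.5 the TP sequence is
  # 1,0,0,1, whose all-points AP enumerates to 0.5.
  truth <- list(unit_square(0, 0), unit_square(5, 0), unit_square(10, 0))
  preds <- list(unit_square(0, 0), unit_square(5.5, 0), unit_square(20, 20),
                unit_square(10, 0))
  ev <- detection_ap(preds, c(0.9, 0.8, 0.7, 0.6), truth, iou = 0.5)
  expect_equal(ev$ap, 0.5, tolerance = 1e-12)
  expect_equal(ev$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(ev$precision, 1 / 2, tolerance = 1e-12)
  expect_identical(ev$curve$tp, c(1L, 0L, 0L, 1L))
  # each ground-truth instance is matched at most once
  expect_lte(max(table(ev$matches$truth)), 1L)
})

test_that("AP is invariant to monotone transformations of the scores", {
  set.seed(61)
  truth <- lapply(seq_len(5), function(i) unit_square(3 * i, 0))
  preds <- c(lapply(seq_len(4), function(i) unit_square(3 * i + 0.1, 0)),
             list(unit_square(40, 40)))
  s <- runif(5)
  ev1 <- detection_ap(preds, s, truth)
  ev2 <- detection_ap(preds, exp(5 * s), truth)
  expect_equal(ev1$ap, ev2$ap, tolerance = 1e-12)
  expect_identical(ev1$curve$tp, ev2$curve$tp)
})

test_that("the IoU threshold sweeps from permissive to exact matching", {
  truth <- list(unit_square(0, 0))
  nudged <- list(unit_square(0.9, 0)) # IoU = 0.1/1.9
  expect_identical(detection_ap(nudged, 1, truth, iou = 0.05)$recall, 1)
  expect_identical(detection_ap(nudged, 1, truth, iou = 0.9)$recall, 0)
  exact <- list(unit_square(0, 0))
  expect_identical(detection_ap(exact, 1, truth, iou = 0.99)$recall, 1)
})

test_that("greedy matching assigns ties by score order then larger IoU", {
  truth <- list(unit_square(0, 0, 2))
  # two predictions overlap the same truth; the higher-scored one wins
  p1 <- unit_square(0, 0, 2)         # IoU 1
  p2 <- unit_square(0.5, 0, 2)       # IoU 1.5*2 / ...
  ev <- detection_ap(list(p2, p1), c(0.9, 0.8), truth, iou = 0.3)
  expect_identical(ev$matches$prediction, 1L)
  expect_identical(ev$curve$tp, c(1L, 0L))

  expect_error(detection_ap(list(unit_square()), 1,
                            list(matrix(c(0, 0, 0, 0, 0, 0), 3, 2))),
               "zero-area")
  expect_error(detection_ap(list(unit_square()), 1, truth, iou = 1.2),
               "iou")
})

test_that("eleven-point interpolation is available as the alternative", {
  truth <- list(unit_square(0, 0), unit_square(5, 0), unit_square(10, 0))
  preds <- list(unit_square(0, 0), unit_square(5.5, 0), unit_square(20, 20),
                unit_square(10, 0))
  ev <- detection_ap(preds, c(0.9, 0.8, 0.7, 0.6), truth,
                     interpolation = "eleven_point")
  # recall points 0,...,0.6 have envelope precision 1 (up to recall 1/3)
  # then 0.5 up to 2/3: mean over the 11-grid
  expect_equal(ev$ap, mean(c(rep(1, 4), rep(0.5, 3), rep(0, 4))),
               tolerance = 1e-12)
})
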