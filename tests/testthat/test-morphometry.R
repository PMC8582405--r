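test_that("axis ratio and orientation follow the equivalent ellipse", {
  expect_equal(axis_ratio(make_circle(2)), 1, tolerance = 0.02)
  expect_equal(axis_ratio(make_square(3)), 1, tolerance = 1e-6)
  # closed form: second moments of an ellipse give exactly a/b
  expect_equal(axis_ratio(make_ellipse(4, 2)), 2, tolerance = 0.02)

  expect_equal(nucleus_orientation(make_ellipse(4, 2)), 0,
               tolerance = 0.01, ignore_attr = TRUE)
  o <- nucleus_orientation(make_ellipse(4, 2, theta = pi / 4))
  expect_equal(as.numeric(o), pi / 4, tolerance = 0.01)
  # disk is isotropic: convention value 0 with a flag
  od <- nucleus_orientation(make_circle(3), isotropy_tol = 1e-6)
  expect_identical(as.numeric(od), 0)
  expect_true(attr(od, "isotropic"))
})

test_that("circularity matches the frozen overlap oracles", {
  expect_equal(circularity(make_circle(3)), 1, tolerance = 0.01)
  # 10:1 rectangle; oracle value from an exact equal-area-disk overlap
  rect <- rbind(c(0, 0), c(10, 0), c(10, 1), c(0, 1))
  expect_equal(circularity(rect), 0.35210, tolerance = 0.01)
  # 2:1 ellipse; same oracle route
  expect_equal(circularity(make_ellipse(4, 2)), 0.78365, tolerance = 0.01)
  # intersection is a subset of the polygon for any convex shape
  set.seed(4)
  for (i in 1:10) {
    p <- make_ellipse(runif(1, 2, 5), runif(1, 1, 2), theta = runif(1, 0, pi))
    expect_lte(circularity(p), 1)
    expect_gt(circularity(p), 0)
  }
})

test_that("intensity entropy reproduces histogram limits", {
  sq <- make_square(6, c(1, 1)) # in um; patch pixel 0.1 um
  expect_equal(intensity_entropy(sq, constant_patch(57)), 0)

  # two intensities at equal frequency -> 1 bit
  m <- matrix(100, 80, 80)
  m[, seq(2, 80, by = 2)] <- 200
  expect_equal(intensity_entropy(sq, calibrated_patch(m, 0.1)), 1,
               tolerance = 1e-6)

  # i.i.d. uniform over 256 levels approaches 8 bits
  set.seed(9)
  big <- calibrated_patch(matrix(sample(0:255, 160^2, replace = TRUE),
                                 160, 160), 0.1)
  sq2 <- make_square(12, c(1.5, 1.5)) # ~14400 interior pixels
  expect_equal(intensity_entropy(sq2, big), 8, tolerance = 0.05)

  # no interior pixel is an error
  tiny <- make_square(0.04, c(0.52, 0.52))
  expect_error(intensity_entropy(tiny, constant_patch(1)), "No pixel centre")
})

test_that("irregularity vanishes for disks and grows with radial spread", {
  expect_lt(irregularity(make_circle(3)), 1e-3)
  star <- make_star(3, 5, k = 8L)
  disk_same_area <- make_circle(sqrt(polygon_area(star) / pi))
  expect_gt(irregularity(star), irregularity(disk_same_area))
  # reproducible to 1e-9 at fixed resampling density and equal to the
  # direct centroid-to-vertex computation
  ell <- make_ellipse(4, 2)
  v1 <- irregularity(ell, n_vertices = 64L)
  v2 <- irregularity(ell, n_vertices = 64L)
  expect_equal(v1, v2, tolerance = 1e-12)
  rb <- resample_boundary(ell, 64L)
  ctr <- polygon_centroid(ell)
  d <- sqrt((rb[, 1] - ctr[1])^2 + (rb[, 2] - ctr[2])^2)
  expect_equal(v1, mean(d^2) - mean(d)^2, tolerance = 1e-9)
})

test_that("compute_morphometrics composes the attributes with scaling laws", {
  # disk near the cohort-mean nucleus size, constant intensity
  disk <- make_circle(3.64, center = c(5, 5))
  out <- compute_morphometrics(disk, patch = constant_patch(80, 120, 120))
  expect_equal(out$area, pi * 3.64^2, tolerance = 0.005)
  expect_equal(out$axis_ratio, 1, tolerance = 0.02)
  expect_equal(out$circularity, 1, tolerance = 0.01)
  expect_lt(out$irregularity, 1e-3)
  expect_identical(out$entropy, 0)

  # scale equivariance: x2 scales area/irregularity x4, perimeter x2,
  # leaves the dimensionless attributes unchanged
  set.seed(7)
  p <- random_star_polygon()
  a <- suppressWarnings(compute_morphometrics(p))
  b <- suppressWarnings(compute_morphometrics(p * 2))
  expect_equal(b$area, 4 * a$area, tolerance = 1e-9)
  expect_equal(b$irregularity, 4 * a$irregularity, tolerance = 1e-9)
  expect_equal(b$perimeter, 2 * a$perimeter, tolerance = 1e-9)
  expect_equal(b$axis_ratio, a$axis_ratio, tolerance = 1e-9)
  expect_equal(b$circularity, a$circularity, tolerance = 1e-6)
  expect_equal(b$orientation, a$orientation, tolerance = 1e-9)
})

test_that("attributes are rotation- and translation-invariant; orientation equivariant", {
  set.seed(12)
  for (i in 1:8) {
    p <- make_ellipse(runif(1, 3, 5), runif(1, 1.5, 2.5), n = 128L)
    th <- runif(1, 0, pi)
    a <- suppressWarnings(compute_morphometrics(p))
    b <- suppressWarnings(compute_morphometrics(rotate_polygon(p, th)))
    shift <- p; shift[, 1] <- shift[, 1] + 7; shift[, 2] <- shift[, 2] - 3
    d <- suppressWarnings(compute_morphometrics(shift))
    expect_equal(b$area, a$area, tolerance = 1e-9)
    expect_equal(b$perimeter, a$perimeter, tolerance = 1e-6)
    expect_equal(b$axis_ratio, a$axis_ratio, tolerance = 1e-6)
    expect_equal(b$circularity, a$circularity, tolerance = 5e-3)
    expect_equal(b$irregularity, a$irregularity, tolerance = 1e-3)
    dth <- (b$orientation - a$orientation) %% pi
    expect_lt(min(abs(dth - th), abs(dth - th + pi), abs(dth - th - pi)),
              0.01)
    expect_equal(d$area, a$area, tolerance = 1e-9)
    expect_equal(d$orientation, a$orientation, tolerance = 1e-9)
    expect_equal(d$irregularity, a$irregularity, tolerance = 1e-9)
  }
})

test_that("invalid contours are reported with the nucleus id", {
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  tb <- tibble::tibble(nucleus_id = "n7", hpf_id = "h1",
                       polygon = list(bowtie))
  expect_error(suppressWarnings(compute_morphometrics(tb)), "n7")
})
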