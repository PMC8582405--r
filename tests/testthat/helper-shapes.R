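# Geometric fixtures used across the suite; everything is built in code.

make_circle <- function(r = 1, n = 256L, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

make_ellipse <- function(a = 4, b = 2, n = 256L, theta = 0, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(th); y <- b * sin(th)
  cbind(center[1] + x * cos(theta) - y * sin(theta),
        center[2] + x * sin(theta) + y * cos(theta))
}

make_square <- function(side = 1, corner = c(0, 0)) {
  rbind(corner,
        corner + c(side, 0),
        corner + c(side, side),
        corner + c(0, side))
}

make_star <- function(r_lo = 3, r_hi = 5, k = 8L, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- ifelse(seq_len(n) %% 2 == 0, r_lo, r_hi)[pmin(ceiling(th / (2 * pi) * n) + 1L, n)]
  r <- r_lo + (r_hi - r_lo) * (cos(k * th) + 1) / 2
  cbind(r * cos(th), r * sin(th))
}

# random simple (star-shaped) polygon about the origin
random_star_polygon <- function(n = 48L, r_base = 3) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- r_base * (1 + runif(n, -0.35, 0.35))
  cbind(r * cos(th), r * sin(th))
}

rotate_polygon <- function(xy, theta) {
  cbind(xy[, 1] * cos(theta) - xy[, 2] * sin(theta),
        xy[, 1] * sin(theta) + xy[, 2] * cos(theta))
}

constant_patch <- function(value = 100, nrow = 80, ncol = 80,
                           pixel_size = 0.1, origin = c(0, 0)) {
  calibrated_patch(matrix(value, nrow, ncol), pixel_size, origin)
}

# small per-case parameter list for generator unit tests
tiny_case_params <- function(mu_R = 3.5, cv_R = 0, a_shape = 0, cv_a = 0,
                             elong_mean = 1e-9, elong_shape = 2.5,
                             texture_sd = 10, texture_cv = 0) {
  list(mu_R = mu_R, cv_R = cv_R, a_shape = a_shape, cv_a = cv_a,
       elong_mean = elong_mean, elong_shape = elong_shape,
       texture_sd = texture_sd, texture_cv = texture_cv)
}
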