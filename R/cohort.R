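# Synthetic cohort generator: cases, fields, nuclear contours and intensity
# patches with class-conditional monomorphic (MEITL-like) versus pleomorphic
# (ITCL-NOS-like) statistical structure. Nuclei are star-shaped polygons
# r(theta) = R * (1 + sum_k a_k cos(k theta + phi_k)), k = 2..6, with an
# area-preserving anisotropic stretch for elongation and a random rotation;
# star-shaped boundaries are simple by construction. Every generated object
# is a deterministic function of the seed.

# Boundary harmonics k = 2..6. The k = 2 term is down-weighted because it
# acts as extra elongation (inflating the axis ratio), while k >= 3 terms
# carry the lobulated waviness that drives irregularity.
harmonic_orders <- 2:6
harmonic_weights <- c(0.35, 1, 0.45, 0.22, 0.12)

# Pleomorphism enters as a population mixture rather than a uniformly
# noisier law: mix_frac adds a subpopulation of enlarged cells (x mix_R,
# x mix_a waviness) and mix2_frac an independent subpopulation of
# normal-size strongly wavy cells (x mix2_a). The two fractions are
# jittered independently between cases (case_cv_mix), so size dispersion
# and contour dispersion vary semi-independently across a cohort.
class_law <- function(mu_R, cv_R, case_cv_R, a_shape, cv_a, case_cv_a,
                      elong_mean, elong_shape, texture_sd, texture_cv,
                      p_cd8, p_cd56, case_cv_disp = 0.10, cv_R_sym = 0,
                      mix_frac = 0, mix_R = 1.3, mix_a = 1.7,
                      mix2_frac = 0, mix2_a = 3.5,
                      mix2_bleb_h = 0, mix2_bleb_w = 0.12,
                      case_cv_mix = 0.25, case_cv_elong = 0.10) {
  list(mu_R = mu_R, cv_R = cv_R, case_cv_R = case_cv_R,
       cv_R_sym = cv_R_sym,
       a_shape = a_shape, cv_a = cv_a, case_cv_a = case_cv_a,
       elong_mean = elong_mean, elong_shape = elong_shape,
       texture_sd = texture_sd, texture_cv = texture_cv,
       p_cd8 = p_cd8, p_cd56 = p_cd56, case_cv_disp = case_cv_disp,
       mix_frac = mix_frac, mix_R = mix_R, mix_a = mix_a,
       mix2_frac = mix2_frac, mix2_a = mix2_a,
       mix2_bleb_h = mix2_bleb_h, mix2_bleb_w = mix2_bleb_w,
       case_cv_mix = case_cv_mix, case_cv_elong = case_cv_elong)
}

mix_laws <- function(a, b, w = 0.5) {
  out <- purrr::map2(a, b, function(u, v) (1 - w) * u + w * v)
  # borderline immunophenotype is MEITL-like: CD8+, CD56+
  out$p_cd8 <- 1
  out$p_cd56 <- 1
  out
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults mirror the study design being emulated: 26 MEITL + 10 ITCL-NOS
#' + 4 borderline cases, 10 high-power fields per case (346 um square at
#' 2304 px), and a truncated-normal nucleus count per field (mean 892, SD
#' 255, minimum 300). The class laws set, per class: the mean equivalent
#' radius and its between-cell and case-level spread, the boundary-harmonic
#' amplitude scale (drives irregularity), an elongation law (axis ratio),
#' and an intensity-texture law (drives entropy); the default preset places
#' MEITL and ITCL-NOS at realistic monomorphic/pleomorphic contrast, while
#' the `"strong"` preset holds class means matched and widens only the
#' dispersion: extra symmetric between-cell size spread plus a
#' subpopulation of blebbed nuclei for the pleomorphic class, with
#' case-level jitter on every law parameter. Borderline cases draw
#' their parameters midway between the class laws with a MEITL-like
#' CD8+/CD56+ immunophenotype.
#'
#' @param n_meitl,n_itcl,n_borderline Case counts per group.
#' @param hpf_per_case Fields sampled per case.
#' @param nuclei_mean,nuclei_sd,nuclei_min Truncated-normal law for the
#'   nucleus count per field.
#' @param preset `"default"` or `"strong"` class separation.
#' @param seed Integer seed controlling every downstream draw.
#' @param laws Optional list with elements `MEITL` and `ITCL-NOS`
#'   overriding the preset class laws.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_meitl = 26L, n_itcl = 10L, n_borderline = 4L,
                          hpf_per_case = 10L,
                          nuclei_mean = 892, nuclei_sd = 255,
                          nuclei_min = 300,
                          preset = c("default", "strong"),
                          seed = 1L, laws = NULL) {
  preset <- match.arg(preset)
  if (is.null(laws)) {
    laws <- if (preset == "default") {
      list(
        "MEITL" = class_law(
          mu_R = 3.41, cv_R = 0.16, case_cv_R = 0.085,
          a_shape = 0.37, cv_a = 0.35, case_cv_a = 0.12,
          elong_mean = 0.14, elong_shape = 2.5,
          texture_sd = 12, texture_cv = 0.18,
          p_cd8 = 0.9, p_cd56 = 0.9),
        "ITCL-NOS" = class_law(
          mu_R = 3.61, cv_R = 0.19, case_cv_R = 0.07,
          a_shape = 0.52, cv_a = 0.5, case_cv_a = 0.14,
          elong_mean = 0.16, elong_shape = 2.0,
          texture_sd = 12, texture_cv = 0.20,
          p_cd8 = 0.2, p_cd56 = 0.15))
    } else {
      # the strong preset is a pure-dispersion contrast: expected per-cell
      # size (E[R^2]), waviness (E[s^2]), elongation and texture level are
      # matched across classes, while the between-cell spreads (cv_R,
      # cv_a, texture_cv) widen for the pleomorphic class and case-level
      # spread tightens. Cell-to-cell variability is the defining feature
      # of pleomorphism, so the dispersion moments must carry the
      # classification.
      list(
        "MEITL" = class_law(
          mu_R = 3.41, cv_R = 0.14, case_cv_R = 0.06,
          a_shape = 0.10, cv_a = 0.25, case_cv_a = 0.14,
          elong_mean = 0.30, elong_shape = 2.5,
          texture_sd = 12, texture_cv = 0.18,
          p_cd8 = 0.9, p_cd56 = 0.9, case_cv_disp = 0.20,
          case_cv_elong = 0.30,
          mix2_frac = 0.02, mix2_a = 1.6,
          mix2_bleb_h = 0.55, mix2_bleb_w = 0.12,
          case_cv_mix = 0.45),
        "ITCL-NOS" = class_law(
          mu_R = 3.30, cv_R = 0.14, case_cv_R = 0.06, cv_R_sym = 0.20,
          a_shape = 0.10, cv_a = 0.50, case_cv_a = 0.14,
          elong_mean = 0.30, elong_shape = 2.5,
          texture_sd = 12, texture_cv = 0.21,
          p_cd8 = 0.2, p_cd56 = 0.15, case_cv_disp = 0.20,
          case_cv_elong = 0.30,
          mix2_frac = 0.26, mix2_a = 1.6,
          mix2_bleb_h = 0.62, mix2_bleb_w = 0.12,
          case_cv_mix = 0.45))
    }
  }
  structure(list(
    n_meitl = as.integer(n_meitl), n_itcl = as.integer(n_itcl),
    n_borderline = as.integer(n_borderline),
    hpf_per_case = as.integer(hpf_per_case),
    nuclei_mean = nuclei_mean, nuclei_sd = nuclei_sd,
    nuclei_min = nuclei_min,
    pixel_size = hpf_pixel_size(), hpf_size = HPF_SIZE_UM,
    preset = preset, seed = as.integer(seed),
    laws = laws),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d MEITL + %d ITCL-NOS + %d borderline, %d HPF/case, preset '%s', seed %d\n",
              x$n_meitl, x$n_itcl, x$n_borderline, x$hpf_per_case,
              x$preset, x$seed))
  invisible(x)
}

# Draw per-case parameters around the class law. Location parameters
# (mu_R, a_shape, texture level) get their own case-level jitters; the
# dispersion parameters (cv_R, cv_a, texture_cv) share the case_cv_disp
# jitter, which models case-to-case heterogeneity of pleomorphism itself.
draw_case_params <- function(law) {
  disp <- function(x) x * rlnorm(1, -law$case_cv_disp^2 / 2,
                                 law$case_cv_disp)
  list(mu_R = law$mu_R * rlnorm(1, -law$case_cv_R^2 / 2, law$case_cv_R),
       cv_R = disp(law$cv_R),
       cv_R_sym = disp(law$cv_R_sym %||% 0),
       a_shape = law$a_shape * rlnorm(1, -law$case_cv_a^2 / 2, law$case_cv_a),
       cv_a = disp(law$cv_a),
       elong_mean = law$elong_mean *
         rlnorm(1, -(law$case_cv_elong %||% 0.10)^2 / 2,
                law$case_cv_elong %||% 0.10),
       elong_shape = law$elong_shape,
       texture_sd = law$texture_sd *
         rlnorm(1, -(law$texture_cv / 2)^2 / 2, law$texture_cv / 2),
       texture_cv = disp(law$texture_cv),
       mix_frac = min(0.6, law$mix_frac *
                        rlnorm(1, -law$case_cv_mix^2 / 2, law$case_cv_mix)),
       mix_R = law$mix_R, mix_a = law$mix_a,
       mix2_frac = min(0.6, law$mix2_frac *
                         rlnorm(1, -law$case_cv_mix^2 / 2, law$case_cv_mix)),
       mix2_a = law$mix2_a,
       mix2_bleb_h = law$mix2_bleb_h, mix2_bleb_w = law$mix2_bleb_w)
}

#' Generate one synthetic nucleus
#'
#' Draws one star-shaped nuclear contour from the per-case law: equivalent
#' radius R (lognormal around `mu_R` with CV `cv_R`), harmonic amplitudes
#' `a_k ~ N(0, (s * 2/k)^2)` for k = 2..6 with a per-cell scale s
#' (lognormal around `a_shape`), an area-preserving elongation drawn from a
#' gamma law, and a uniform rotation. Draws whose boundary modulation dips
#' below 0.1 of the base radius are redrawn (bounded retries, counted in
#' the `"n_redraws"` attribute).
#'
#' @param params Per-case parameter list (see [cohort_config()] laws).
#' @param center Length-2 (x, y) centre in micrometres.
#' @param n_vertices Boundary discretisation.
#' @return List: `polygon` (n x 2 matrix), `r_max` (conservative radius),
#'   and `gen` (the generating parameters, recorded for recovery tests).
#' @export
generate_nucleus <- function(params, center = c(0, 0), n_vertices = 64L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  redraws <- 0L
  f1 <- params$mix_frac %||% 0
  f2 <- params$mix2_frac %||% 0
  u <- if (f1 + f2 > 0) runif(1) else 1
  repeat {
    R <- params$mu_R * rlnorm(1, -params$cv_R^2 / 2, params$cv_R)
    sym <- params$cv_R_sym %||% 0
    if (sym > 0) R <- R * max(0.4, 1 + rnorm(1, 0, sym))
    s <- params$a_shape * rlnorm(1, -params$cv_a^2 / 2, params$cv_a)
    # the wavy subpopulation is lobulated, not elongated: its amplitude
    # boost applies to harmonics k >= 3 and leaves the k = 2 term alone
    w_scale <- rep(1, length(harmonic_orders))
    blebby <- FALSE
    if (u < f1) {
      R <- R * params$mix_R
      s <- s * params$mix_a
    } else if (u < f1 + f2) {
      w_scale[harmonic_orders >= 3] <- params$mix2_a
      blebby <- (params$mix2_bleb_h %||% 0) > 0
    }
    a_k <- rnorm(length(harmonic_orders), 0, s * harmonic_weights * w_scale)
    phi_k <- runif(length(harmonic_orders), 0, 2 * pi)
    mod <- as.vector(cos(outer(th, harmonic_orders) +
                           matrix(phi_k, length(th), length(phi_k),
                                  byrow = TRUE)) %*% a_k)
    if (blebby) {
      # one or two narrow protrusions (nuclear blebs): tall, narrow radial
      # bumps that add strong centroid-distance variance while displacing
      # little area
      for (b in seq_len(1L + stats::rbinom(1, 1, 0.5))) {
        th0 <- runif(1, 0, 2 * pi)
        h <- abs(rnorm(1, params$mix2_bleb_h, 0.25 * params$mix2_bleb_h))
        dth <- pmin(abs(th - th0), 2 * pi - abs(th - th0))
        mod <- mod + h * exp(-0.5 * (dth / params$mix2_bleb_w)^2)
      }
    }
    if (min(1 + mod) > 0.1 || redraws >= 20L) break
    redraws <- redraws + 1L
  }
  e <- 1 + rgamma(1, shape = params$elong_shape,
                  scale = params$elong_mean / params$elong_shape)
  theta0 <- runif(1, 0, pi)
  r <- R * (1 + mod)
  x0 <- r * cos(th) * sqrt(e)
  y0 <- r * sin(th) / sqrt(e)
  ct <- cos(theta0); st <- sin(theta0)
  poly <- cbind(center[1] + x0 * ct - y0 * st,
                center[2] + x0 * st + y0 * ct)
  structure(list(
    polygon = poly,
    r_max = max(sqrt((poly[, 1] - center[1])^2 + (poly[, 2] - center[2])^2)),
    gen = list(R = R, s = s, a_k = a_k, phi_k = phi_k, e = e,
               theta0 = theta0, center = center)),
    n_redraws = redraws)
}

# Fill intensities for one nucleus into its bounding-box patch: pixels
# whose centres fall inside the placed polygon get base level +
# Gaussian-blob texture + white noise, the rest the pale background level.
# Returns a calibrated_patch.
fill_nucleus_patch <- function(poly, gen, texture_sd, pixel_size,
                               background = 232, base_mean = 118,
                               n_blobs = 2L) {
  j0 <- floor(min(poly[, 1]) / pixel_size) - 1L
  j1 <- ceiling(max(poly[, 1]) / pixel_size) + 1L
  i0 <- floor(min(poly[, 2]) / pixel_size) - 1L
  i1 <- ceiling(max(poly[, 2]) / pixel_size) + 1L
  js <- j0:j1; is <- i0:i1
  inside <- cpp_grid_in_polygon(js * pixel_size, is * pixel_size, poly)
  vals <- rep(background, length(js) * length(is))
  n_in <- sum(inside)
  if (n_in > 0) {
    # x/y of inside pixels in the nucleus frame, for blob placement
    px <- rep(js, times = length(is))[inside] * pixel_size - gen$center[1]
    py <- rep(is, each = length(js))[inside] * pixel_size - gen$center[2]
    v <- rep(rnorm(1, base_mean, 10), n_in)
    for (b in seq_len(n_blobs)) {
      bc <- runif(2, -gen$R / 2, gen$R / 2)
      amp <- rnorm(1, 0, 18)
      sg <- gen$R * runif(1, 0.3, 0.6)
      v <- v + amp * exp(-((px - bc[1])^2 + (py - bc[2])^2) / (2 * sg^2))
    }
    v <- v + rnorm(n_in, 0, texture_sd)
    vals[inside] <- v
  }
  m <- matrix(pmin(pmax(round(vals), 0), 255),
              nrow = length(is), ncol = length(js), byrow = TRUE)
  calibrated_patch(m, pixel_size, origin = c(j0, i0) * pixel_size)
}

#' Generate one synthetic high-power field
#'
#' Draws the nucleus count from the truncated-normal density law, then
#' places nuclei by dart throwing with non-overlapping interiors
#' (conservative bounding-circle test on a spatial grid, larger nuclei
#' placed first). Each placed nucleus gets an intensity patch over its
#' bounding box. If placement stalls, the field is emitted with the
#' achieved count and a warning.
#'
#' @param case_params Per-case parameter list.
#' @param config A [cohort_config()] (geometry/calibration constants).
#' @param n_nuclei Nucleus count; drawn from the density law when `NULL`.
#' @param hpf_id Field identifier.
#' @param patches Also synthesise per-nucleus intensity patches.
#' @return List: `nuclei` (contour tibble with `polygon`, `patch` and
#'   generator-truth columns), `n_target`, `n_placed`.
#' @export
generate_hpf <- function(case_params, config = cohort_config(),
                         n_nuclei = NULL, hpf_id = "hpf1", patches = TRUE) {
  size <- config$hpf_size
  ps <- config$pixel_size
  if (is.null(n_nuclei)) {
    repeat {
      n_nuclei <- round(rnorm(1, config$nuclei_mean, config$nuclei_sd))
      if (n_nuclei >= config$nuclei_min) break
    }
  }
  n_nuclei <- as.integer(n_nuclei)
  nucs <- lapply(seq_len(n_nuclei), function(i) generate_nucleus(case_params))
  ord <- order(vapply(nucs, `[[`, numeric(1), "r_max"), decreasing = TRUE)
  nucs <- nucs[ord]
  rmaxs <- vapply(nucs, `[[`, numeric(1), "r_max")
  cell <- max(2 * max(rmaxs), 1)
  ng <- max(1L, floor(size / cell))
  cell <- size / ng
  grid <- vector("list", ng * ng)
  placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
  keep_idx <- integer(0) # nucleus index per placed entry
  keep <- logical(n_nuclei)
  centers <- matrix(0, n_nuclei, 2)
  for (i in seq_len(n_nuclei)) {
    ri <- rmaxs[i]
    poly_i <- nucs[[i]]$polygon
    ok <- FALSE
    for (try in seq_len(60L)) {
      cx <- runif(1, ri, size - ri)
      cy <- runif(1, ri, size - ri)
      gx <- min(ng, max(1L, ceiling(cx / cell)))
      gy <- min(ng, max(1L, ceiling(cy / cell)))
      clash <- FALSE
      for (ux in max(1L, gx - 1L):min(ng, gx + 1L)) {
        for (uy in max(1L, gy - 1L):min(ng, gy + 1L)) {
          nb <- grid[[(uy - 1L) * ng + ux]]
          if (is.null(nb)) next
          # conservative circle pre-filter, then exact polygon overlap
          near <- nb[(placed_x[nb] - cx)^2 + (placed_y[nb] - cy)^2 <
                       (placed_r[nb] + ri)^2]
          for (j in near) {
            if (cpp_polys_overlap(poly_i, cx, cy, nucs[[keep_idx[j]]]$polygon,
                                  placed_x[j], placed_y[j])) {
              clash <- TRUE
              break
            }
          }
          if (clash) break
        }
        if (clash) break
      }
      if (!clash) {
        ok <- TRUE
        break
      }
    }
    if (!ok) next
    placed_x <- c(placed_x, cx); placed_y <- c(placed_y, cy)
    placed_r <- c(placed_r, ri)
    keep_idx <- c(keep_idx, i)
    idx <- (min(ng, max(1L, ceiling(cy / cell))) - 1L) * ng +
      min(ng, max(1L, ceiling(cx / cell)))
    grid[[idx]] <- c(grid[[idx]], length(placed_x))
    keep[i] <- TRUE
    centers[i, ] <- c(cx, cy)
  }
  if (sum(keep) < n_nuclei) {
    warn(sprintf("Field %s: placed %d of %d nuclei before dart-throwing stalled.",
                 hpf_id, sum(keep), n_nuclei))
  }
  nucs <- nucs[keep]
  centers <- centers[keep, , drop = FALSE]
  n <- length(nucs)
  polys <- vector("list", n)
  patch_list <- vector("list", n)
  gens <- vector("list", n)
  for (i in seq_len(n)) {
    g <- nucs[[i]]$gen
    g$center <- centers[i, ]
    poly <- nucs[[i]]$polygon
    poly[, 1] <- poly[, 1] + centers[i, 1]
    poly[, 2] <- poly[, 2] + centers[i, 2]
    polys[[i]] <- poly
    gens[[i]] <- g
    if (patches) {
      tsd <- case_params$texture_sd *
        rlnorm(1, -(case_params$texture_cv)^2 / 2, case_params$texture_cv)
      patch_list[[i]] <- fill_nucleus_patch(poly, g, tsd, ps)
    }
  }
  nuclei <- tibble(
    nucleus_id = paste0(hpf_id, "_n", seq_len(n)),
    hpf_id = hpf_id,
    polygon = polys,
    patch = if (patches) patch_list else rep(list(NULL), n),
    true_R = vapply(gens, `[[`, numeric(1), "R"),
    true_elong = vapply(gens, `[[`, numeric(1), "e"),
    true_shape_scale = vapply(gens, `[[`, numeric(1), "s"))
  list(nuclei = nuclei, n_target = n_nuclei, n_placed = n)
}

#' Generate a synthetic cohort
#'
#' Draws the case manifest (diagnosis labels, CD8/CD56 immunophenotypes)
#' and per-case generator parameters for the configured cohort, together
#' with per-field nucleus counts and sub-seeds so each field can be
#' generated independently and reproducibly. Borderline cases draw their
#' morphology parameters midway between the two class laws with a
#' CD8+/CD56+ phenotype. Geometry is not materialised here; use
#' [generate_hpf()] per field or [simulate_cohort_features()] to stream the
#' whole cohort through feature extraction.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: `manifest`, `cases` (named
#'   list of per-case parameter sets with `hpf_seeds` and `hpf_ids`),
#'   `true_params` tibble, and the `config` echo.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  diagnosis <- c(rep("MEITL", config$n_meitl),
                 rep("ITCL-NOS", config$n_itcl),
                 rep("borderline", config$n_borderline))
  n_cases <- length(diagnosis)
  if (config$n_meitl == 0 || config$n_itcl == 0) {
    warn("A disease class has zero cases; downstream classification will fail.")
  }
  case_id <- sprintf("T%02d", seq_len(n_cases))
  bl_law <- mix_laws(config$laws[["MEITL"]], config$laws[["ITCL-NOS"]])
  cases <- vector("list", n_cases)
  cd8 <- character(n_cases); cd56 <- character(n_cases)
  for (i in seq_len(n_cases)) {
    law <- if (diagnosis[i] == "borderline") bl_law else
      config$laws[[diagnosis[i]]]
    cases[[i]] <- draw_case_params(law)
    cd8[i] <- if (runif(1) < law$p_cd8) "+" else "-"
    cd56[i] <- if (runif(1) < law$p_cd56) "+" else "-"
    cases[[i]]$hpf_ids <- sprintf("%s_h%02d", case_id[i],
                                  seq_len(config$hpf_per_case))
    cases[[i]]$hpf_seeds <- sample.int(.Machine$integer.max,
                                       config$hpf_per_case)
  }
  names(cases) <- case_id
  manifest <- tibble(case_id = case_id, diagnosis = diagnosis,
                     cd8 = cd8, cd56 = cd56,
                     hpf_ids = lapply(cases, `[[`, "hpf_ids"))
  true_params <- tibble(
    case_id = case_id, diagnosis = diagnosis,
    mu_R = vapply(cases, `[[`, numeric(1), "mu_R"),
    a_shape = vapply(cases, `[[`, numeric(1), "a_shape"),
    elong_mean = vapply(cases, `[[`, numeric(1), "elong_mean"),
    texture_sd = vapply(cases, `[[`, numeric(1), "texture_sd"))
  structure(list(manifest = manifest, cases = cases,
                 true_params = true_params, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases x %d HPFs (preset '%s', seed %d)\n",
              nrow(x$manifest), x$config$hpf_per_case,
              x$config$preset, x$config$seed))
  invisible(x)
}

#' Stream a synthetic cohort through feature extraction
#'
#' Generates every field of the cohort and immediately reduces it to its
#' 28-feature moment vector, so the full-scale cohort never has to be held
#' in memory. Returns the per-field feature table alongside the manifest
#' and the generator truth, plus a timing summary.
#'
#' @param config A [cohort_config()] or a pre-drawn `synthetic_cohort`.
#' @param min_nuclei Minimum population size per field (see
#'   [hpf_moments()]).
#' @param progress Print a line per case.
#' @return List: `manifest`, `hpf_features` (per-field rows with
#'   `case_id`), `true_params`, `placement_shortfall` (fields x counts),
#'   and `seconds_per_hpf`.
#' @export
simulate_cohort_features <- function(config = cohort_config(),
                                     min_nuclei = 8L, progress = FALSE) {
  cohort <- if (inherits(config, "synthetic_cohort")) config
            else generate_cohort(config)
  config <- cohort$config
  rows <- list()
  shortfall <- list()
  t0 <- proc.time()[["elapsed"]]
  n_hpf_total <- 0L
  for (cid in cohort$manifest$case_id) {
    cp <- cohort$cases[[cid]]
    for (h in seq_len(config$hpf_per_case)) {
      set.seed(cp$hpf_seeds[h])
      hpf <- withCallingHandlers(
        generate_hpf(cp, config, hpf_id = cp$hpf_ids[h]),
        warning = function(w) invokeRestart("muffleWarning"))
      morph <- compute_morphometrics(hpf$nuclei)
      row <- hpf_moments(morph, min_nuclei = min_nuclei,
                         hpf_id = cp$hpf_ids[h])
      row$case_id <- cid
      rows[[length(rows) + 1L]] <- row
      if (hpf$n_placed < hpf$n_target) {
        shortfall[[length(shortfall) + 1L]] <-
          tibble(hpf_id = cp$hpf_ids[h], n_target = hpf$n_target,
                 n_placed = hpf$n_placed)
      }
      n_hpf_total <- n_hpf_total + 1L
    }
    if (progress) {
      message(sprintf("case %s done (%.1f s elapsed)", cid,
                      proc.time()[["elapsed"]] - t0))
    }
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  hpf_features <- dplyr::bind_rows(rows) |>
    dplyr::relocate("case_id")
  list(manifest = cohort$manifest,
       hpf_features = hpf_features,
       true_params = cohort$true_params,
       placement_shortfall = dplyr::bind_rows(shortfall),
       seconds_per_hpf = elapsed / max(n_hpf_total, 1L))
}

#' Run the full synthetic analysis end to end
#'
#' Convenience wrapper: simulate the cohort, extract per-field and
#' case-level features, build the feature matrix (borderline cases held
#' out), and tune/cross-validate the subtype classifier.
#'
#' @param config A [cohort_config()].
#' @param include_ihc Add CD8/CD56 columns to the classifier input.
#' @param n_draws Random-search budget.
#' @param features Optional pre-computed result of
#'   [simulate_cohort_features()] to reuse across classifier runs.
#' @return List: `model` (a `subtype_model`), `borderline` (predictions),
#'   `cases`, `hpf_features`, `manifest`, `true_params`,
#'   `seconds_per_hpf`.
#' @export
run_subtype_analysis <- function(config = cohort_config(),
                                 include_ihc = FALSE, n_draws = 50L,
                                 features = NULL) {
  feats <- features %||% simulate_cohort_features(config)
  cases <- aggregate_cases(feats$hpf_features, feats$manifest)
  fm <- build_feature_matrix(cases, include_ihc = include_ihc)
  model <- tune_and_crossvalidate(fm, seed = config$seed, n_draws = n_draws)
  list(model = model,
       borderline = predict_borderline(model),
       cases = cases,
       hpf_features = feats$hpf_features,
       manifest = feats$manifest,
       true_params = feats$true_params,
       seconds_per_hpf = feats$seconds_per_hpf)
}
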