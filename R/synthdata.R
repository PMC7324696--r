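#' Phantom anatomy parameters
#'
#' Parameters of the synthetic male-pelvis phantom used to exercise the full
#' pipeline without clinical data: an ellipsoidal CTV (prostate plus proximal
#' seminal vesicles), a bowed cylindrical rectum posterior to it, and a
#' spherical bladder superior-anterior.  Defaults are sized to the
#' cohort-mean anatomy (CTV about 40 cc, rectum about 78 cc) with a 2 mm CT
#' slice spacing.
#'
#' @param ctv_semiaxes Length-3 CTV semi-axes (mm; x, y, z).
#' @param rectum_radius Rectum tube radius (mm).
#' @param rectum_length Rectum length (mm).
#' @param rectum_bow Sagittal bow of the rectum axis (mm); the axis bows
#'   posteriorly away from mid-gland toward both ends.
#' @param gap Minimum anterior rectum-to-CTV gap at mid-gland (mm, >= 0).
#' @param bladder_radius Bladder radius (mm).
#' @param slice_spacing CT slice spacing (mm).
#' @param n_vertices Contour vertices per polygon.
#' @param contour_jitter Radial contouring noise (mm, standard deviation)
#'   applied when `seed` is non-NULL, emulating manual contouring variation.
#' @param seed Optional integer seed; the same seed always reproduces the
#'   same phantom.
#' @return List of class `phantom_params`.
#' @export
phantom_params <- function(ctv_semiaxes = c(25, 19, 20), rectum_radius = 15,
                           rectum_length = 110, rectum_bow = 6, gap = 2,
                           bladder_radius = 24, slice_spacing = 2,
                           n_vertices = 120L, contour_jitter = 0.3,
                           seed = NULL) {
  if (gap < 0) stop("'gap' must be >= 0")
  if (any(c(ctv_semiaxes, rectum_radius, rectum_length, bladder_radius,
            slice_spacing) <= 0)) {
    stop("all phantom dimensions must be positive")
  }
  structure(as.list(environment()), class = "phantom_params")
}

#' Generate a pre-implant phantom structure set
#'
#' Builds CTV, rectum and bladder contour stacks on a common slice grid.
#' The rectum axis is placed so that its anterior surface sits exactly `gap`
#' mm behind the CTV's posterior surface at mid-gland, bowing further
#' posterior toward its superior and inferior ends.
#'
#' @param p A [phantom_params()].
#' @return Named list of [contour_stack()]s: `ctv`, `rectum`, `bladder`.
#' @export
make_phantom <- function(p = phantom_params()) {
  if (!inherits(p, "phantom_params")) stop("'p' must be phantom_params")
  if (!is.null(p$seed)) set.seed(p$seed)
  a <- p$ctv_semiaxes
  ctv <- cs_ellipsoid(c(0, 0, 0), a, p$slice_spacing, p$n_vertices, "ctv")
  y_axis_mid <- a[2] + p$gap + p$rectum_radius
  halfL <- p$rectum_length / 2
  center_fun <- function(z) c(0, y_axis_mid + p$rectum_bow * (z / halfL)^2)
  rectum <- cs_cylinder(radius = p$rectum_radius, z_range = c(-halfL, halfL),
                        slice_spacing = p$slice_spacing,
                        n_vertices = p$n_vertices, name = "rectum",
                        center_fun = center_fun)
  bladder <- cs_sphere(c(0, -a[2] - 5, a[3] + p$bladder_radius - 5),
                       p$bladder_radius, p$slice_spacing, p$n_vertices,
                       "bladder")
  out <- list(ctv = ctv, rectum = rectum, bladder = bladder)
  if (!is.null(p$seed) && p$contour_jitter > 0) {
    out <- lapply(out, .jitter_stack, sd = p$contour_jitter)
  }
  out
}

# radial low-frequency contour noise around each polygon centroid
.jitter_stack <- function(s, sd) {
  s$slices <- lapply(s$slices, function(sl) {
    sl$polys <- lapply(sl$polys, function(p) {
      c0 <- colMeans(p)
      n <- nrow(p)
      th <- atan2(p[, 2] - c0[2], p[, 1] - c0[1])
      amp <- stats::rnorm(3, 0, sd)
      ph <- stats::runif(3, 0, 2 * pi)
      dr <- amp[1] * cos(th + ph[1]) + amp[2] * cos(2 * th + ph[2]) +
        amp[3] * cos(3 * th + ph[3])
      r <- sqrt(rowSums(sweep(p, 2, c0)^2))
      cbind(c0[1] + (r + dr) * cos(th), c0[2] + (r + dr) * sin(th))
    })
    sl
  })
  s
}

#' Spacer implant parameters
#'
#' @param max_displacement Peak posterior rectal displacement at mid-gland
#'   (mm, >= 0); about 10 mm of separation is typical of a hydrogel implant.
#' @param taper_extent Axial distance beyond the CTV half-extent over which
#'   the displacement tapers to zero (mm).
#' @param seed Optional integer seed (reserved for stochastic variants).
#' @return List of class `spacer_params`.
#' @export
spacer_params <- function(max_displacement = 10, taper_extent = 15,
                          seed = NULL) {
  if (max_displacement < 0) stop("'max_displacement' must be >= 0")
  structure(list(max_displacement = max_displacement,
                 taper_extent = taper_extent, seed = seed),
            class = "spacer_params")
}

#' Apply a virtual spacer implant to a structure set
#'
#' Displaces the rectum posteriorly (+y) by a raised-cosine axial profile
#' peaking at mid-gland and vanishing `taper_extent` mm beyond the CTV's
#' superior/inferior extent - the separation pattern of a hydrogel injected
#' between prostate and rectum - and adds a spacer structure (`spacer`) filling
#' the vacated space.  The rectum is translated slice-wise, so its volume is
#' conserved exactly.
#'
#' @param structs Named list with at least `ctv` and `rectum` contour stacks.
#' @param sp A [spacer_params()].
#' @param resolution Raster resolution (mm) used to contour the vacated gap.
#' @return The structure set with the displaced `rectum` and an added `spacer`
#'   stack.
#' @export
apply_spacer <- function(structs, sp = spacer_params(), resolution = 1) {
  if (is.null(structs$rectum) || is.null(structs$ctv)) {
    stop("'structs' must contain 'rectum' and 'ctv'")
  }
  if (sp$max_displacement == 0) return(structs)
  zc <- mean(range(stack_z(structs$ctv)))
  H <- diff(range(stack_z(structs$ctv))) / 2 + sp$taper_extent
  shift_at <- function(z) {
    u <- (z - zc) / H
    ifelse(abs(u) < 1, sp$max_displacement * cos(pi * u / 2)^2, 0)
  }
  rectum <- structs$rectum
  gap_slices <- list()
  new_slices <- lapply(rectum$slices, function(sl) {
    s <- shift_at(sl$z)
    if (s <= 0) return(sl)
    shifted <- lapply(sl$polys, function(p) cbind(p[, 1], p[, 2] + s))
    # vacated space: original minus shifted rectum footprint
    bb <- .stacks_bbox(list(structure(list(slices = list(sl)),
                                      class = "contour_stack")))
    xg <- .grid_axis(bb$xmin, bb$xmax, resolution, resolution)
    yg <- .grid_axis(bb$ymin, bb$ymax + s, resolution, resolution)
    g <- expand.grid(x = xg, y = yg)
    din <- .curves_dist_min(g$x, g$y, sl$polys)
    din_sh <- .curves_dist_min(g$x, g$y, shifted)
    in0 <- .points_in_polys(g$x, g$y, sl$polys)
    in1 <- .points_in_polys(g$x, g$y, shifted)
    # signed-distance field of (in original) and (not in shifted)
    f <- pmin(ifelse(in0, din, -din), ifelse(in1, -din_sh, din_sh))
    gap_polys <- .contours_from_field(xg, yg, f, 0)
    if (length(gap_polys) > 0L) {
      gap_slices[[length(gap_slices) + 1L]] <<- list(z = sl$z,
                                                     polys = gap_polys)
    }
    list(z = sl$z, polys = shifted)
  })
  structs$rectum <- contour_stack(rectum$name, new_slices,
                                  rectum$slice_spacing)
  structs$spacer <- contour_stack("spacer", gap_slices, rectum$slice_spacing)
  structs
}

#' Surrogate dose model
#'
#' A deterministic stand-in for an optimized VMAT dose distribution, built
#' for testing the dose-endpoint machinery: the prescription dose is
#' delivered uniformly inside the PTV and falls off sigmoidally with 3D
#' distance from the PTV surface, with a configurable 80 %-to-20 % penumbra
#' width.  It is not a beam model; it exists to give geometry-dependent
#' rectal dose metrics with the correct monotone structure (moving the rectum
#' away from the PTV strictly lowers its V55Gy).
#'
#' @param structs Named list of contour stacks; `ptv` is required, the others
#'   only enlarge the grid coverage.
#' @param prescription Prescription dose in Gy (default 60).
#' @param penumbra 80-20 % falloff distance in mm (default 8).
#' @param resolution In-plane dose-grid resolution in mm (default 2.5).
#' @param grid_margin Extra grid coverage around the structures (mm).
#' @return A [dose_grid()].
#' @export
surrogate_dose <- function(structs, prescription = 60, penumbra = 8,
                           resolution = 2.5, grid_margin = 25) {
  ptv <- structs$ptv
  if (is.null(ptv)) stop("'structs' must contain a 'ptv' stack")
  stacks <- Filter(is_contour_stack, structs)
  bb <- .stacks_bbox(stacks)
  dz <- ptv$slice_spacing
  allz <- unlist(lapply(stacks, stack_z))
  xg <- .grid_axis(bb$xmin, bb$xmax, resolution, grid_margin)
  yg <- .grid_axis(bb$ymin, bb$ymax, resolution, grid_margin)
  zg <- .grid_axis(min(allz), max(allz), dz, grid_margin)
  g <- expand.grid(x = xg, y = yg)

  zs <- stack_z(ptv)
  nz <- length(zs)
  curve_d <- lapply(ptv$slices, function(sl) {
    Q <- do.call(rbind, lapply(sl$polys, .sample_closed, step = resolution / 2))
    .pt_dist_field(g$x, g$y, Q)
  })
  inside <- lapply(ptv$slices, function(sl)
    .points_in_polys(g$x, g$y, sl$polys))

  w <- penumbra / log(6)   # 2/(1+exp(d/w)) drops 0.8 -> 0.2 over 'penumbra'
  vals <- array(0, dim = c(length(xg), length(yg), length(zg)))
  for (k in seq_along(zg)) {
    z <- zg[k]
    d3 <- rep(Inf, nrow(g))
    for (j in seq_len(nz)) {
      dzv <- z - zs[j]
      d3 <- pmin(d3, sqrt(curve_d[[j]]^2 + dzv^2))
    }
    # end caps: directly above/below the end-slice footprint the nearest
    # surface is the flat cap, half a slice beyond the end slice
    if (z > zs[nz]) d3 <- pmin(d3, ifelse(inside[[nz]],
                                          pmax(z - zs[nz] - dz / 2, 0), Inf))
    if (z < zs[1]) d3 <- pmin(d3, ifelse(inside[[1]],
                                         pmax(zs[1] - dz / 2 - z, 0), Inf))
    jn <- which.min(abs(zs - z))
    inside_here <- abs(zs[jn] - z) <= dz / 2 + 1e-9 && TRUE
    sgn <- if (inside_here) ifelse(inside[[jn]], -1, 1) else rep(1, nrow(g))
    ds <- sgn * d3
    vals[, , k] <- matrix(prescription * pmin(1, 2 / (1 + exp(ds / w))),
                          nrow = length(xg))
  }
  dose_grid(origin = c(xg[1], yg[1], zg[1]),
            spacing = c(resolution, resolution, dz),
            values = vals)
}

#' Cohort simulation configuration
#'
#' Settings for [simulate_cohort()].  In `"model"` mode, geometric features
#' are drawn from log-normal (volumes) and truncated-normal (distances)
#' marginals calibrated to the published 21-patient cohort summary, coupled
#' through a Gaussian copula, and the dose endpoints are generated from the
#' published Model 2 equations plus Gaussian noise whose variance is chosen
#' to reproduce the published R-squared
#' (`sigma^2 = Var(yhat) (1 - R2) / R2`).  In `"geometric"` mode each
#' patient is a randomized phantom run through the full geometry + spacer +
#' surrogate-dose pipeline.
#'
#' @param n Cohort size (default 21, the published modelling cohort).
#' @param mode `"model"` or `"geometric"`.
#' @param seed Integer seed; fixed seed gives a reproducible cohort.
#' @param rho Copula correlation between the normalized rectum-in-PTV volume
#'   and the wall-to-CTV distance (default -0.5: organs that overlap the PTV
#'   more tend to lie closer; joint correlations are otherwise unpublished
#'   and this coupling is an explicit assumption).
#' @param rho_rectum_rw Copula correlation between rectum and rectal-wall
#'   volumes (default 0.8; near-duplicates by construction).
#' @param r_squared_delta,r_squared_pre Target R-squared of the generated
#'   endpoints around the Model 2 equations (defaults 0.81 and 0.87).
#' @param recipe [structure_recipe()] used in geometric mode.
#' @param dose_resolution In-plane surrogate-dose resolution (mm, geometric
#'   mode).
#' @return List of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n = 21L, mode = c("model", "geometric"),
                              seed = 1L, rho = -0.5, rho_rectum_rw = 0.8,
                              r_squared_delta = 0.81, r_squared_pre = 0.87,
                              recipe = structure_recipe(raster_resolution = 1.5),
                              dose_resolution = 2.5) {
  mode <- match.arg(mode)
  if (n < 1L) stop("'n' must be >= 1")
  structure(list(n = as.integer(n), mode = mode, seed = seed, rho = rho,
                 rho_rectum_rw = rho_rectum_rw,
                 r_squared_delta = r_squared_delta,
                 r_squared_pre = r_squared_pre, recipe = recipe,
                 dose_resolution = dose_resolution),
            class = "cohort_sim_config")
}

# moment-matched log-normal parameters
.lnorm_pars <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# transform standard-normal draws to a truncated marginal by inverse CDF,
# rejecting out-of-range values (redrawn from the untruncated marginal)
.trunc_transform <- function(z, qfun, lo, hi) {
  x <- qfun(stats::pnorm(z))
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- qfun(stats::runif(length(bad)))
    bad <- bad[x[bad] < lo | x[bad] > hi]
    guard <- guard + 1L
  }
  pmin(pmax(x, lo), hi)
}

#' Simulate a calibrated patient cohort
#'
#' Generates a cohort feature table with dose endpoints; see
#' [cohort_sim_config()] for the two generation modes.
#'
#' @param config A [cohort_sim_config()].
#' @return Cohort `data.frame` with the canonical columns of
#'   [cohort_columns()].
#' @examples
#' coh <- simulate_cohort(cohort_sim_config(n = 21, seed = 1))
#' summarize_cohort(coh)
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  if (!inherits(config, "cohort_sim_config")) {
    stop("'config' must be a cohort_sim_config")
  }
  set.seed(config$seed)
  if (config$mode == "model") .simulate_cohort_model(config)
  else .simulate_cohort_geometric(config)
}

.simulate_cohort_model <- function(config) {
  n <- config$n
  cs <- published_cohort_summary()
  par_of <- function(metric) cs[cs$metric == metric, ]

  # Gaussian copula over (rectum, rw, ctv, norm_rinptv, rw_to_ctv)
  R <- diag(5)
  R[1, 2] <- R[2, 1] <- config$rho_rectum_rw
  R[4, 5] <- R[5, 4] <- config$rho
  L <- chol(R)
  Z <- matrix(stats::rnorm(n * 5), n, 5) %*% L

  draw_ln <- function(z, metric) {
    p <- par_of(metric)
    lp <- .lnorm_pars(p$mean, p$sd)
    .trunc_transform(z, function(u) stats::qlnorm(u, lp[1], lp[2]),
                     p$min, p$max)
  }
  p_d <- par_of("rw_to_ctv_cm")
  rectum <- draw_ln(Z[, 1], "rectum_vol_cc")
  rw <- pmin(draw_ln(Z[, 2], "rw_vol_cc"), rectum)
  ctv <- draw_ln(Z[, 3], "ctv_vol_cc")
  norm_rinptv <- draw_ln(Z[, 4], "norm_rinptv_pct")
  rw_to_ctv <- .trunc_transform(Z[, 5],
                                function(u) stats::qnorm(u, p_d$mean, p_d$sd),
                                p_d$min, p_d$max)

  coh <- data.frame(
    patient_id = sprintf("SIM%03d", seq_len(n)),
    rectum_vol_cc = rectum,
    rw_vol_cc = rw,
    ctv_vol_cc = ctv,
    norm_ctv_pct = 100 * ctv / rectum,
    rinptv_cc = norm_rinptv * rectum / 100,
    norm_rinptv_pct = norm_rinptv,
    rw_to_ctv_cm = rw_to_ctv,
    rw_to_ctv_cubed_cc = rw_to_ctv^3,
    rw_to_ctv_inv_cubed = rw_to_ctv^-3,
    stringsAsFactors = FALSE
  )
  reg <- published_models()
  noisy <- function(model, r2) {
    yhat <- predict(model, coh, warn_extrapolation = FALSE)
    sd_y <- stats::sd(yhat)
    sigma <- if (r2 >= 1 || sd_y == 0) 0 else sd_y * sqrt((1 - r2) / r2)
    yhat + stats::rnorm(length(yhat), 0, sigma)
  }
  coh$delta_rv55_pct <- noisy(reg$delta_model2, config$r_squared_delta)
  coh$pre_rv55_pct <- noisy(reg$pre_model2, config$r_squared_pre)
  coh
}

.simulate_cohort_geometric <- function(config) {
  n <- config$n
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    scale_ctv <- exp(stats::rnorm(1, 0, 0.15))
    pp <- phantom_params(
      ctv_semiaxes = c(25, 19, 20) * scale_ctv,
      rectum_radius = min(max(stats::rnorm(1, 15, 2), 11), 20),
      rectum_length = min(max(stats::rnorm(1, 110, 12), 80), 140),
      rectum_bow = stats::runif(1, 3, 9),
      gap = stats::runif(1, 0.5, 4.5),
      seed = NULL)
    structs <- make_phantom(pp)
    structs$ptv <- expand_margin(structs$ctv, margin_spec(), config$recipe)
    feats <- extract_features(structs, config$recipe,
                              patient_id = sprintf("GEO%03d", i))
    disp <- min(max(stats::rnorm(1, 10, 2.5), 3), 18)
    post <- apply_spacer(structs, spacer_params(max_displacement = disp))
    # the surrogate dose depends only on the PTV, which the spacer does not
    # change, so one grid (covering both rectum positions) serves both plans
    dose <- surrogate_dose(c(structs, list(post_rectum = post$rectum)),
                           resolution = config$dose_resolution)
    dm <- paired_metrics(dose, dose, structs$rectum, post$rectum)
    feats$delta_rv55_pct <- dm$delta_rv55
    feats$pre_rv55_pct <- dm$pre_rv55
    rows[[i]] <- feats
  }
  do.call(rbind, rows)
}
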