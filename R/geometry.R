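#' Margin and structure-recipe configuration
#'
#' `margin_spec()` holds the anisotropic expansion margins used to grow a CTV
#' into a PTV.  Defaults follow the common clinical recipe of 7 mm in every
#' direction except 5 mm posteriorly (toward the rectum, +y).
#' `structure_recipe()` holds the knobs of the derived-structure recipes: the
#' wall-shell thickness, the height-limiting extent beyond the PTV, and the
#' raster resolution used wherever a boolean or morphological operation needs
#' a grid.
#'
#' @param anterior,posterior,left,right,superior,inferior Margins in mm,
#'   each >= 0.
#' @param wall_thickness Inner-shell thickness in mm (default 3).
#' @param height_limit_extent Extent in mm kept beyond the extreme PTV slices
#'   when height-limiting a wall (default 17.5).
#' @param raster_resolution In-plane raster resolution in mm (default 1).
#' @return A named list of class `margin_spec` / `structure_recipe`.
#' @export
margin_spec <- function(anterior = 7, posterior = 5, left = 7, right = 7,
                        superior = 7, inferior = 7) {
  m <- list(anterior = anterior, posterior = posterior, left = left,
            right = right, superior = superior, inferior = inferior)
  if (any(unlist(m) < 0)) stop("margins must be >= 0")
  structure(m, class = "margin_spec")
}

#' @rdname margin_spec
#' @export
structure_recipe <- function(wall_thickness = 3, height_limit_extent = 17.5,
                             raster_resolution = 1.0) {
  if (wall_thickness < 0) stop("'wall_thickness' must be >= 0")
  if (height_limit_extent < 0) stop("'height_limit_extent' must be >= 0")
  if (raster_resolution <= 0) stop("'raster_resolution' must be > 0")
  structure(list(wall_thickness = wall_thickness,
                 height_limit_extent = height_limit_extent,
                 raster_resolution = raster_resolution),
            class = "structure_recipe")
}

#' Expand a structure by anisotropic margins (CTV to PTV)
#'
#' Grows a contour stack by direction-dependent margins, the way a planning
#' system builds a PTV from a CTV.  A point belongs to the expanded structure
#' when its displacement from some point of the input fits inside the
#' anisotropic margin ellipsoid (axis half-lengths chosen by the sign of each
#' displacement component, so the posterior margin acts only toward +y).  The
#' expansion is evaluated as a scaled distance field on a raster grid and
#' re-contoured per slice, which keeps the boundary sub-voxel accurate.
#' New slices are added superiorly/inferiorly as far as the z margins reach
#' (whole slices only).
#'
#' @param ctv Input [contour_stack()] (non-empty).
#' @param m A [margin_spec()].
#' @param cfg A [structure_recipe()]; only `raster_resolution` is used.
#' @return The expanded [contour_stack()].
#' @examples
#' ctv <- cs_sphere(radius = 15, slice_spacing = 2)
#' ptv <- expand_margin(ctv, margin_spec())
#' structure_volume(ptv) > structure_volume(ctv)
#' @export
expand_margin <- function(ctv, m = margin_spec(), cfg = structure_recipe()) {
  if (!is_contour_stack(ctv)) stop("'ctv' must be a contour_stack")
  if (length(ctv$slices) == 0L) stop("cannot expand an empty contour stack")
  mm <- unlist(m[c("anterior", "posterior", "left", "right",
                   "superior", "inferior")])
  res <- cfg$raster_resolution
  if (all(mm < res / 4)) return(ctv)     # identity: nothing to grow
  # floor tiny-but-nonzero margins at a quarter voxel so the level set stays
  # resolvable; exact zeros keep their hard "no displacement" meaning
  eff <- function(v) if (v == 0) 0 else max(v, res / 4)
  m_ant <- eff(m$anterior); m_post <- eff(m$posterior)
  m_left <- eff(m$left); m_right <- eff(m$right)
  m_sup <- eff(m$superior); m_inf <- eff(m$inferior)

  dz <- ctv$slice_spacing
  zs <- stack_z(ctv)
  bb <- .stacks_bbox(list(ctv))
  pad <- max(m_left, m_right, m_ant, m_post) + res
  xg <- .grid_axis(bb$xmin, bb$xmax, res, pad)
  yg <- .grid_axis(bb$ymin, bb$ymax, res, pad)
  g <- expand.grid(x = xg, y = yg)

  # per-source-slice scaled in-plane squared distance (0 inside the polygons);
  # +x = left margin, -x = right, +y = posterior, -y = anterior
  E2 <- lapply(ctv$slices, function(sl) {
    Q <- do.call(rbind, lapply(sl$polys, .sample_closed, step = res / 2))
    v <- .scaled_sq_field(g$x, g$y, Q, m_left, m_right, m_post, m_ant)
    v[.points_in_polys(g$x, g$y, sl$polys)] <- 0
    v
  })

  n_up <- ceiling(m_sup / dz); n_dn <- ceiling(m_inf / dz)
  zout <- seq(min(zs) - n_dn * dz, max(zs) + n_up * dz, by = dz)
  big <- 1e6
  slices <- list()
  for (z in zout) {
    D2 <- rep(big, nrow(g))
    for (i in seq_along(zs)) {
      dzv <- z - zs[i]
      zt <- if (abs(dzv) < 1e-9) 0
      else {
        s <- if (dzv > 0) m_sup else m_inf
        if (s > 0) (dzv / s)^2 else big
      }
      if (zt >= 1) next
      D2 <- pmin(D2, E2[[i]] + zt)
    }
    if (all(D2 > 1)) next
    polys <- .contours_from_field(xg, yg, sqrt(pmin(D2, 4)), 1)
    if (length(polys) > 0L) {
      slices[[length(slices) + 1L]] <- list(z = z, polys = polys)
    }
  }
  contour_stack(paste0(ctv$name, "_expanded"), slices, dz)
}

#' Build an inner wall shell of an organ
#'
#' Creates the wall structure of a hollow organ (e.g. the 3 mm rectal wall,
#' RW) by eroding the organ inward by `cfg$wall_thickness` and subtracting:
#' the wall is the set of points closer than the thickness to the organ
#' surface.  The erosion is three-dimensional: the distance of an interior
#' point to the surface is taken as the minimum 3D distance to the contour
#' curves of nearby slices and to the end caps, so the shell of a sphere
#' matches the closed-form spherical shell.  Slices where the organ is
#' everywhere thinner than the wall contribute the whole slice (with a
#' message), mirroring planning-system behaviour for collapsed lumens.
#'
#' @param organ Input [contour_stack()] (non-empty).
#' @param cfg A [structure_recipe()]; `wall_thickness` and
#'   `raster_resolution` are used.  A thickness of 0 yields an empty wall.
#' @return A [contour_stack()] whose slices contain the organ contour plus
#'   the eroded contour as a hole (even-odd rule).
#' @export
make_wall <- function(organ, cfg = structure_recipe()) {
  if (!is_contour_stack(organ)) stop("'organ' must be a contour_stack")
  if (length(organ$slices) == 0L) stop("cannot build a wall of an empty stack")
  t <- cfg$wall_thickness
  res <- cfg$raster_resolution
  if (t == 0) {
    return(contour_stack(paste0(organ$name, "_wall"), list(),
                         organ$slice_spacing))
  }
  dz <- organ$slice_spacing
  zs <- stack_z(organ)
  nz <- length(zs)
  bb <- .stacks_bbox(list(organ))
  xg <- .grid_axis(bb$xmin, bb$xmax, res, res)
  yg <- .grid_axis(bb$ymin, bb$ymax, res, res)
  g <- expand.grid(x = xg, y = yg)

  curve_d <- lapply(organ$slices, function(sl) {
    Q <- do.call(rbind, lapply(sl$polys, .sample_closed, step = res / 2))
    .pt_dist_field(g$x, g$y, Q)
  })
  inside <- lapply(organ$slices,
                   function(sl) .points_in_polys(g$x, g$y, sl$polys))
  # virtual half-slice curves (averaged distance fields) reduce the
  # z-quantization bias of the surface-distance estimate
  zs_all <- zs
  d_all <- curve_d
  if (nz > 1L) {
    for (j in seq_len(nz - 1L)) {
      if (abs(zs[j + 1L] - zs[j] - dz) < 1e-6) {
        zs_all <- c(zs_all, (zs[j] + zs[j + 1L]) / 2)
        d_all <- c(d_all, list((curve_d[[j]] + curve_d[[j + 1L]]) / 2))
      }
    }
  }

  full_slices <- 0L
  slices <- vector("list", nz)
  for (i in seq_len(nz)) {
    # 3D distance to the surface: nearby slice curves ...
    d3 <- rep(Inf, nrow(g))
    for (j in seq_along(zs_all)) {
      dzv <- zs_all[j] - zs[i]
      if (abs(dzv) > t + dz) next
      d3 <- pmin(d3, sqrt(d_all[[j]]^2 + dzv^2))
    }
    # ... and the end caps half a slice beyond the extreme slices
    cap_top <- (zs[nz] + dz / 2) - zs[i]
    if (cap_top <= t) d3 <- pmin(d3, ifelse(inside[[nz]], cap_top, Inf))
    cap_bot <- zs[i] - (zs[1] - dz / 2)
    if (cap_bot <= t) d3 <- pmin(d3, ifelse(inside[[1]], cap_bot, Inf))

    F <- ifelse(inside[[i]], pmin(d3, t + 2 * res), -curve_d[[i]])
    eroded <- .contours_from_field(xg, yg, F, t)
    if (length(eroded) == 0L) full_slices <- full_slices + 1L
    slices[[i]] <- list(z = zs[i], polys = c(organ$slices[[i]]$polys, eroded))
  }
  if (full_slices > 0L) {
    message(sprintf(
      "make_wall: %d slice(s) thinner than the wall; whole slice kept",
      full_slices))
  }
  contour_stack(paste0(organ$name, "_wall"), slices, dz)
}

#' Height-limit a wall structure to the PTV extent
#'
#' Truncates a (wall) structure to the axial interval reaching
#' `cfg$height_limit_extent` mm (default 17.5) beyond the most superior and
#' inferior PTV slices, producing the optimization structure used for rectal
#' and bladder walls in hypofractionated prostate planning.  Retained slices
#' are passed through unchanged, so the operation is idempotent.
#'
#' @param wall Input [contour_stack()].
#' @param ptv PTV [contour_stack()] on the same slice grid.
#' @param cfg A [structure_recipe()]; `height_limit_extent` is used.
#' @return The truncated [contour_stack()]; empty (with a warning) when the
#'   z ranges are disjoint.
#' @export
height_limit <- function(wall, ptv, cfg = structure_recipe()) {
  if (!is_contour_stack(wall) || !is_contour_stack(ptv)) {
    stop("'wall' and 'ptv' must be contour_stacks")
  }
  if (length(ptv$slices) == 0L) stop("'ptv' is empty")
  ext <- cfg$height_limit_extent
  zp <- stack_z(ptv)
  lo <- min(zp) - ext - 1e-9
  hi <- max(zp) + ext + 1e-9
  keep <- vapply(wall$slices, function(s) s$z >= lo && s$z <= hi, logical(1))
  if (!any(keep)) {
    warning("height_limit: structure and PTV z ranges are disjoint; ",
            "empty result")
  }
  contour_stack(wall$name, wall$slices[keep], wall$slice_spacing)
}

#' Volume of a contour stack
#'
#' Slice-summed volume: the even-odd polygon area of every slice (shoelace
#' formula on the vector contours, holes subtracted) times the slice spacing.
#'
#' @param s A [contour_stack()].
#' @return Volume in cc (1 cc = 1000 mm^3).
#' @export
structure_volume <- function(s) {
  if (!is_contour_stack(s)) stop("'s' must be a contour_stack")
  if (length(s$slices) == 0L) return(0)
  a <- vapply(s$slices, function(sl) .slice_area(sl$polys), numeric(1))
  sum(a) * s$slice_spacing / 1000
}

#' Overlap volume of two structures (boolean intersection)
#'
#' Rasterized intersection volume, the operation behind the rectum-in-PTV
#' (RinPTV) predictor.  Slices of `b` are matched to the z grid of `a`
#' (nearest slice within half a spacing); each matched slice pair is rendered
#' on a shared half-resolution grid and the common area accumulated.
#'
#' @param a,b [contour_stack()] objects.
#' @param resolution In-plane raster resolution in mm (default 0.5).
#' @return Intersection volume in cc; 0 for disjoint structures.
#' @export
overlap_volume <- function(a, b, resolution = 0.5) {
  if (!is_contour_stack(a) || !is_contour_stack(b)) {
    stop("'a' and 'b' must be contour_stacks")
  }
  if (length(a$slices) == 0L || length(b$slices) == 0L) return(0)
  idx <- .match_slices(a, b)
  bba <- .stacks_bbox(list(a)); bbb <- .stacks_bbox(list(b))
  xmin <- max(bba$xmin, bbb$xmin); xmax <- min(bba$xmax, bbb$xmax)
  ymin <- max(bba$ymin, bbb$ymin); ymax <- min(bba$ymax, bbb$ymax)
  if (xmin >= xmax || ymin >= ymax) return(0)
  xg <- .grid_axis(xmin, xmax, resolution)
  yg <- .grid_axis(ymin, ymax, resolution)
  g <- expand.grid(x = xg, y = yg)
  cell <- resolution^2
  vol <- 0
  for (i in seq_along(a$slices)) {
    j <- idx[i]
    if (is.na(j)) next
    ina <- .points_in_polys(g$x, g$y, a$slices[[i]]$polys)
    if (!any(ina)) next
    inb <- .points_in_polys(g$x[ina], g$y[ina], b$slices[[j]]$polys)
    vol <- vol + sum(inb) * cell
  }
  vol * a$slice_spacing / 1000
}

#' Slice-wise Hausdorff distance between two contours
#'
#' Hausdorff distance between the boundary curves of two 2D contours: the
#' larger of the two directed distances, each being the farthest any point of
#' one curve lies from the other curve.  Distances are between the *curves*
#' (not the filled regions); the symmetric form is the default, with the
#' one-directional variant available via `directed`.
#'
#' Each curve is resampled at `step` mm and measured against the exact
#' segments of the other curve, so the result is accurate to well under the
#' sampling step.
#'
#' @param p,q Polygon vertex matrices (n x 2, mm) or lists of such matrices
#'   (multiple contours on a slice are treated as one merged boundary).
#' @param directed `FALSE` (symmetric, default), `"pq"` or `"qp"`.
#' @param step Boundary sampling step in mm (default 0.2).
#' @return Distance in cm.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 73)[-73]
#' c1 <- cbind(10 * cos(th), 10 * sin(th))
#' c2 <- cbind(25 * cos(th), 25 * sin(th))
#' slice_hausdorff(c1, c2)  # 1.5 cm
#' @export
slice_hausdorff <- function(p, q, directed = FALSE, step = 0.2) {
  P <- .as_poly_list(p); Q <- .as_poly_list(q)
  d_pq <- .directed_hausdorff_mm(P, Q, step)
  if (identical(directed, "pq")) return(d_pq / 10)
  d_qp <- .directed_hausdorff_mm(Q, P, step)
  if (identical(directed, "qp")) return(d_qp / 10)
  max(d_pq, d_qp) / 10
}

.as_poly_list <- function(p) {
  polys <- if (is.list(p) && !is.data.frame(p)) p else list(p)
  polys <- lapply(polys, .normalize_polygon)
  polys <- polys[vapply(polys, Negate(is.null), logical(1))]
  if (length(polys) == 0L) stop("degenerate polygon: need >= 3 distinct vertices")
  polys
}

.directed_hausdorff_mm <- function(P, Q, step) {
  S <- do.call(rbind, lapply(P, .sample_closed, step = step))
  max(.curves_dist_min(S[, 1], S[, 2], Q))
}

#' Mean slice-wise Hausdorff distance between two structures
#'
#' The rectal-wall-to-CTV distance metric: the 2D Hausdorff distance is
#' evaluated on every CT slice where *both* structures have at least one
#' contour, and the unweighted mean over those slices is returned.  Slices
#' present in only one structure are excluded, which is why the height-limited
#' wall (consistent superior/inferior extent) is the intended input.
#'
#' @param rw17 First [contour_stack()] (typically the height-limited rectal
#'   wall).
#' @param ctv Second [contour_stack()] (typically the CTV).
#' @param step Boundary sampling step in mm.
#' @return Mean slice Hausdorff distance in cm.
#' @export
mean_slice_hausdorff <- function(rw17, ctv, step = 0.2) {
  if (length(rw17$slices) == 0L || length(ctv$slices) == 0L) {
    stop("both structures must be non-empty")
  }
  idx <- .match_slices(rw17, ctv)
  common <- which(!is.na(idx))
  if (length(common) == 0L) stop("no common slices between the two structures")
  d <- vapply(common, function(i) {
    slice_hausdorff(rw17$slices[[i]]$polys, ctv$slices[[idx[i]]]$polys,
                    step = step)
  }, numeric(1))
  mean(d)
}
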