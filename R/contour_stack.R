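#' Per-slice contour representation of a 3D structure
#'
#' A `contour_stack` is the universal structure container used throughout the
#' package: an ordered set of axial slices, each holding one or more closed 2D
#' polygons in patient coordinates (x = patient left, y = patient posterior,
#' both in mm; z = patient superior).  Multiple polygons on a slice are
#' interpreted with the even-odd rule, so a polygon nested inside another is a
#' hole.  This is the in-memory analogue of a treatment-planning-system ROI
#' (rectum, rectal wall, CTV, PTV, bladder, hydrogel spacer, ...).
#'
#' Polygons are stored *open* (the closing edge from last to first vertex is
#' implicit); an explicitly repeated first vertex is stripped on construction.
#'
#' @param name Structure label.
#' @param slices List of slices, each a list with elements `z` (slice position
#'   in mm) and `polys` (list of n x 2 numeric matrices of vertices in mm).
#'   Slices are sorted by `z` on construction.
#' @param slice_spacing Slice spacing in mm (> 0).
#' @return An object of class `contour_stack`.
#' @examples
#' sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
#' cube <- contour_stack("cube", list(
#'   list(z = 1, polys = list(sq)),
#'   list(z = 3, polys = list(sq))
#' ), slice_spacing = 2)
#' structure_volume(cube)
#' @export
contour_stack <- function(name, slices, slice_spacing) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(slice_spacing) || length(slice_spacing) != 1L ||
      slice_spacing <= 0) {
    stop("'slice_spacing' must be a single positive number (mm)")
  }
  slices <- lapply(slices, function(s) {
    if (is.null(s$z) || !is.finite(s$z)) stop("every slice needs a finite 'z'")
    polys <- lapply(s$polys, .normalize_polygon)
    polys <- polys[vapply(polys, Negate(is.null), logical(1))]
    list(z = as.numeric(s$z), polys = polys)
  })
  slices <- slices[vapply(slices, function(s) length(s$polys) > 0L, logical(1))]
  if (length(slices) > 0L) {
    z <- vapply(slices, `[[`, numeric(1), "z")
    slices <- slices[order(z)]
    z <- sort(z)
    if (anyDuplicated(z)) stop("slice z positions must be strictly increasing")
    if (length(z) > 1L) {
      dz <- diff(z)
      # slices may legitimately skip positions (empty slices dropped); every
      # gap must still be a whole multiple of the spacing
      mult <- dz / slice_spacing
      if (any(abs(mult - round(mult)) > 1e-6)) {
        stop("slice z positions are not on a uniform grid of 'slice_spacing'")
      }
    }
  }
  structure(list(name = name, slices = slices, slice_spacing = slice_spacing),
            class = "contour_stack")
}

#' @rdname contour_stack
#' @param x Object to test or print.
#' @export
is_contour_stack <- function(x) inherits(x, "contour_stack")

#' @export
print.contour_stack <- function(x, ...) {
  nz <- length(x$slices)
  cat(sprintf("<contour_stack> %s: %d slice(s), spacing %.3g mm", x$name, nz,
              x$slice_spacing))
  if (nz > 0L) {
    z <- stack_z(x)
    cat(sprintf(", z in [%.1f, %.1f] mm, volume %.2f cc",
                min(z), max(z), structure_volume(x)))
  }
  cat("\n")
  invisible(x)
}

#' Slice z positions of a contour stack
#'
#' @param s A `contour_stack`.
#' @return Numeric vector of slice positions (mm), increasing.
#' @export
stack_z <- function(s) {
  vapply(s$slices, `[[`, numeric(1), "z")
}

# strip an explicit closing vertex, drop degenerate polygons
.normalize_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L) stop("polygon vertices must be an n x 2 matrix")
  storage.mode(p) <- "double"
  n <- nrow(p)
  if (n >= 2L && all(abs(p[n, ] - p[1, ]) < 1e-9)) p <- p[-n, , drop = FALSE]
  if (nrow(unique(round(p, 9))) < 3L) return(NULL)
  unname(p)
}

#' Analytic shape constructors
#'
#' Convenience builders for contour stacks of simple solids sampled on an
#' axial slice grid aligned to whole multiples of `slice_spacing`.  They are
#' used by the phantom generator and by the test suite to compare rasterized
#' geometry against closed-form volumes.
#'
#' @param center Numeric length-3 centre (mm) for solids, length-2 (x, y) for
#'   `cs_cylinder`.
#' @param radius Radius in mm.
#' @param semiaxes Length-3 ellipsoid semi-axes (mm) along x, y, z.
#' @param z_range Length-2 axial extent (mm) for the cylinder.
#' @param xlim,ylim,zlim Length-2 extents (mm) for the cuboid.
#' @param slice_spacing Slice spacing in mm.
#' @param n_vertices Number of polygon vertices per contour.
#' @param name Structure label.
#' @param center_fun Optional function `z -> c(x, y)` giving a per-slice
#'   cylinder axis position (for bowed tubes such as a rectum).
#' @return A [contour_stack()].
#' @export
cs_sphere <- function(center = c(0, 0, 0), radius, slice_spacing = 2,
                      n_vertices = 180L, name = "sphere") {
  cs_ellipsoid(center, rep(radius, 3L), slice_spacing, n_vertices, name)
}

#' @rdname cs_sphere
#' @export
cs_ellipsoid <- function(center = c(0, 0, 0), semiaxes, slice_spacing = 2,
                         n_vertices = 180L, name = "ellipsoid") {
  stopifnot(length(center) == 3L, length(semiaxes) == 3L, all(semiaxes > 0))
  z <- .z_grid(center[3] - semiaxes[3], center[3] + semiaxes[3], slice_spacing)
  slices <- list()
  for (zi in z) {
    u <- 1 - ((zi - center[3]) / semiaxes[3])^2
    if (u <= 1e-9) next
    s <- sqrt(u)
    slices[[length(slices) + 1L]] <- list(
      z = zi,
      polys = list(.ellipse_poly(center[1:2], semiaxes[1] * s, semiaxes[2] * s,
                                 n_vertices)))
  }
  contour_stack(name, slices, slice_spacing)
}

#' @rdname cs_sphere
#' @export
cs_cylinder <- function(center = c(0, 0), radius, z_range, slice_spacing = 2,
                        n_vertices = 180L, name = "cylinder",
                        center_fun = NULL) {
  stopifnot(length(center) == 2L, radius > 0, length(z_range) == 2L)
  z <- .z_grid(min(z_range), max(z_range), slice_spacing)
  slices <- lapply(z, function(zi) {
    c0 <- if (is.null(center_fun)) center else center_fun(zi)
    list(z = zi, polys = list(.ellipse_poly(c0, radius, radius, n_vertices)))
  })
  contour_stack(name, slices, slice_spacing)
}

#' @rdname cs_sphere
#' @export
cs_cuboid <- function(xlim, ylim, zlim, slice_spacing = 2, name = "cuboid") {
  z <- .z_grid(min(zlim), max(zlim), slice_spacing)
  poly <- rbind(c(xlim[1], ylim[1]), c(xlim[2], ylim[1]),
                c(xlim[2], ylim[2]), c(xlim[1], ylim[2]))
  slices <- lapply(z, function(zi) list(z = zi, polys = list(poly)))
  contour_stack(name, slices, slice_spacing)
}

# slice positions: whole multiples of dz strictly inside (lo, hi)
.z_grid <- function(lo, hi, dz) {
  k <- seq(ceiling(lo / dz - 1e-9), floor(hi / dz + 1e-9))
  z <- k * dz
  z[z > lo - 1e-9 & z < hi + 1e-9]
}

.ellipse_poly <- function(center, a, b, n = 180L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + a * cos(th), center[2] + b * sin(th))
}
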