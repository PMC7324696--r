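# Internal raster / distance-field machinery shared by the geometry, DVH and
# surrogate-dose code.  All quantities are mm.  Grids are axis-aligned and
# snapped to whole multiples of the resolution so that grids built
# independently for different structures coincide.

`%||%` <- function(a, b) if (is.null(a)) b else a

.grid_axis <- function(lo, hi, res, pad = 0) {
  lo <- floor((lo - pad) / res) * res - res
  hi <- ceiling((hi + pad) / res) * res + res
  seq(lo, hi, by = res)
}

# bounding box over all polygons of a list of stacks
.stacks_bbox <- function(stacks) {
  xs <- ys <- numeric(0)
  for (s in stacks) for (sl in s$slices) for (p in sl$polys) {
    xs <- c(xs, range(p[, 1])); ys <- c(ys, range(p[, 2]))
  }
  if (length(xs) == 0L) return(NULL)
  list(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

# even-odd membership of points in a set of polygons
.points_in_polys <- function(px, py, polys) {
  inside <- rep(FALSE, length(px))
  for (p in polys) {
    inside <- xor(inside, pracma::inpolygon(px, py, p[, 1], p[, 2]))
  }
  inside
}

# resample a closed polygon boundary at approximately 'step' mm
.sample_closed <- function(p, step) {
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- p[i, ]; b <- p[nxt[i], ]
    len <- sqrt(sum((b - a)^2))
    m <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = m + 1L)[-(m + 1L)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

.row_mins <- function(M) {
  if (is.null(dim(M))) return(M)
  do.call(pmin, lapply(seq_len(ncol(M)), function(j) M[, j]))
}

# minimum squared anisotropically-scaled distance from grid points to a set of
# sampled boundary points Q.  The scale applied to each displacement component
# depends on its sign (mxp toward +x, mxn toward -x, ...), which is how an
# asymmetric expansion margin (e.g. 5 mm posterior, 7 mm elsewhere) is encoded.
# A zero margin admits only zero displacement along that axis.
.scaled_sq_field <- function(gx, gy, Q, mxp, mxn, myp, myn, big = 1e6) {
  if (is.null(Q) || nrow(Q) == 0L) return(rep(big, length(gx)))
  dx <- outer(gx, Q[, 1], "-")
  dy <- outer(gy, Q[, 2], "-")
  sx <- ifelse(dx >= 0, mxp, mxn)
  sy <- ifelse(dy >= 0, myp, myn)
  tx <- ifelse(sx > 0, (dx / ifelse(sx > 0, sx, 1))^2,
               ifelse(abs(dx) < 1e-9, 0, big))
  ty <- ifelse(sy > 0, (dy / ifelse(sy > 0, sy, 1))^2,
               ifelse(abs(dy) < 1e-9, 0, big))
  .row_mins(tx + ty)
}

# plain (unscaled) minimum distance from grid points to sampled boundary points
.pt_dist_field <- function(gx, gy, Q) {
  if (is.null(Q) || nrow(Q) == 0L) return(rep(Inf, length(gx)))
  d2 <- outer(gx, Q[, 1], "-")^2 + outer(gy, Q[, 2], "-")^2
  sqrt(.row_mins(d2))
}

# exact minimum distance from points to the closed polyline of one polygon
.seg_dist_min <- function(px, py, poly) {
  n <- length(px); m <- nrow(poly)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  vx <- bx - ax; vy <- by - ay
  L2 <- pmax(vx^2 + vy^2, 1e-12)
  wx <- outer(px, ax, "-")
  wy <- outer(py, ay, "-")
  tt <- (wx * matrix(vx, n, m, byrow = TRUE) +
           wy * matrix(vy, n, m, byrow = TRUE)) / matrix(L2, n, m, byrow = TRUE)
  tt[tt < 0] <- 0; tt[tt > 1] <- 1
  ex <- wx - tt * matrix(vx, n, m, byrow = TRUE)
  ey <- wy - tt * matrix(vy, n, m, byrow = TRUE)
  sqrt(.row_mins(ex^2 + ey^2))
}

# exact minimum distance from points to a *list* of polygons' boundaries
.curves_dist_min <- function(px, py, polys) {
  d <- rep(Inf, length(px))
  for (p in polys) d <- pmin(d, .seg_dist_min(px, py, p))
  d
}

# extract level-set contours of a scalar field sampled on (xg, yg);
# F is a vector in expand.grid(xg, yg) order
.contours_from_field <- function(xg, yg, F, level, min_area = 1e-3) {
  M <- matrix(F, nrow = length(xg))
  cl <- grDevices::contourLines(xg, yg, M, levels = level)
  polys <- lapply(cl, function(c0) cbind(c0$x, c0$y))
  polys <- lapply(polys, .normalize_polygon)
  polys <- polys[vapply(polys, Negate(is.null), logical(1))]
  polys[vapply(polys, function(p) .shoelace(p) > min_area, logical(1))]
}

.shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# even-odd area of a slice: nested polygons alternate sign (holes subtract)
.slice_area <- function(polys) {
  k <- length(polys)
  if (k == 0L) return(0)
  if (k == 1L) return(.shoelace(polys[[1]]))
  areas <- vapply(polys, .shoelace, numeric(1))
  depth <- integer(k)
  for (i in seq_len(k)) {
    v <- polys[[i]][1, ]
    for (j in seq_len(k)) {
      if (i == j) next
      if (pracma::inpolygon(v[1], v[2], polys[[j]][, 1], polys[[j]][, 2])) {
        depth[i] <- depth[i] + 1L
      }
    }
  }
  sum(areas * ifelse(depth %% 2L == 0L, 1, -1))
}

# match slices of stack b onto the z grid of stack a; returns an index vector
# over a's slices with NA where b has no slice within half a spacing
.match_slices <- function(a, b) {
  za <- stack_z(a); zb <- stack_z(b)
  tol <- min(a$slice_spacing, b$slice_spacing) / 2 + 1e-9
  vapply(za, function(z) {
    i <- which.min(abs(zb - z))
    if (length(i) == 1L && abs(zb[i] - z) <= tol) i else NA_integer_
  }, integer(1))
}
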