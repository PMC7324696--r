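# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (dense sampling, explicit loops) so they never share code
# paths with the implementation they check.

circle_poly <- function(cx = 0, cy = 0, r = 10, n = 144L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

square_poly <- function(x0 = 0, y0 = 0, side = 10) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

# random star-shaped polygon (non-self-intersecting by construction)
random_star_poly <- function(n = 24L, r_base = 10, wobble = 0.35) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- r_base * (1 + wobble * (runif(n) - 0.5))
  cx <- runif(1, -5, 5); cy <- runif(1, -5, 5)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# dense point sampling of a closed polygon boundary
dense_boundary <- function(p, step = 0.1) {
  n <- nrow(p)
  out <- list()
  for (i in seq_len(n)) {
    a <- p[i, ]; b <- p[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    m <- max(2L, ceiling(len / step) + 1L)
    t <- seq(0, 1, length.out = m)[-m]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

# brute-force symmetric Hausdorff distance (mm) over densely sampled points
bf_hausdorff_mm <- function(p, q, step = 0.1) {
  P <- dense_boundary(p, step); Q <- dense_boundary(q, step)
  d2 <- outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2
  max(max(apply(d2, 1, min)), max(apply(d2, 2, min)))^0.5
}

# brute-force cumulative DVH by explicit voxel loop with the same 2x2
# supersampled-centre membership rule
bf_v_at_dose <- function(dose, s, threshold) {
  xc <- dose$origin[1] + (seq_len(dose$dims[1]) - 1) * dose$spacing[1]
  yc <- dose$origin[2] + (seq_len(dose$dims[2]) - 1) * dose$spacing[2]
  zc <- dose$origin[3] + (seq_len(dose$dims[3]) - 1) * dose$spacing[3]
  total <- 0; above <- 0
  for (sl in s$slices) {
    k <- which.min(abs(zc - sl$z))
    if (abs(zc[k] - sl$z) > min(dose$spacing[3], s$slice_spacing) / 2 + 1e-9) next
    for (i in seq_along(xc)) for (j in seq_along(yc)) {
      w <- 0
      for (ox in c(-1, 1)) for (oy in c(-1, 1)) {
        px <- xc[i] + ox * dose$spacing[1] / 4
        py <- yc[j] + oy * dose$spacing[2] / 4
        inside <- FALSE
        for (pg in sl$polys) {
          inside <- xor(inside, pracma::inpolygon(px, py, pg[, 1], pg[, 2]))
        }
        if (inside) w <- w + 0.25
      }
      if (w > 0) {
        total <- total + w
        if (dose$values[i, j, k] >= threshold) above <- above + w
      }
    }
  }
  100 * above / total
}

# explicit leave-one-out refits
bf_loocv <- function(data, terms, dependent) {
  n <- nrow(data)
  fml <- stats::reformulate(terms, response = dependent)
  errs <- vapply(seq_len(n), function(i) {
    f <- stats::lm(fml, data = data[-i, ])
    unname(data[[dependent]][i] - stats::predict(f, data[i, , drop = FALSE]))
  }, numeric(1))
  y <- data[[dependent]]
  list(press = sum(errs^2),
       predicted_r_squared = 1 - sum(errs^2) / sum((y - mean(y))^2),
       mae = mean(abs(errs)))
}

# brute-force VIF from individual regressions
bf_vif <- function(X) {
  X <- as.data.frame(X)
  sapply(names(X), function(j) {
    r2 <- summary(stats::lm(
      stats::reformulate(setdiff(names(X), j), response = j), data = X))$r.squared
    1 / (1 - r2)
  })
}
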