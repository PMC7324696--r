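# The linear-model pipeline: screening, fitting, selection, validation.

test_that("Pearson screening handles exact, orthogonal and invalid input", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  set.seed(2)
  a <- rnorm(50)
  b <- rnorm(50)
  b <- residuals(lm(b ~ a))   # orthogonalized
  expect_lt(abs(pearson_cor(a, b)$r), 1e-12)
  expect_error(pearson_cor(rep(1, 10), x), "constant")
})

test_that("the generator reproduces the published predictor-endpoint correlation", {
  coh <- simulate_cohort(cohort_sim_config(n = 1000, seed = 7))
  r <- pearson_cor(coh$norm_rinptv_pct, coh$delta_rv55_pct)$r
  expect_equal(r, 0.90, tolerance = 0.02 / 0.90)
})

test_that("OLS recovers noiseless coefficients and the centroid identity", {
  set.seed(4)
  d <- data.frame(norm_rinptv_pct = runif(21, 0.2, 10.4))
  d$delta_rv55_pct <- 0.73 + 1.10 * d$norm_rinptv_pct
  m <- suppressWarnings(ols_fit(d, "delta_rv55_pct", "norm_rinptv_pct"))
  expect_equal(m$intercept$estimate, 0.73, tolerance = 1e-10)
  expect_equal(m$terms$estimate, 1.10, tolerance = 1e-10)
  # centroid property on a noisy fit
  d$delta_rv55_pct <- d$delta_rv55_pct + rnorm(21)
  m2 <- ols_fit(d, "delta_rv55_pct", "norm_rinptv_pct")
  at_mean <- predict(m2, data.frame(norm_rinptv_pct = mean(d$norm_rinptv_pct)),
                     warn_extrapolation = FALSE)
  expect_equal(at_mean, mean(d$delta_rv55_pct))
  # degenerate constant response
  d$delta_rv55_pct <- rep(3, 21)
  expect_warning(m3 <- ols_fit(d, "delta_rv55_pct", "norm_rinptv_pct"),
                 "constant")
  expect_equal(m3$intercept$estimate, 3)
  expect_equal(m3$r_squared, 0)
})

test_that("the Gaussian-profile AIC obeys its closed-form deltas", {
  set.seed(9)
  d <- data.frame(x1 = rnorm(21), x2 = rnorm(21))
  d$y <- d$x1 + rnorm(21)
  m1 <- ols_fit(d, "y", "x1")
  m2 <- ols_fit(d, "y", c("x1", "x2"))
  # same RSS, one extra parameter -> AIC larger by exactly 2
  m2_same_rss <- m2; m2_same_rss$rss <- m1$rss
  expect_equal(model_aic(m2_same_rss) - model_aic(m1), 2)
  # halving the RSS at fixed size lowers AIC by n log 2
  m_half <- m1; m_half$rss <- m1$rss / 2
  expect_equal(model_aic(m1) - model_aic(m_half), 21 * log(2))
  # zero RSS sentinel
  m0 <- m1; m0$rss <- 0
  expect_warning(a0 <- model_aic(m0), "zero")
  expect_identical(a0, -Inf)
})

test_that("AIC ranks models identically to likelihood-based AIC", {
  set.seed(10)
  n <- 30
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- d$x1 + 0.5 * d$x2 + rnorm(n)
  specs <- list("x1", "x2", "x3", c("x1", "x2"), c("x1", "x3"),
                c("x2", "x3"), c("x1", "x2", "x3"), c("x3", "x2"),
                c("x2", "x1"), c("x3", "x1", "x2"))
  ours <- vapply(specs, function(tm) model_aic(ols_fit(d, "y", tm)),
                 numeric(1))
  rs <- vapply(specs, function(tm)
    AIC(lm(reformulate(tm, "y"), data = d)), numeric(1))
  expect_identical(order(ours), order(rs))
})

test_that("VIF matches brute force and flags collinearity", {
  set.seed(12)
  n <- 60
  # orthogonal centred columns -> all VIF 1
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-9)
  # near-duplicate -> huge VIF
  X2 <- data.frame(a = rnorm(n))
  X2$b <- X2$a + rnorm(n, 0, 1e-4)
  expect_gt(max(vif(X2)), 5)
  # random design equals brute force
  X3 <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  X3$b <- X3$b + 0.7 * X3$a
  expect_equal(vif(X3), bf_vif(X3), tolerance = 1e-10)
  # exact collinearity -> Inf sentinel
  X4 <- data.frame(a = rnorm(n))
  X4$b <- 2 * X4$a
  expect_true(any(is.infinite(vif(X4))))
})

test_that("backward stepwise selection recovers the true support", {
  set.seed(3)
  n <- 200
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- 2 * d$a + rnorm(n, 0, sqrt(4 / 10))   # SNR 10
  sel <- stepwise_select(d, "y", stepwise_config(candidates = c("a", "b", "c"),
                                                 exclusive_groups = list()))
  expect_identical(sel$model$terms$term, "a")
  # agrees with the reference backward-AIC implementation
  st <- step(lm(y ~ a + b + c, data = d), direction = "backward", trace = 0)
  expect_setequal(sel$model$terms$term, names(coef(st))[-1])
  # report carries the full machinery
  expect_s3_class(sel$report$pearson_table, "data.frame")
  expect_true(nrow(sel$report$aic_trace) >= 1)
  expect_equal(sel$report$alpha, 0.01)
})

test_that("perfectly duplicated predictors are reduced to one", {
  set.seed(14)
  n <- 40
  d <- data.frame(a = rnorm(n))
  d$b <- d$a + rnorm(n, 0, 1e-6)
  d$y <- d$a + rnorm(n, 0, 0.3)
  sel <- stepwise_select(d, "y", stepwise_config(candidates = c("a", "b"),
                                                 exclusive_groups = list()))
  expect_equal(nrow(sel$model$terms), 1L)
  expect_true(all(sel$report$vif_table$vif < 5))
})

test_that("selection respects exclusive groups and the size cap", {
  set.seed(15)
  n <- 60
  d <- data.frame(rectum_vol_cc = rnorm(n, 80, 20))
  d$rw_vol_cc <- 0.45 * d$rectum_vol_cc + rnorm(n, 0, 2)
  d$x1 <- rnorm(n); d$x2 <- rnorm(n); d$x3 <- rnorm(n); d$x4 <- rnorm(n)
  d$y <- 0.05 * d$rectum_vol_cc + d$x1 + d$x2 + d$x3 + 0.5 * d$x4 + rnorm(n)
  cfg <- stepwise_config(candidates = c("rectum_vol_cc", "rw_vol_cc",
                                        "x1", "x2", "x3", "x4"),
                         max_predictors = 3)
  sel <- stepwise_select(d, "y", cfg)
  expect_lte(nrow(sel$model$terms), 3L)
  expect_lt(sum(c("rectum_vol_cc", "rw_vol_cc") %in% sel$model$terms$term), 2L)
  expect_true(all(sel$report$vif_table$vif < 5))
})

test_that("structure coefficients obey the defining identity", {
  set.seed(16)
  d <- data.frame(x = rnorm(30))
  d$y <- d$x + rnorm(30)
  m <- ols_fit(d, "y", "x")
  sc <- structure_coefficients(m, d)
  # single-predictor model: rs^2 = 1 identically
  expect_equal(sc$rs2, 1, tolerance = 1e-12)
  # printed-value combinations
  expect_equal(structure_coefficient(0.90, 0.81)^2, 1.00, tolerance = 5e-3)
  expect_equal(structure_coefficient(0.54, 0.88)^2, 0.33, tolerance = 0.005 / 0.33)
  expect_error(structure_coefficient(0.5, 0), "> 0")
})

test_that("LOOCV via the hat matrix equals explicit refits", {
  set.seed(17)
  for (k in 1:10) {
    n <- sample(15:30, 1)
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- d$x1 - d$x2 + rnorm(n)
    lv <- loocv(d, c("x1", "x2"), "y")
    bf <- bf_loocv(d, c("x1", "x2"), "y")
    expect_equal(lv$press, bf$press, tolerance = 1e-8)
    expect_equal(lv$predicted_r_squared, bf$predicted_r_squared,
                 tolerance = 1e-8)
    expect_equal(lv$mae, bf$mae, tolerance = 1e-8)
  }
  # noiseless data: perfect prediction
  d <- data.frame(x = 1:20, y = 3 + 2 * (1:20))
  lv0 <- loocv(d, "x", "y")
  expect_equal(lv0$predicted_r_squared, 1, tolerance = 1e-12)
  expect_equal(lv0$mae, 0, tolerance = 1e-10)
})

test_that("relative MAE normalizes by the response range", {
  expect_equal(relative_mae(0.96, c(0.8, 10.8)), 9.60)
  expect_equal(relative_mae(1.29, c(0, 10)), 12.90)
  expect_error(relative_mae(1, c(2, 2)), "range")
})

test_that("predicted R-squared rarely exceeds the training R-squared", {
  set.seed(18)
  bad <- 0
  for (k in 1:100) {
    n <- 21
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- 0.5 * d$x1 + rnorm(n)
    m <- ols_fit(d, "y", c("x1", "x2"))
    lv <- loocv(d, c("x1", "x2"), "y")
    if (lv$predicted_r_squared > m$r_squared + 0.02) bad <- bad + 1
  }
  expect_equal(bad, 0)
})
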