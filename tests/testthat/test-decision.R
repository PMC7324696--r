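# Published models, flowchart logic and nomograms.

test_that("the registry ships the published coefficients verbatim", {
  reg <- published_models()
  expect_setequal(names(reg), c("delta_model1", "delta_model2",
                                "pre_model1", "pre_model2"))
  d2 <- reg$delta_model2
  expect_equal(d2$intercept$estimate, 0.73)
  expect_equal(d2$intercept$se, 0.51)
  expect_equal(d2$terms$estimate, 1.10)
  expect_equal(d2$terms$rs2, 1.00)
  expect_equal(d2$r_squared, 0.81)
  expect_equal(d2$pct_mae, 9.60)
  d1 <- reg$delta_model1
  expect_equal(d1$terms$estimate[d1$terms$term == "rectum_vol_cc"], -0.0077)
  p1 <- reg$pre_model1
  expect_equal(p1$terms$estimate[p1$terms$term == "rw_to_ctv_inv_cubed"], 13.88)
  expect_equal(p1$r_squared, 0.88)
  p2 <- reg$pre_model2
  expect_equal(p2$intercept$estimate, 0.67)
  expect_equal(p2$terms$estimate, c(1.37, 0.009))
  # every term is a canonical feature column
  for (m in reg) expect_true(all(m$terms$term %in% cohort_columns()))
})

test_that("prediction evaluates the linear form and warns on extrapolation", {
  reg <- published_models()
  expect_equal(predict(reg$delta_model2, data.frame(norm_rinptv_pct = 3.4),
                       warn_extrapolation = FALSE), 0.73 + 1.10 * 3.4)
  expect_equal(predict(reg$delta_model2, data.frame(norm_rinptv_pct = 0),
                       warn_extrapolation = FALSE), 0.73)
  expect_equal(predict(reg$pre_model2,
                       data.frame(norm_rinptv_pct = 3.4, norm_ctv_pct = 62.3),
                       warn_extrapolation = FALSE),
               0.67 + 1.37 * 3.4 + 0.009 * 62.3)
  expect_error(predict(reg$pre_model2, data.frame(norm_rinptv_pct = 3.4)),
               "missing feature")
  w <- testthat::capture_warnings(
    predict(reg$delta_model2, data.frame(norm_rinptv_pct = 20)))
  expect_true(any(grepl("outside", w)))   # beyond the training range
  expect_true(any(grepl("above 10", w)))  # beyond the observed reductions
})

test_that("the two-stage flowchart screens pre-implant dose first", {
  # worked example: high pre-implant dose but insufficient predicted benefit
  d <- apply_flowchart(5.44, 3.21)
  expect_true(d$stage1_pass)
  expect_false(d$stage2_pass)
  expect_false(d$recommend_implant)
  # stage order: low pre-implant dose fails regardless of the benefit
  d2 <- apply_flowchart(2.9, 9.0)
  expect_false(d2$stage1_pass)
  expect_true(is.na(d2$stage2_pass))
  expect_false(d2$recommend_implant)
  # boundary convention: exactly at both cutoffs is retained
  d3 <- apply_flowchart(3.0, 3.5)
  expect_true(d3$recommend_implant)
  expect_equal(d3$margin_to_cutoffs, 0)
})

test_that("the flowchart verdict is monotone in both endpoints", {
  set.seed(21)
  for (k in 1:50) {
    pre <- runif(1, 0, 8); delta <- runif(1, 0, 8)
    v <- apply_flowchart(pre, delta)$recommend_implant
    v_up <- apply_flowchart(pre + runif(1, 0, 3),
                            delta + runif(1, 0, 3))$recommend_implant
    expect_true(v_up >= v)
  }
})

test_that("decide_implant predicts and screens a feature table", {
  f <- data.frame(patient_id = c("A", "B"),
                  norm_rinptv_pct = c(6, 0.5),
                  norm_ctv_pct = c(60, 40))
  d <- decide_implant(f, warn_extrapolation = FALSE)
  expect_equal(d$patient_id, c("A", "B"))
  expect_equal(d$predicted_delta_rv55, 0.73 + 1.10 * c(6, 0.5))
  expect_true(d$recommend_implant[1])
  expect_false(d$recommend_implant[2])
})

test_that("cohort retention counts are consistent", {
  f <- data.frame(norm_rinptv_pct = c(6, 0.5, 3, 10),
                  norm_ctv_pct = rep(60, 4))
  s <- cohort_decision_summary(f)
  expect_equal(s$n, 4)
  expect_equal(s$stage1_retained - s$final_retained, s$removed_stage2)
  expect_equal(s$n - s$stage1_retained, s$removed_stage1)
  expect_equal(s$fraction_retained, s$final_retained / 4)
  # vacuous cutoffs retain everyone
  s0 <- cohort_decision_summary(f, decision_config(omega1 = 0, omega2 = 0))
  expect_equal(s0$fraction_retained, 1)
})

test_that("nomogram scales are affine and invert the prediction exactly", {
  reg <- published_models()
  nm2 <- build_nomogram(reg$delta_model2)
  # single predictor: its span IS the 100-point scale
  expect_equal(nm2$max_span, 1.10 * (10.4 - 0.2))
  pts <- nomogram_points(nm2, data.frame(norm_rinptv_pct = c(0.2, 10.4)))
  expect_equal(pts$total_points, c(0, 100))
  set.seed(22)
  nm <- build_nomogram(reg$pre_model2)
  f <- data.frame(norm_rinptv_pct = runif(50, 0.2, 10.4),
                  norm_ctv_pct = runif(50, 19.6, 257.7))
  round_trip <- predict_from_points(nm, nomogram_points(nm, f)$total_points)
  direct <- predict(reg$pre_model2, f, warn_extrapolation = FALSE)
  expect_lt(max(abs(round_trip - direct) / pmax(abs(direct), 1)), 1e-3)
  # zero-coefficient predictors are dropped with a warning
  m <- reg$pre_model2
  m$terms$estimate[2] <- 0
  expect_warning(nm0 <- build_nomogram(m), "zero-coefficient")
  expect_equal(nrow(nm0$terms), 1L)
})

test_that("the nomogram renders without error", {
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error(plot(build_nomogram(published_models()$pre_model2)))
  grDevices::dev.off()
  unlink(f)
})
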