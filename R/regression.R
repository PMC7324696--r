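#' Pearson correlation with significance test
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `r` (correlation) and `p` (two-sided p-value from the
#'   t distribution with n - 2 degrees of freedom).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("'x' and 'y' must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant column")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Fit an ordinary least-squares linear model
#'
#' Thin wrapper around [stats::lm()] that returns the package's portable
#' linear-model object: named slope coefficients with standard errors,
#' intercept, R-squared, the overall-F p-value and the training sample size.
#' A constant response yields zero slopes, an intercept equal to the mean and
#' R-squared reported as 0 with a warning.
#'
#' @param data Cohort `data.frame` containing `dependent` and all `terms`.
#' @param dependent Name of the response column.
#' @param terms Character vector of predictor column names.
#' @return Object of class `rv_model`: list with `dependent`, `intercept`
#'   (`estimate`, `se`), `terms` (`data.frame(term, estimate, se, p)`),
#'   `r_squared`, `p_value`, `n`, `rss`.
#' @export
ols_fit <- function(data, dependent, terms) {
  miss <- setdiff(c(dependent, terms), names(data))
  if (length(miss) > 0L) stop("columns not in data: ", paste(miss, collapse = ", "))
  y <- data[[dependent]]
  n <- length(y)
  if (n <= length(terms) + 1L) stop("need n > number of terms + 1")
  if (stats::sd(y) == 0) {
    warning("constant response: R-squared undefined, reported as 0")
    return(structure(list(
      dependent = dependent,
      intercept = list(estimate = mean(y), se = 0),
      terms = data.frame(term = terms, estimate = rep(0, length(terms)),
                         se = NA_real_, p = NA_real_,
                         stringsAsFactors = FALSE),
      r_squared = 0, p_value = NA_real_, n = n, rss = 0), class = "rv_model"))
  }
  fml <- stats::reformulate(terms, response = dependent)
  fit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(fit)))) stop("singular design: rank-deficient predictor matrix")
  sm <- summary(fit)
  co <- sm$coefficients
  pf_val <- if (is.null(sm$fstatistic)) NA_real_ else {
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  }
  structure(list(
    dependent = dependent,
    intercept = list(estimate = unname(co["(Intercept)", 1]),
                     se = unname(co["(Intercept)", 2])),
    terms = data.frame(term = terms,
                       estimate = unname(co[terms, 1]),
                       se = unname(co[terms, 2]),
                       p = unname(co[terms, 4]),
                       stringsAsFactors = FALSE),
    r_squared = sm$r.squared,
    p_value = pf_val,
    n = n,
    rss = sum(stats::residuals(fit)^2)), class = "rv_model")
}

#' @export
print.rv_model <- function(x, ...) {
  cat(sprintf("<rv_model> %s ~ %s\n", x$dependent,
              if (nrow(x$terms) > 0) paste(x$terms$term, collapse = " + ")
              else "1"))
  cat(sprintf("  intercept %.4g (SE %.3g)\n", x$intercept$estimate,
              x$intercept$se))
  for (i in seq_len(nrow(x$terms))) {
    cat(sprintf("  %-22s %.4g (SE %.3g)\n", x$terms$term[i],
                x$terms$estimate[i], x$terms$se[i]))
  }
  if (!is.null(x$r_squared) && is.finite(x$r_squared)) {
    cat(sprintf("  R-squared %.3f, n = %d\n", x$r_squared, x$n))
  }
  invisible(x)
}

#' Gaussian-profile Akaike information criterion of a fitted model
#'
#' AIC under the Gaussian likelihood with the variance profiled out:
#' `n * log(RSS / n) + 2 * (k + 2)` where k is the number of slopes (the +2
#' counts the intercept and the error variance).  Any constant offset shared
#' across models of the same data cancels in comparisons, so rankings agree
#' with likelihood-based AIC.
#'
#' @param model An `rv_model` from [ols_fit()] (carries its training RSS).
#' @param y Optional training response, used only as a consistency check on
#'   the sample size.
#' @return AIC value; `-Inf` with a warning when RSS is 0.
#' @export
model_aic <- function(model, y = NULL) {
  if (!inherits(model, "rv_model")) stop("'model' must be an rv_model")
  n <- model$n
  if (!is.null(y) && length(y) != n) stop("'y' length does not match the fit")
  k <- nrow(model$terms)
  if (model$rss <= 0) {
    warning("zero residual sum of squares: AIC is -Inf")
    return(-Inf)
  }
  n * log(model$rss / n) + 2 * (k + 2)
}

#' Variance inflation factors
#'
#' VIF of each predictor column: `1 / (1 - R2_j)` from regressing column j on
#' the remaining columns (with intercept).  Exact collinearity yields `Inf`.
#'
#' @param X Numeric matrix or data.frame with >= 2 columns.
#' @return Named numeric vector of VIFs (each >= 1).
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 2L) stop("VIF needs at least 2 predictor columns")
  vapply(names(X), function(j) {
    fit <- stats::lm(stats::reformulate(setdiff(names(X), j), response = j),
                     data = X)
    # exact collinearity triggers a perfect-fit note in summary.lm; the Inf
    # sentinel below is the intended report for that case
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Stepwise model selection configuration
#'
#' @param vif_limit Multicollinearity cutoff; terms are pruned until every
#'   VIF is below this (default 5).
#' @param max_predictors Maximum number of retained predictors (default 3,
#'   guarding against overfitting small cohorts).
#' @param exclusive_groups List of predictor-name sets of which at most one
#'   member may enter a model (default: whole-rectum vs rectal-wall volume,
#'   which are near-duplicates by construction).
#' @param candidates Candidate predictor names (default: all canonical
#'   geometric features).
#' @param alpha Significance level used for flagging in reports (default
#'   0.01; not a selection criterion).
#' @return List of class `stepwise_config`.
#' @export
stepwise_config <- function(vif_limit = 5, max_predictors = 3,
                            exclusive_groups = list(c("rectum_vol_cc",
                                                      "rw_vol_cc")),
                            candidates = candidate_predictors("model1"),
                            alpha = 0.01) {
  if (vif_limit <= 1) stop("'vif_limit' must be > 1")
  if (max_predictors < 1) stop("'max_predictors' must be >= 1")
  structure(list(vif_limit = vif_limit, max_predictors = max_predictors,
                 exclusive_groups = exclusive_groups, candidates = candidates,
                 alpha = alpha), class = "stepwise_config")
}

#' Candidate predictor sets
#'
#' The two candidate pools used when refitting the published model families:
#' `"model1"` offers every geometric feature; `"model2"` is restricted to
#' volumes and their normalizations, i.e. quantities available directly in a
#' treatment planning system without external contour analysis (no
#' wall-to-CTV distance metrics).
#'
#' @param which `"model1"` or `"model2"`.
#' @return Character vector of predictor column names.
#' @export
candidate_predictors <- function(which = c("model1", "model2")) {
  which <- match.arg(which)
  vols <- c("rectum_vol_cc", "rw_vol_cc", "ctv_vol_cc", "norm_ctv_pct",
            "rinptv_cc", "norm_rinptv_pct")
  if (which == "model2") vols
  else c(vols, "rw_to_ctv_cm", "rw_to_ctv_inv_cubed")
}

#' Backward stepwise AIC selection with VIF pruning
#'
#' The model-building pipeline: (1) Pearson screening of all candidates
#' against the response; (2) within each exclusive group, only the member
#' with the larger absolute correlation enters; (3) backward elimination -
#' starting from the full model, repeatedly remove the single term whose
#' removal lowers the AIC the most, stopping when no removal lowers it
#' (ties broken toward the term with the larger p-value); (4) while any VIF
#' is at or above `vif_limit`, drop the highest-VIF term; (5) enforce
#' `max_predictors` by further AIC-ordered removal.
#'
#' @param data Cohort `data.frame`.
#' @param dependent Response column name.
#' @param cfg A [stepwise_config()].
#' @return List with `model` (the selected `rv_model`, including structure
#'   coefficients merged into its term table) and `report` (class
#'   `fit_report`): Pearson table, AIC trace, VIF table, structure
#'   coefficients and the significance level.
#' @export
stepwise_select <- function(data, dependent, cfg = stepwise_config()) {
  cand <- intersect(cfg$candidates, names(data))
  if (length(cand) == 0L) stop("no candidate predictors present in data")
  y <- data[[dependent]]

  pearson <- do.call(rbind, lapply(cand, function(v) {
    pc <- pearson_cor(data[[v]], y)
    data.frame(term = v, r = pc$r, p = pc$p,
               significant = pc$p < cfg$alpha, stringsAsFactors = FALSE)
  }))

  current <- cand
  for (grp in cfg$exclusive_groups) {
    g <- intersect(grp, current)
    if (length(g) > 1L) {
      keep <- g[which.max(abs(pearson$r[match(g, pearson$term)]))]
      current <- setdiff(current, setdiff(g, keep))
    }
  }
  if (length(y) <= length(current) + 1L) {
    stop("too few rows for the candidate set after group exclusion")
  }

  fit_aic <- function(terms) {
    m <- ols_fit(data, dependent, terms)
    list(model = m, aic = suppressWarnings(model_aic(m)))
  }
  cur <- fit_aic(current)
  trace <- data.frame(step = "start", removed = NA_character_,
                      aic = cur$aic, n_terms = length(current),
                      stringsAsFactors = FALSE)

  drop_best <- function(current, cur, why, force = FALSE) {
    # evaluate every single-term removal; apply the best if it lowers AIC
    # (or unconditionally when force = TRUE)
    cands <- lapply(current, function(tm) fit_aic(setdiff(current, tm)))
    aics <- vapply(cands, `[[`, numeric(1), "aic")
    best <- min(aics)
    ties <- which(aics <= best + 1e-9)
    if (length(ties) > 1L) {
      pv <- cur$model$terms$p[match(current[ties], cur$model$terms$term)]
      ties <- ties[which.max(pv)]
    }
    i <- ties[1]
    if (!force && aics[i] >= cur$aic - 1e-9) return(NULL)
    list(current = setdiff(current, current[i]), cur = cands[[i]],
         removed = current[i], why = why)
  }

  repeat {   # backward AIC
    if (length(current) <= 1L) break
    st <- drop_best(current, cur, "aic")
    if (is.null(st)) break
    current <- st$current; cur <- st$cur
    trace <- rbind(trace, data.frame(step = "aic", removed = st$removed,
                                     aic = cur$aic,
                                     n_terms = length(current)))
  }
  while (length(current) >= 2L) {   # VIF pruning
    v <- vif(data[current])
    if (all(v < cfg$vif_limit)) break
    worst <- names(v)[which.max(v)]
    current <- setdiff(current, worst)
    cur <- fit_aic(current)
    trace <- rbind(trace, data.frame(step = "vif", removed = worst,
                                     aic = cur$aic,
                                     n_terms = length(current)))
  }
  while (length(current) > cfg$max_predictors) {   # size cap
    st <- drop_best(current, cur, "max_predictors", force = TRUE)
    current <- st$current; cur <- st$cur
    trace <- rbind(trace, data.frame(step = "max_predictors",
                                     removed = st$removed, aic = cur$aic,
                                     n_terms = length(current)))
  }

  model <- cur$model
  sc <- structure_coefficients(model, data)
  model$terms$rs <- sc$rs[match(model$terms$term, sc$term)]
  model$terms$rs2 <- sc$rs2[match(model$terms$term, sc$term)]
  vt <- if (length(current) >= 2L) vif(data[current]) else
    stats::setNames(rep(1, length(current)), current)
  report <- structure(list(
    pearson_table = pearson,
    aic_trace = trace,
    vif_table = data.frame(term = names(vt), vif = unname(vt),
                           stringsAsFactors = FALSE),
    structure_coeffs = sc,
    alpha = cfg$alpha), class = "fit_report")
  list(model = model, report = report)
}

#' Structure coefficients of a fitted model
#'
#' The structure coefficient of a predictor is its Pearson correlation with
#' the response divided by the square root of the model R-squared,
#' `rs = r / sqrt(R2)`; its square apportions the model's explained variance
#' among the predictors.  For a single-predictor model `rs^2 = 1` identically.
#'
#' @param m An `rv_model` with `r_squared > 0`.
#' @param data The training cohort table.
#' @return `data.frame(term, r_pears, rs, rs2)`.
#' @seealso [structure_coefficient()] for the scalar identity.
#' @export
structure_coefficients <- function(m, data) {
  if (!inherits(m, "rv_model")) stop("'m' must be an rv_model")
  if (is.null(m$r_squared) || m$r_squared <= 0) {
    stop("structure coefficients undefined for R-squared = 0")
  }
  y <- data[[m$dependent]]
  do.call(rbind, lapply(m$terms$term, function(v) {
    r <- stats::cor(data[[v]], y)
    rs <- structure_coefficient(r, m$r_squared)
    data.frame(term = v, r_pears = r, rs = rs, rs2 = rs^2,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname structure_coefficients
#' @param r_pears Pearson correlation between a predictor and the response.
#' @param r_squared Model R-squared (> 0).
#' @export
structure_coefficient <- function(r_pears, r_squared) {
  if (any(r_squared <= 0)) stop("'r_squared' must be > 0")
  r_pears / sqrt(r_squared)
}

#' Leave-one-out cross-validation of a fixed term set
#'
#' LOOCV with the term set held fixed (no re-selection inside folds): each
#' row is predicted from a model fitted to the remaining rows.  The held-out
#' residuals are obtained through the hat-matrix identity
#' `e_i / (1 - h_ii)`, which equals explicit refitting for OLS.  Reports the
#' predicted R-squared `1 - PRESS / SST`, the mean absolute held-out error
#' (MAE, response units) and the relative MAE (% of the response range).
#'
#' @param data Cohort `data.frame`.
#' @param terms Predictor names (fixed during refits).
#' @param dependent Response column name.
#' @return List of class `loocv_result`: `predicted_r_squared`, `mae`,
#'   `pct_mae`, `press`, `loo_errors`.
#' @export
loocv <- function(data, terms, dependent) {
  y <- data[[dependent]]
  n <- length(y)
  if (n < length(terms) + 3L) stop("need n >= number of terms + 3")
  fml <- stats::reformulate(terms, response = dependent)
  fit <- stats::lm(fml, data = data)
  h <- stats::hatvalues(fit)
  bad <- which(1 - h < 1e-10)
  if (length(bad) > 0L) {
    stop("singular leave-one-out refit for row(s): ",
         paste(bad, collapse = ", "))
  }
  e <- stats::residuals(fit) / (1 - h)
  press <- sum(e^2)
  sst <- sum((y - mean(y))^2)
  mae <- mean(abs(e))
  structure(list(predicted_r_squared = 1 - press / sst,
                 mae = mae,
                 pct_mae = relative_mae(mae, y),
                 press = press,
                 loo_errors = unname(e)), class = "loocv_result")
}

#' Relative mean absolute error
#'
#' Normalizes a mean absolute error by the observed range of the response:
#' `100 * mae / (max(y) - min(y))`.
#'
#' @param mae Mean absolute error (response units).
#' @param y Response vector, or a length-2 range.
#' @return %MAE.
#' @export
relative_mae <- function(mae, y) {
  rng <- diff(range(y))
  if (rng <= 0) stop("response range must be positive")
  100 * mae / rng
}
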