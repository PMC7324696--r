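.registry_env <- new.env(parent = emptyenv())

.load_registry <- function() {
  if (!is.null(.registry_env$reg)) return(.registry_env$reg)
  path <- system.file("extdata", "published_models.json",
                      package = "spacerdose")
  if (path == "") stop("published model registry not found")
  .registry_env$reg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  .registry_env$reg
}

#' Published predictive models for hydrogel spacer decision support
#'
#' Returns the registry of the four frozen linear models predicting the
#' pre-implant rectal V55Gy (`pre_model1`, `pre_model2`) and its pre-to-post
#' implant change (`delta_model1`, `delta_model2`), in % of rectal volume.
#' Model 1 variants use the full geometric feature set (including the
#' rectal-wall-to-CTV distance metrics); Model 2 variants use only volume
#' metrics available directly in a treatment planning system and are the
#' recommended default.  Coefficients, standard errors, squared structure
#' coefficients and validation statistics are shipped verbatim from the
#' versioned JSON resource bundled with the package.
#'
#' @return Named list of `rv_model` objects with additional fields
#'   `predicted_r_squared`, `mae`, `pct_mae`, `p_label`, `training_ranges`.
#' @seealso [published_correlations()], [published_cohort_summary()]
#' @export
published_models <- function() {
  reg <- .load_registry()
  rng <- published_cohort_summary()
  lapply(reg$models, function(m) {
    tr <- lapply(m$terms$term, function(v) {
      r <- rng[rng$metric == v, ]
      if (nrow(r) == 1L) c(min = r$min, max = r$max) else c(min = NA, max = NA)
    })
    names(tr) <- m$terms$term
    structure(list(
      dependent = m$dependent,
      intercept = list(estimate = m$intercept$estimate, se = m$intercept$se),
      terms = m$terms,
      r_squared = m$r_squared,
      p_value = NA_real_,
      p_label = m$p_label,
      n = m$n,
      rss = NA_real_,
      predicted_r_squared = m$predicted_r_squared,
      mae = m$mae,
      pct_mae = m$pct_mae,
      notes = m$notes %||% NULL,
      training_ranges = tr), class = "rv_model")
  })
}

#' @rdname published_models
#' @export
published_correlations <- function() {
  reg <- .load_registry()
  cr <- reg$correlations
  out <- data.frame(term = names(cr$delta_rv55_pct),
                    delta_rv55_pct = unlist(cr$delta_rv55_pct),
                    pre_rv55_pct = unlist(cr$pre_rv55_pct),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname published_models
#' @export
published_cohort_summary <- function() {
  reg <- .load_registry()
  cs <- reg$cohort_summary
  out <- do.call(rbind, lapply(names(cs), function(v) {
    data.frame(metric = v, mean = cs[[v]]$mean, sd = cs[[v]]$sd,
               min = cs[[v]]$min, max = cs[[v]]$max, stringsAsFactors = FALSE)
  }))
  out
}

#' Predict a rectal dose endpoint from a feature vector
#'
#' Evaluates the linear model `intercept + sum(beta_i * x_i)` on one or more
#' feature rows.  Feature values outside the model's training ranges raise an
#' extrapolation warning, as does a predicted dose-reduction above 10 %
#' (beyond the largest reduction seen in model development, where the error
#' is uncharacterized).
#'
#' @param object An `rv_model` (fitted or from [published_models()]).
#' @param newdata `data.frame` containing every model term as a column.
#' @param warn_extrapolation Emit range warnings (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of predictions (% of rectal volume).
#' @examples
#' m <- published_models()$delta_model2
#' predict(m, data.frame(norm_rinptv_pct = 3.4))  # 0.73 + 1.10 * 3.4
#' @export
predict.rv_model <- function(object, newdata, warn_extrapolation = TRUE, ...) {
  miss <- setdiff(object$terms$term, names(newdata))
  if (length(miss) > 0L) {
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  }
  pred <- rep(object$intercept$estimate, nrow(newdata))
  for (i in seq_len(nrow(object$terms))) {
    pred <- pred + object$terms$estimate[i] * newdata[[object$terms$term[i]]]
  }
  if (warn_extrapolation) {
    if (!is.null(object$training_ranges)) {
      for (v in names(object$training_ranges)) {
        r <- object$training_ranges[[v]]
        x <- newdata[[v]]
        if (!any(is.na(r)) && any(x < r["min"] | x > r["max"])) {
          warning(sprintf("'%s' outside the model training range [%g, %g]: extrapolating",
                          v, r["min"], r["max"]))
        }
      }
    }
    if (grepl("delta", object$dependent) && any(pred > 10)) {
      warning("predicted dose reduction above 10 %: beyond the observed ",
              "training range, the associated error may be large")
    }
    if (!is.null(object$notes)) warning(object$notes)
  }
  unname(pred)
}

#' Decision cutoffs for spacer patient selection
#'
#' @param omega1 Lower limit (%) on the predicted pre-implant rectal V55Gy;
#'   patients below it are unlikely to develop bowel toxicity even without a
#'   spacer (default 3.0).
#' @param omega2 Lower limit (%) on the predicted change in rectal V55Gy;
#'   patients below it gain too little from the implant (default 3.5).
#' @param model_choice 1 or 2, selecting the published model family used for
#'   both predictions (default 2, the planning-system-only models).
#' @return List of class `decision_config`.
#' @export
decision_config <- function(omega1 = 3.0, omega2 = 3.5, model_choice = 2L) {
  if (omega1 < 0 || omega2 < 0) stop("cutoffs must be >= 0")
  if (!model_choice %in% c(1L, 2L)) stop("'model_choice' must be 1 or 2")
  structure(list(omega1 = omega1, omega2 = omega2,
                 model_choice = as.integer(model_choice)),
            class = "decision_config")
}

#' Two-stage patient-selection flowchart
#'
#' Applies the selection flowchart to (predicted or measured) rectal dose
#' endpoints: stage 1 retains patients whose pre-implant V55Gy reaches the
#' `omega1` cutoff (others would gain little because their rectal dose is
#' already low); stage 2, evaluated only for stage-1 survivors, retains
#' patients whose predicted V55Gy reduction reaches `omega2`.  Values exactly
#' at a cutoff are retained.  A spacer implant is recommended when both
#' stages pass.
#'
#' @param pre_rv55 Pre-implant rectal V55Gy values (%).
#' @param delta_rv55 Change in rectal V55Gy values (%).
#' @param config A [decision_config()].
#' @return `data.frame` with columns `predicted_pre_rv55`,
#'   `predicted_delta_rv55`, `stage1_pass`, `stage2_pass` (`NA` when stage 1
#'   fails, since the flowchart never evaluates it), `recommend_implant`,
#'   `margin_to_cutoffs` (the smaller of the two distances above the
#'   cutoffs, %).
#' @examples
#' apply_flowchart(5.44, 3.21)  # stage 1 passes, stage 2 fails
#' @export
apply_flowchart <- function(pre_rv55, delta_rv55, config = decision_config()) {
  stopifnot(length(pre_rv55) == length(delta_rv55))
  stage1 <- pre_rv55 >= config$omega1
  stage2 <- ifelse(stage1, delta_rv55 >= config$omega2, NA)
  data.frame(
    predicted_pre_rv55 = pre_rv55,
    predicted_delta_rv55 = delta_rv55,
    stage1_pass = stage1,
    stage2_pass = stage2,
    recommend_implant = stage1 & !is.na(stage2) & stage2,
    margin_to_cutoffs = pmin(pre_rv55 - config$omega1,
                             delta_rv55 - config$omega2)
  )
}

#' Decide spacer implantation for new patients
#'
#' Predicts both rectal dose endpoints from the geometric features with the
#' chosen published model family and runs the two-stage flowchart.
#'
#' @param features `data.frame` of feature rows (see [extract_features()]).
#' @param config A [decision_config()].
#' @param registry Model registry (default [published_models()]).
#' @param warn_extrapolation Passed to [predict.rv_model()].
#' @return The [apply_flowchart()] data frame, with `patient_id` prepended
#'   when present in `features`.
#' @export
decide_implant <- function(features, config = decision_config(),
                           registry = published_models(),
                           warn_extrapolation = TRUE) {
  pre_m <- registry[[paste0("pre_model", config$model_choice)]]
  delta_m <- registry[[paste0("delta_model", config$model_choice)]]
  pre <- predict(pre_m, features, warn_extrapolation = warn_extrapolation)
  delta <- predict(delta_m, features, warn_extrapolation = warn_extrapolation)
  out <- apply_flowchart(pre, delta, config)
  if ("patient_id" %in% names(features)) {
    out <- cbind(patient_id = features$patient_id, out)
  }
  out
}

#' Cohort-level retention summary of the selection flowchart
#'
#' @param t Cohort feature table (non-empty).
#' @param config A [decision_config()].
#' @param registry Model registry.
#' @return List with `n`, `stage1_retained`, `final_retained`,
#'   `removed_stage1`, `removed_stage2` and `fraction_retained`.
#' @export
cohort_decision_summary <- function(t, config = decision_config(),
                                    registry = published_models()) {
  if (nrow(t) == 0L) stop("cohort table is empty")
  d <- decide_implant(t, config, registry, warn_extrapolation = FALSE)
  s1 <- sum(d$stage1_pass)
  fin <- sum(d$recommend_implant)
  list(n = nrow(t),
       stage1_retained = s1,
       final_retained = fin,
       removed_stage1 = nrow(t) - s1,
       removed_stage2 = s1 - fin,
       fraction_retained = fin / nrow(t))
}

#' Build a nomogram from a linear model
#'
#' Converts a fitted or published linear model into the conventional
#' points-scale nomogram: each predictor's contribution over its stated range
#' is mapped affinely onto a 0-100 point axis scaled so that 100 points equal
#' the largest single-term contribution span, and the summed points map
#' affinely back to the predicted endpoint.  The mapping is exact (affine),
#' so reading a prediction off the nomogram reproduces [predict.rv_model()]
#' up to rounding of the drawn axes.
#'
#' @param model An `rv_model`.
#' @param ranges Named list of `c(min, max)` per predictor; defaults to the
#'   model's training ranges.
#' @return Object of class `nomogram_spec`: term table (`term`, `beta`,
#'   `min`, `max`, `ref`, `points_per_unit`), `max_span`, `base` (prediction
#'   at all reference values) and the model dependent.
#' @export
build_nomogram <- function(model, ranges = NULL) {
  if (is.null(ranges)) {
    ranges <- model$training_ranges
    if (is.null(ranges)) stop("no predictor ranges available; supply 'ranges'")
  }
  terms <- model$terms
  keep <- terms$estimate != 0
  if (any(!keep)) {
    warning("zero-coefficient predictor(s) excluded from the nomogram: ",
            paste(terms$term[!keep], collapse = ", "))
    terms <- terms[keep, , drop = FALSE]
  }
  tab <- do.call(rbind, lapply(seq_len(nrow(terms)), function(i) {
    v <- terms$term[i]
    r <- ranges[[v]]
    if (is.null(r) || any(is.na(r)) || r[1] >= r[2]) {
      stop("need a finite min < max range for predictor ", v)
    }
    b <- terms$estimate[i]
    data.frame(term = v, beta = b, min = r[1], max = r[2],
               ref = if (b > 0) r[1] else r[2],
               span = abs(b) * (r[2] - r[1]), stringsAsFactors = FALSE)
  }))
  max_span <- max(tab$span)
  tab$points_per_unit <- 100 * tab$beta / max_span
  base <- model$intercept$estimate + sum(tab$beta * tab$ref)
  structure(list(dependent = model$dependent, terms = tab,
                 max_span = max_span, base = base,
                 intercept = model$intercept$estimate),
            class = "nomogram_spec")
}

#' Evaluate and invert a nomogram
#'
#' `nomogram_points()` converts feature values to per-term and total points;
#' `predict_from_points()` converts total points back to the predicted
#' endpoint.
#'
#' @param spec A `nomogram_spec` from [build_nomogram()].
#' @param features `data.frame` with the nomogram's predictors.
#' @param total_points Total points (numeric vector).
#' @return `nomogram_points()`: `data.frame` of per-term points plus
#'   `total_points`; `predict_from_points()`: predicted endpoint (%).
#' @export
nomogram_points <- function(spec, features) {
  pts <- sapply(seq_len(nrow(spec$terms)), function(i) {
    v <- spec$terms$term[i]
    spec$terms$points_per_unit[i] * (features[[v]] - spec$terms$ref[i])
  })
  pts <- matrix(pts, nrow = nrow(features))
  colnames(pts) <- spec$terms$term
  out <- as.data.frame(pts)
  out$total_points <- rowSums(pts)
  out
}

#' @rdname nomogram_points
#' @export
predict_from_points <- function(spec, total_points) {
  spec$base + total_points * spec$max_span / 100
}

#' @export
print.nomogram_spec <- function(x, ...) {
  cat(sprintf("<nomogram> %s: %d predictor scale(s), 100 points = %.3g %%\n",
              x$dependent, nrow(x$terms), x$max_span))
  for (i in seq_len(nrow(x$terms))) {
    cat(sprintf("  %-22s [%g, %g] -> [%.1f, %.1f] points\n",
                x$terms$term[i], x$terms$min[i], x$terms$max[i],
                x$terms$points_per_unit[i] * (x$terms$min[i] - x$terms$ref[i]),
                x$terms$points_per_unit[i] * (x$terms$max[i] - x$terms$ref[i])))
  }
  invisible(x)
}

#' Draw a nomogram
#'
#' Simple base-graphics rendering of a [build_nomogram()] specification:
#' one points axis, one axis per predictor and the total-points-to-prediction
#' axis.
#'
#' @param x A `nomogram_spec`.
#' @param n_ticks Approximate tick count per axis.
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.nomogram_spec <- function(x, n_ticks = 6, ...) {
  k <- nrow(x$terms)
  rows <- k + 2L
  graphics::plot.new()
  graphics::plot.window(xlim = c(-0.28, 1.05), ylim = c(0.5, rows + 0.5))
  draw_axis <- function(row, at, labels, title) {
    graphics::segments(min(at), row, max(at), row)
    graphics::segments(at, row - 0.06, at, row + 0.06)
    graphics::text(at, row + 0.18, labels, cex = 0.7)
    graphics::text(-0.26, row, title, adj = 0, cex = 0.8)
  }
  pts_at <- pretty(c(0, 100), n_ticks)
  draw_axis(rows, pts_at / 100, pts_at, "Points")
  for (i in seq_len(k)) {
    vals <- pretty(c(x$terms$min[i], x$terms$max[i]), n_ticks)
    vals <- vals[vals >= x$terms$min[i] & vals <= x$terms$max[i]]
    at <- x$terms$points_per_unit[i] * (vals - x$terms$ref[i]) / 100
    draw_axis(rows - i, at, vals, x$terms$term[i])
  }
  tp_max <- 100 * k
  tp_at <- pretty(c(0, tp_max), n_ticks)
  preds <- predict_from_points(x, tp_at)
  draw_axis(1, tp_at / tp_max, sprintf("%.1f", preds),
            paste0(x$dependent, " (total points)"))
  graphics::title(main = paste("Nomogram:", x$dependent))
  invisible(x)
}
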