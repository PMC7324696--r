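#' Extract the per-patient geometric feature vector
#'
#' Assembles the independent predictors used by the rectal dose-reduction
#' models from a pre-implant structure set: absolute volumes of the rectum,
#' rectal wall and CTV; the rectum-in-PTV overlap; the CTV and overlap
#' volumes normalized by the whole-rectum volume (in %); and the mean
#' slice-wise Hausdorff distance between the height-limited rectal wall and
#' the CTV (in cm) together with its cube and inverse cube.
#'
#' Derived structures that are absent from `structs` are built on demand:
#' the PTV by [expand_margin()], the rectal wall by [make_wall()] and the
#' height-limited wall by [height_limit()].
#'
#' @param structs Named list of [contour_stack()]s.  `rectum` and `ctv` are
#'   required; `ptv`, `rw` and `rw17` are used when present.
#' @param cfg A [structure_recipe()].
#' @param margins A [margin_spec()] for the CTV-to-PTV expansion.
#' @param patient_id Identifier stored in the output row.
#' @return A one-row `data.frame` with the canonical feature columns
#'   `patient_id`, `rectum_vol_cc`, `rw_vol_cc`, `ctv_vol_cc`,
#'   `norm_ctv_pct`, `rinptv_cc`, `norm_rinptv_pct`, `rw_to_ctv_cm`,
#'   `rw_to_ctv_cubed_cc`, `rw_to_ctv_inv_cubed`.
#' @export
extract_features <- function(structs, cfg = structure_recipe(),
                             margins = margin_spec(), patient_id = "P1") {
  need <- setdiff(c("rectum", "ctv"), names(structs))
  if (length(need) > 0L) {
    stop("missing required structure(s): ", paste(need, collapse = ", "))
  }
  rectum <- structs$rectum
  ctv <- structs$ctv
  ptv <- structs$ptv %||% expand_margin(ctv, margins, cfg)
  rw <- structs$rw %||% make_wall(rectum, cfg)
  rw17 <- structs$rw17 %||% height_limit(rw, ptv, cfg)

  rectum_vol <- structure_volume(rectum)
  rinptv <- overlap_volume(ptv, rectum)
  d <- mean_slice_hausdorff(rw17, ctv)
  data.frame(
    patient_id = patient_id,
    rectum_vol_cc = rectum_vol,
    rw_vol_cc = structure_volume(rw),
    ctv_vol_cc = structure_volume(ctv),
    norm_ctv_pct = 100 * structure_volume(ctv) / rectum_vol,
    rinptv_cc = rinptv,
    norm_rinptv_pct = 100 * rinptv / rectum_vol,
    rw_to_ctv_cm = d,
    rw_to_ctv_cubed_cc = d^3,
    rw_to_ctv_inv_cubed = d^-3,
    stringsAsFactors = FALSE
  )
}

#' Canonical cohort-table column names
#'
#' @return Character vector of the feature and endpoint column names used in
#'   cohort CSV files.
#' @export
cohort_columns <- function() {
  c("patient_id", "rectum_vol_cc", "rw_vol_cc", "ctv_vol_cc", "norm_ctv_pct",
    "rinptv_cc", "norm_rinptv_pct", "rw_to_ctv_cm", "rw_to_ctv_cubed_cc",
    "rw_to_ctv_inv_cubed", "delta_rv55_pct", "pre_rv55_pct")
}

#' Summarize a cohort table column-wise
#'
#' Per-column mean, sample standard deviation (n - 1 denominator), minimum
#' and maximum for every numeric column, the summary layout used to report
#' cohort marginals.
#'
#' @param t Cohort `data.frame` with at least 2 rows.
#' @return `data.frame(metric, mean, sd, min, max)`.
#' @export
summarize_cohort <- function(t) {
  if (!is.data.frame(t) || nrow(t) < 2L) {
    stop("cohort summary needs a data.frame with >= 2 rows")
  }
  num <- names(t)[vapply(t, is.numeric, logical(1))]
  do.call(rbind, lapply(num, function(cn) {
    x <- t[[cn]]
    data.frame(metric = cn, mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }))
}
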