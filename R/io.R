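# Readers/writers for the package's plain-text interchange formats:
# structure JSON, dose JSON, cohort CSV, model JSON and the YAML run config.

#' Read and write contour stacks as JSON
#'
#' The structure interchange format is
#' `{"name", "slice_spacing_mm", "slices": [{"z_mm", "polygons":
#' [[[x, y], ...], ...]}, ...]}` with coordinates in mm.  Polygons are
#' written with explicit closure (the first vertex repeated at the end);
#' closure is normalized away on read.
#'
#' @param path File path.
#' @param s A [contour_stack()].
#' @return `read_structure_json()` returns a [contour_stack()];
#'   `write_structure_json()` returns `path` invisibly.
#' @export
read_structure_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$name) || is.null(j$slice_spacing_mm) || is.null(j$slices)) {
    stop("not a structure JSON file: ", path)
  }
  slices <- lapply(j$slices, function(sl) {
    polys <- lapply(sl$polygons, function(pg) {
      do.call(rbind, lapply(pg, function(v) c(v[[1]], v[[2]])))
    })
    list(z = sl$z_mm, polys = polys)
  })
  contour_stack(j$name, slices, j$slice_spacing_mm)
}

#' @rdname read_structure_json
#' @export
write_structure_json <- function(s, path) {
  if (!is_contour_stack(s)) stop("'s' must be a contour_stack")
  obj <- list(
    name = s$name,
    slice_spacing_mm = s$slice_spacing,
    slices = lapply(s$slices, function(sl) {
      list(z_mm = sl$z,
           polygons = lapply(sl$polys, function(p) {
             closed <- rbind(p, p[1, ])
             lapply(seq_len(nrow(closed)), function(i) closed[i, ])
           }))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read and write dose grids as JSON
#'
#' Format: `{"origin_mm", "spacing_mm", "dims", "values_gy"}` with
#' `values_gy` flattened in column-major order (x fastest, then y, then z).
#'
#' @param path File path.
#' @param d A [dose_grid()].
#' @return `read_dose_json()` returns a [dose_grid()].
#' @export
read_dose_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(j$origin_mm) || is.null(j$spacing_mm) || is.null(j$dims) ||
      is.null(j$values_gy)) {
    stop("not a dose JSON file: ", path)
  }
  dose_grid(j$origin_mm, j$spacing_mm, array(j$values_gy, dim = j$dims))
}

#' @rdname read_dose_json
#' @export
write_dose_json <- function(d, path) {
  if (!inherits(d, "dose_grid")) stop("'d' must be a dose_grid")
  obj <- list(origin_mm = d$origin, spacing_mm = d$spacing, dims = d$dims,
              values_gy = as.vector(d$values))
  # 17 significant digits give a bit-exact double round trip
  jsonlite::write_json(obj, path, digits = I(17))
  invisible(path)
}

#' Read and write cohort tables as CSV
#'
#' Cohort files use the canonical headers of [cohort_columns()]; extra
#' columns are preserved, and the endpoint columns are optional (they are
#' absent until measured or simulated).
#'
#' @param path File path.
#' @param t Cohort `data.frame`.
#' @return `read_cohort_csv()` returns a `data.frame`.
#' @export
read_cohort_csv <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(t)) stop("cohort CSV must have 'patient_id'")
  if (anyDuplicated(t$patient_id)) stop("duplicate patient_id values")
  t
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(t, path) {
  utils::write.csv(t, path, row.names = FALSE)
  invisible(path)
}

#' Serialize fitted models to JSON
#'
#' @param m An `rv_model`.
#' @param path File path.
#' @param provenance Optional provenance string stored alongside the model.
#' @return `read_model_json()` returns an `rv_model`.
#' @export
write_model_json <- function(m, path, provenance = NULL) {
  if (!inherits(m, "rv_model")) stop("'m' must be an rv_model")
  obj <- list(dependent = m$dependent,
              intercept = m$intercept,
              terms = m$terms,
              r_squared = m$r_squared,
              p_value = m$p_value,
              n = m$n,
              provenance = provenance %||%
                paste0("spacerdose ", as.character(utils::packageVersion("spacerdose"))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(j$dependent) || is.null(j$terms)) {
    stop("not a model JSON file: ", path)
  }
  structure(list(dependent = j$dependent,
                 intercept = j$intercept,
                 terms = as.data.frame(j$terms),
                 r_squared = j$r_squared,
                 p_value = j$p_value %||% NA_real_,
                 n = j$n,
                 rss = NA_real_), class = "rv_model")
}

#' Read a pipeline run configuration
#'
#' Run configurations are YAML files with the blocks `paths` (structures,
#' dose, output), `structure_map` (clinical contour label to canonical role:
#' `ctv`, `rectum`, optionally `ptv`, `rw`, `rw17`, `bladder`), `recipe`,
#' `margins`, `stepwise`, `decision`, `simulate`, plus `seed` and
#' `log_level`.  Unknown top-level keys are rejected.  The canonical roles
#' `ctv` and `rectum` must be mapped for commands that read structures.
#'
#' @param path YAML file path.
#' @return Named configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("paths", "structure_map", "recipe", "margins", "stepwise",
             "decision", "simulate", "seed", "log_level", "model",
             "dependent")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

# small stable polynomial hash of the canonical JSON of a config,
# used only to fingerprint runs in the provenance log
.config_hash <- function(cfg) {
  s <- as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 10,
                                     force = TRUE))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
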