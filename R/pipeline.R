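#' Run a pipeline command
#'
#' Dispatches the end-to-end commands behind the command-line interface.
#' Every run writes its artifacts under the configured output directory plus
#' a provenance log (`run_log.json`: command, inputs, config hash, package
#' version, seed).  Outputs are deterministic for fixed inputs and seed.
#'
#' Commands:
#' \describe{
#'   \item{simulate}{Generate a cohort table ([simulate_cohort()]) and write
#'     `cohort.csv`.}
#'   \item{extract}{Read structure JSON files, map clinical labels to
#'     canonical roles and write a one-row `features.csv`
#'     ([extract_features()]).}
#'   \item{fit}{Run [stepwise_select()] on a cohort CSV and write
#'     `model_<dependent>.json` plus `fit_report_<dependent>.json`.}
#'   \item{validate}{LOOCV of a fitted model on a cohort CSV
#'     ([loocv()]), written to `loocv_<dependent>.json`.}
#'   \item{predict}{Predict endpoints for a feature CSV with a model JSON or
#'     a published model; writes `predictions.csv`.}
#'   \item{decide}{Run the selection flowchart over a feature CSV; writes
#'     `decisions.csv`.}
#'   \item{nomogram}{Write the machine-readable nomogram scale
#'     `nomogram_<dependent>.json` of a published or fitted model.}
#' }
#'
#' @param config A `run_config` (from [read_run_config()]) or an equivalent
#'   named list.
#' @param command One of `simulate`, `extract`, `fit`, `validate`,
#'   `predict`, `decide`, `nomogram`.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "extract", "fit", "validate",
                                     "predict", "decide", "nomogram")) {
  command <- match.arg(command)
  out_dir <- config$paths$output %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  artifacts <- list()
  recipe <- do.call(structure_recipe, config$recipe %||% list())
  margins <- do.call(margin_spec, config$margins %||% list())

  if (command == "simulate") {
    sim <- config$simulate %||% list()
    cc <- cohort_sim_config(n = sim$n %||% 21L, mode = sim$mode %||% "model",
                            seed = seed)
    coh <- simulate_cohort(cc)
    artifacts$cohort <- file.path(out_dir, "cohort.csv")
    write_cohort_csv(coh, artifacts$cohort)
  } else if (command == "extract") {
    smap <- config$structure_map
    if (is.null(smap$ctv) || is.null(smap$rectum)) {
      stop("config error: structure_map must map 'ctv' and 'rectum'")
    }
    sdir <- config$paths$structures %||%
      stop("config error: paths$structures is required for 'extract'")
    structs <- lapply(smap, function(f) read_structure_json(file.path(sdir, f)))
    feats <- extract_features(structs, recipe, margins,
                              patient_id = config$paths$patient_id %||% "P1")
    artifacts$features <- file.path(out_dir, "features.csv")
    write_cohort_csv(feats, artifacts$features)
  } else if (command == "fit") {
    coh <- read_cohort_csv(.required_path(config, "cohort"))
    dependent <- config$dependent %||% "delta_rv55_pct"
    scfg <- do.call(stepwise_config, config$stepwise %||% list())
    sel <- stepwise_select(coh, dependent, scfg)
    artifacts$model <- file.path(out_dir, paste0("model_", dependent, ".json"))
    write_model_json(sel$model, artifacts$model)
    artifacts$report <- file.path(out_dir,
                                  paste0("fit_report_", dependent, ".json"))
    jsonlite::write_json(sel$report, artifacts$report, auto_unbox = TRUE,
                         digits = NA, na = "null", force = TRUE)
  } else if (command == "validate") {
    coh <- read_cohort_csv(.required_path(config, "cohort"))
    m <- .resolve_model(config)
    lv <- loocv(coh, m$terms$term, m$dependent)
    artifacts$loocv <- file.path(out_dir,
                                 paste0("loocv_", m$dependent, ".json"))
    jsonlite::write_json(lv[c("predicted_r_squared", "mae", "pct_mae",
                              "press")],
                         artifacts$loocv, auto_unbox = TRUE, digits = NA)
  } else if (command == "predict") {
    feats <- read_cohort_csv(.required_path(config, "features"))
    m <- .resolve_model(config)
    feats$prediction <- predict(m, feats, warn_extrapolation = FALSE)
    feats$model_dependent <- m$dependent
    artifacts$predictions <- file.path(out_dir, "predictions.csv")
    write_cohort_csv(feats, artifacts$predictions)
  } else if (command == "decide") {
    feats <- read_cohort_csv(.required_path(config, "features"))
    dcfg <- do.call(decision_config, config$decision %||% list())
    d <- decide_implant(feats, dcfg, warn_extrapolation = FALSE)
    artifacts$decisions <- file.path(out_dir, "decisions.csv")
    write_cohort_csv(d, artifacts$decisions)
  } else if (command == "nomogram") {
    m <- .resolve_model(config)
    spec <- build_nomogram(m)
    artifacts$nomogram <- file.path(out_dir,
                                    paste0("nomogram_", m$dependent, ".json"))
    jsonlite::write_json(list(dependent = spec$dependent, terms = spec$terms,
                              max_span = spec$max_span, base = spec$base,
                              intercept = spec$intercept),
                         artifacts$nomogram, auto_unbox = TRUE, digits = NA)
  }

  log <- list(command = command,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed,
              config_hash = .config_hash(config[setdiff(names(config),
                                                        "paths")]),
              inputs = config$paths,
              package_version =
                as.character(utils::packageVersion("spacerdose")),
              artifacts = artifacts)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, na = "null", force = TRUE)
  invisible(artifacts)
}

.required_path <- function(config, key) {
  p <- config$paths[[key]]
  if (is.null(p)) stop("config error: paths$", key, " is required")
  p
}

# model source: a published model name or a fitted-model JSON path
.resolve_model <- function(config) {
  m <- config$model %||% "delta_model2"
  if (file.exists(m)) return(read_model_json(m))
  reg <- published_models()
  if (m %in% names(reg)) return(reg[[m]])
  stop("config error: 'model' must be a model JSON path or one of: ",
       paste(names(reg), collapse = ", "))
}
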