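# Orchestration: run the full analysis (generate -> filter -> extract ->
# select -> classify -> explain) from one configuration, with reproducible
# artifacts and a provenance manifest.

#' Assemble a pipeline run configuration
#'
#' @param cohort a [cohort_spec()].
#' @param features a [feature_config()].
#' @param criteria criteria to run (`"I"`, `"II"`).
#' @param selections selection methods for the grid.
#' @param classifiers classifier names for the grid.
#' @param pop,epochs,filter_k selection settings.
#' @param shap_nperm permutations for the explanation stage.
#' @param seed master seed recorded in every output.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       features = feature_config(),
                       criteria = c("I", "II"),
                       selections = c("none", "SMA"),
                       classifiers = c("balanced_bagging", "complement_nb",
                                       "easy_ensemble"),
                       pop = 100, epochs = 100, filter_k = 31,
                       shap_nperm = 32, seed = 1L) {
  structure(list(cohort = cohort, features = features, criteria = criteria,
                 selections = selections, classifiers = classifiers,
                 pop = pop, epochs = epochs, filter_k = filter_k,
                 shap_nperm = shap_nperm, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown fields are rejected; missing fields fall back to the defaults of
#' [run_config()], [cohort_spec()] and [feature_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("cohort", "features", "criteria", "selections", "classifiers",
             "pop", "epochs", "filter_k", "shap_nperm", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("unknown config fields: %s", paste(bad, collapse = ", "))
  co <- raw$cohort %||% list()
  if (!is.null(co$condition_gain)) {
    co$condition_gain <- stats::setNames(as.numeric(unlist(co$condition_gain)),
                                         stance_conditions)
  }
  fe <- raw$features %||% list()
  if (!is.null(fe$filter)) fe$filter <- do.call(filter_config, fe$filter)
  run_config(
    cohort = do.call(cohort_spec, co),
    features = do.call(feature_config, fe),
    criteria = raw$criteria %||% c("I", "II"),
    selections = raw$selections %||% c("none", "SMA"),
    classifiers = raw$classifiers %||% c("balanced_bagging", "complement_nb",
                                         "easy_ensemble"),
    pop = raw$pop %||% 100, epochs = raw$epochs %||% 100,
    filter_k = raw$filter_k %||% 31, shap_nperm = raw$shap_nperm %||% 32,
    seed = raw$seed %||% 1L)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, out_dir, artifacts) {
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("swayrisk")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    artifacts = artifacts
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Generate stage: cohort CSVs
#'
#' @param config a `run_config`.
#' @param out_dir output directory.
#' @return invisibly, the written paths.
#' @export
pipeline_generate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config$cohort)
  paths <- write_cohort_csv(cohort, out_dir)
  write_manifest(config, out_dir, as.list(paths))
  invisible(paths)
}

#' Feature stage: feature-table CSV and exclusion log
#'
#' Reads the cohort CSVs from `out_dir` (producing them first if absent),
#' extracts features and writes `features.csv` (+ JSON sidecar with the
#' exclusion log).
#'
#' @param config a `run_config`.
#' @param out_dir directory holding (or receiving) the cohort CSVs.
#' @return invisibly, the feature table path.
#' @export
pipeline_features <- function(config, out_dir) {
  pfile <- file.path(out_dir, "participants.csv")
  tfile <- file.path(out_dir, "trajectories.csv")
  if (!file.exists(pfile) || !file.exists(tfile)) {
    pipeline_generate(config, out_dir)
  }
  participants <- read_participants_csv(pfile)
  trials <- read_trajectories_csv(tfile, fs = config$cohort$sampling_rate)
  ft <- build_feature_table(participants, trials, config$features)
  fpath <- file.path(out_dir, "features.csv")
  write_feature_table(ft, fpath)
  invisible(fpath)
}

#' Full pipeline run
#'
#' Generate (if needed) -> features (if needed) -> grid of selections x
#' classifiers per criterion -> Shapley explanation of the best pipeline
#' (highest test AUC) per criterion. Writes `metrics.csv` (+ ROC JSON),
#' `shap_criteria_<crit>.csv` and `manifest.json`; everything is
#' reproducible byte-for-byte under a fixed master seed.
#'
#' @param config a `run_config`.
#' @param out_dir output directory.
#' @return invisibly, a list with the grid report and the explanation
#'   summaries.
#' @export
pipeline_run <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fpath <- file.path(out_dir, "features.csv")
  if (!file.exists(fpath)) pipeline_features(config, out_dir)
  ft <- read_feature_table(fpath)
  report <- run_grid(ft, criteria = config$criteria,
                     selections = config$selections,
                     classifiers = config$classifiers,
                     pop = config$pop, epochs = config$epochs,
                     filter_k = config$filter_k, seed = config$seed)
  mpath <- file.path(out_dir, "metrics.csv")
  write_metrics_report(report, mpath)
  shap_paths <- character(0)
  summaries <- list()
  for (crit in config$criteria) {
    sub <- report[report$criterion == crit, ]
    best <- sub[order(-sub$auc), ][1, ]
    fit <- fall_risk_model(ft, criteria = crit, selection = best$selection,
                           classifier = best$classifier, pop = config$pop,
                           epochs = config$epochs,
                           filter_k = config$filter_k, seed = config$seed)
    sh <- explain_fall_risk(fit, ft, nperm = config$shap_nperm,
                            seed = derive_seed(config$seed, 31))
    spath <- file.path(out_dir, sprintf("shap_criteria_%s.csv", crit))
    utils::write.csv(summarize_shap(sh), spath, row.names = FALSE)
    shap_paths <- c(shap_paths, spath)
    summaries[[crit]] <- sh
  }
  write_manifest(config, out_dir,
                 as.list(c(metrics = mpath, shap = shap_paths)))
  invisible(list(report = report, shap = summaries))
}

#' Human-readable summary of a completed run
#'
#' Prints the metrics grid per criterion in the conventional
#' selection-by-classifier layout and returns the report invisibly.
#'
#' @param run_dir directory written by [pipeline_run()].
#' @return invisibly, the metrics report data.frame.
#' @export
pipeline_report <- function(run_dir) {
  mpath <- file.path(run_dir, "metrics.csv")
  if (!file.exists(mpath)) stopf("no metrics report in %s (expected %s)",
                                 run_dir, mpath)
  rep <- read_metrics_report(mpath)
  for (crit in unique(rep$criterion)) {
    cat(sprintf("\nCriteria %s\n", crit))
    sub <- rep[rep$criterion == crit,
               c("selection", "classifier", "accuracy", "recall",
                 "specificity", "auc")]
    sub[, 3:6] <- round(sub[, 3:6], 2)
    print(sub, row.names = FALSE)
  }
  invisible(rep)
}
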