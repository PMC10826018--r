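# End-to-end modelling layer: split -> normalize -> select -> fit ->
# evaluate, as a single classed fit (fall_risk_model) and as the full
# selection x classifier grid (run_grid).

norm_feature_table <- function(table, rows, tf, label) {
  cols <- c(attr(table, "feature_cols"), attr(table, "personal_cols"))
  Z <- minmax_apply(tf, as.data.frame(table)[rows, cols, drop = FALSE])
  df <- data.frame(Z, check.names = FALSE, stringsAsFactors = FALSE)
  df[[label]] <- as.integer(table[[label]][rows])
  feature_table(df, feature_cols = attr(table, "feature_cols"),
                personal_cols = attr(table, "personal_cols"),
                label_cols = label)
}

select_features <- function(method, train_table, label, cfg, pop, epochs,
                            filter_k, seed) {
  feat_cols <- attr(train_table, "feature_cols")
  switch(method,
    none = {
      mask <- rep(TRUE, length(feat_cols))
      names(mask) <- feat_cols
      selection_result("none", mask, NA_real_, numeric(0), 0L, seed)
    },
    SMA = select_sma(train_table, label, cfg, pop, epochs, seed),
    HHO = select_hho(train_table, label, cfg, pop, epochs, seed),
    ABC = select_abc(train_table, label, cfg, pop, epochs, seed),
    MI = select_filter_baseline(train_table, label, "mi", filter_k),
    `F-value` = select_filter_baseline(train_table, label, "f_value",
                                       filter_k),
    stopf("unknown selection method '%s'", method))
}

design_matrix <- function(norm_table, mask) {
  feat_cols <- attr(norm_table, "feature_cols")
  pers_cols <- attr(norm_table, "personal_cols")
  keep <- c(feat_cols[as.logical(mask)], pers_cols)
  as.matrix(as.data.frame(norm_table)[, keep, drop = FALSE])
}

#' Fit one fall-risk classification pipeline
#'
#' The classic modelling entry point: stratified 50/20/30 split on the
#' chosen criterion, min-max normalization fitted on the training split
#' only, wrapper (or filter, or no) feature selection on the normalized
#' training split, classifier fit on the selected posturographic features
#' plus the personal metrics (which bypass selection), and evaluation on
#' the held-out test split.
#'
#' @param table a `feature_table` from [build_feature_table()].
#' @param criteria `"I"` (fall history) or `"II"` (TUG >= 10 s).
#' @param selection one of `"none"`, `"SMA"`, `"HHO"`, `"ABC"`, `"MI"`,
#'   `"F-value"`.
#' @param classifier a [classifier_spec()] or classifier name.
#' @param split a [split_spec()] (stratification label is set from
#'   `criteria`).
#' @param cfg a [fitness_config()] for wrapper selection.
#' @param pop,epochs wrapper optimizer settings (full-scale default: 100/100).
#' @param filter_k number of features kept by the filter baselines.
#' @param seed master seed; fans out to split, selection and classifier.
#' @return object of class `fall_risk_fit`.
#' @export
fall_risk_model <- function(table, criteria = c("II", "I"),
                            selection = "SMA",
                            classifier = "easy_ensemble",
                            split = NULL, cfg = NULL,
                            pop = 100, epochs = 100, filter_k = 31,
                            seed = 1L) {
  criteria <- match.arg(criteria)
  label <- paste0("criteria_", criteria)
  split <- split %||% split_spec(stratify_by = label,
                                 seed = derive_seed(seed, 11))
  split$stratify_by <- label
  cfg <- cfg %||% fitness_config(seed = derive_seed(seed, 12))
  idx <- split_dataset(table, split)
  cols <- c(attr(table, "feature_cols"), attr(table, "personal_cols"))
  tf <- minmax_fit(as.data.frame(table)[idx$train, cols, drop = FALSE])
  train_tab <- norm_feature_table(table, idx$train, tf, label)
  sel <- select_features(selection, train_tab, label, cfg, pop, epochs,
                         filter_k, derive_seed(seed, 13))
  if (is.character(classifier)) {
    classifier <- classifier_spec(classifier, seed = derive_seed(seed, 14))
  }
  Xtr <- design_matrix(train_tab, sel$best_mask)
  model <- fit_classifier(classifier, Xtr, train_tab[[label]])
  test_tab <- norm_feature_table(table, idx$test, tf, label)
  metrics <- evaluate_model(model, design_matrix(test_tab, sel$best_mask),
                            test_tab[[label]])
  structure(list(
    criteria = criteria, label = label, selection = sel,
    classifier_spec = classifier, model = model, normalizer = tf,
    split = idx, feature_cols = attr(table, "feature_cols"),
    personal_cols = attr(table, "personal_cols"),
    metrics = metrics, seed = seed
  ), class = "fall_risk_fit")
}

#' @export
print.fall_risk_fit <- function(x, ...) {
  cat(sprintf("<fall_risk_fit> criteria %s: %s selection (%d/%d features) + %s\n",
              x$criteria, x$selection$algorithm, sum(x$selection$best_mask),
              length(x$selection$best_mask), x$classifier_spec$name))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.fall_risk_fit <- function(object, ...) {
  cat("Fall-risk classification pipeline\n")
  cat("  criterion:   ", object$label, "\n")
  cat("  selection:   ", object$selection$algorithm, "-",
      sum(object$selection$best_mask), "of",
      length(object$selection$best_mask), "posturographic features\n")
  cat("  classifier:  ", object$classifier_spec$name, "\n")
  cat("  split sizes: ", paste(vapply(object$split, length, 0L),
                               collapse = "/"), "(train/val/test)\n")
  cat("  test metrics:\n")
  print(object$metrics)
  if (sum(object$selection$best_mask) <= 20 &&
      sum(object$selection$best_mask) > 0) {
    cat("  selected features:\n   ",
        paste(object$selection$selected_names, collapse = ", "), "\n")
  }
  invisible(object)
}

#' Predict fall risk for new data
#'
#' Applies the stored train-fitted normalizer and feature mask, then the
#' fitted classifier.
#'
#' @param object a `fall_risk_fit`.
#' @param newdata a `feature_table` or data.frame with the original columns.
#' @param type `"prob"`, `"class"` or `"score"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.fall_risk_fit <- function(object, newdata, type = "prob", ...) {
  cols <- c(object$feature_cols, object$personal_cols)
  Z <- minmax_apply(object$normalizer,
                    as.data.frame(newdata)[, cols, drop = FALSE])
  keep <- c(object$feature_cols[as.logical(object$selection$best_mask)],
            object$personal_cols)
  predict(object$model, Z[, keep, drop = FALSE], type = type)
}

#' Shapley explanation of a fitted fall-risk pipeline
#'
#' Explains the fitted classifier's probability output over its input
#' columns (selected posturographic features plus personal metrics), using
#' the training split as background (capped at 100 rows) and, by default,
#' the test split as the explained set.
#'
#' @param fit a `fall_risk_fit`.
#' @param table the `feature_table` the fit was built from.
#' @param explain_rows row indices to explain (default: the test split).
#' @param nperm permutations per instance.
#' @param seed seed.
#' @return a `shap_summary`.
#' @export
explain_fall_risk <- function(fit, table, explain_rows = NULL, nperm = 64,
                              seed = 1L) {
  cols <- c(fit$feature_cols, fit$personal_cols)
  Z <- minmax_apply(fit$normalizer, as.data.frame(table)[, cols, drop = FALSE])
  keep <- c(fit$feature_cols[as.logical(fit$selection$best_mask)],
            fit$personal_cols)
  Zk <- Z[, keep, drop = FALSE]
  explain_rows <- explain_rows %||% fit$split$test
  shap_values(fit$model, Zk[fit$split$train, , drop = FALSE],
              Zk[explain_rows, , drop = FALSE], nperm = nperm, seed = seed)
}

#' Run the full selection x classifier grid
#'
#' One evaluation row per (selection, classifier) per criterion, computed
#' on the test split; confusion matrices and ROC points are retained in the
#' `details` attribute. Selection and normalization are fitted strictly on
#' the training split of each criterion.
#'
#' @param table a `feature_table`.
#' @param criteria character vector among `"I"`, `"II"`.
#' @param selections selection methods (see [fall_risk_model()]).
#' @param classifiers classifier names.
#' @param pop,epochs,filter_k selection settings.
#' @param seed master seed.
#' @return data.frame of class `risk_grid` with columns criterion,
#'   selection, classifier, accuracy, recall, specificity, gm, auc, tp, fp,
#'   tn, fn, n_selected, seed.
#' @export
run_grid <- function(table, criteria = c("I", "II"),
                     selections = c("none", "SMA", "HHO", "ABC"),
                     classifiers = c("balanced_bagging", "complement_nb",
                                     "easy_ensemble"),
                     pop = 100, epochs = 100, filter_k = 31, seed = 1L) {
  rows <- list()
  details <- list()
  for (crit in criteria) {
    label <- paste0("criteria_", crit)
    split <- split_spec(stratify_by = label, seed = derive_seed(seed, 21))
    idx <- split_dataset(table, split)
    cols <- c(attr(table, "feature_cols"), attr(table, "personal_cols"))
    tf <- minmax_fit(as.data.frame(table)[idx$train, cols, drop = FALSE])
    train_tab <- norm_feature_table(table, idx$train, tf, label)
    test_tab <- norm_feature_table(table, idx$test, tf, label)
    cfg <- fitness_config(seed = derive_seed(seed, 22))
    for (selm in selections) {
      sel <- select_features(selm, train_tab, label, cfg, pop, epochs,
                             filter_k, derive_seed(seed, 23))
      Xtr <- design_matrix(train_tab, sel$best_mask)
      Xte <- design_matrix(test_tab, sel$best_mask)
      for (clf in classifiers) {
        cspec <- classifier_spec(clf, seed = derive_seed(seed, 24))
        model <- fit_classifier(cspec, Xtr, train_tab[[label]])
        em <- evaluate_model(model, Xte, test_tab[[label]])
        key <- paste(crit, selm, clf, sep = "|")
        details[[key]] <- list(metrics = em, mask = sel$best_mask)
        rows[[key]] <- data.frame(
          criterion = crit, selection = selm, classifier = clf,
          accuracy = em$accuracy, recall = em$sensitivity,
          specificity = em$specificity, gm = em$gm, auc = em$auc,
          tp = em$tp, fp = em$fp, tn = em$tn, fn = em$fn,
          n_selected = sum(sel$best_mask), seed = seed,
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "details") <- details
  class(report) <- c("risk_grid", "data.frame")
  report
}

#' @export
print.risk_grid <- function(x, digits = 2, ...) {
  d <- as.data.frame(x)
  for (cn in c("accuracy", "recall", "specificity", "gm", "auc")) {
    d[[cn]] <- round(d[[cn]], digits)
  }
  print(d[, c("criterion", "selection", "classifier", "accuracy", "recall",
              "specificity", "auc")], row.names = FALSE)
  invisible(x)
}

#' Write a grid report to CSV (with ROC points as JSON)
#'
#' @param report a `risk_grid`.
#' @param path CSV path; ROC points are written to `<path>.roc.json`.
#' @return invisibly, the paths.
#' @export
write_metrics_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  det <- attr(report, "details")
  roc <- lapply(det, function(d) d$metrics$roc_points)
  rpath <- paste0(path, ".roc.json")
  jsonlite::write_json(roc, rpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(report = path, roc = rpath))
}

#' Read a grid report written by [write_metrics_report()]
#' @param path CSV path.
#' @return data.frame report.
#' @export
read_metrics_report <- function(path) {
  if (!file.exists(path)) stopf("metrics report not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
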