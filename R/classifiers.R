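# Splitting, normalization, imbalance-aware classifiers and evaluation.
#
# Complement Naive Bayes (Rennie et al. 2003), AdaBoost-SAMME over weighted
# CNB learners, Easy Ensemble (balanced undersampled AdaBoost members) and
# Balanced Bagging (balanced bootstrap + feature bootstrap) are implemented
# here; SVM, decision tree and MLP comparators wrap e1071, rpart and nnet.
# All models expose a continuous positive-class score via risk_scores() and
# hard labels at the 0.5 probability threshold via risk_labels().

#' Train/validation/test split specification
#'
#' @param fractions named fractions `c(train=, val=, test=)` summing to 1.
#' @param stratify_by label column used for stratification.
#' @param seed seed for the within-class shuffles.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.5, val = 0.2, test = 0.3),
                       stratify_by = "criteria_II", seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stopf("split fractions must sum to 1")
  if (!identical(names(fractions), c("train", "val", "test"))) {
    stopf("fractions must be named train, val, test")
  }
  structure(list(fractions = fractions, stratify_by = stratify_by,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Stratified train/validation/test split
#'
#' Within each class the (seeded, shuffled) members are allocated to the
#' three splits by the largest-remainder method, so realized sizes match the
#' printed fractions as closely as integer counts allow (n = 215 gives
#' 107/43/65). Ties in the remainders are broken toward the later split
#' (test before val before train).
#'
#' @param y binary label vector (or a `feature_table`, in which case the
#'   `stratify_by` column of `spec` is used).
#' @param spec a [split_spec()].
#' @return list of integer index vectors `train`, `val`, `test` (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(y, spec = split_spec()) {
  if (inherits(y, "feature_table")) y <- y[[spec$stratify_by]]
  y <- as.integer(y)
  tab <- table(y)
  if (length(tab) < 2) stopf("both classes must be present")
  if (min(tab) < 3) stopf("each class needs at least 3 members to split")
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(spec$seed, {
    for (cls in names(tab)) {
      idx <- sample(which(y == as.integer(cls)))
      quota <- spec$fractions * length(idx)
      base <- floor(quota)
      rem <- quota - base
      seats <- length(idx) - sum(base)
      if (seats > 0) {
        # largest remainder; ties go to the later split (test first)
        ord <- order(-rem, -seq_along(rem))
        base[ord[seq_len(seats)]] <- base[ord[seq_len(seats)]] + 1
      }
      cuts <- cumsum(base)
      out$train <- c(out$train, idx[seq_len(base[1])])
      if (base[2] > 0) out$val <- c(out$val, idx[(cuts[1] + 1):cuts[2]])
      if (base[3] > 0) out$test <- c(out$test, idx[(cuts[2] + 1):cuts[3]])
    }
  })
  out <- lapply(out, function(v) unname(sort(v)))
  for (s in names(out)) {
    if (length(unique(y[out[[s]]])) < 2) {
      stopf("split '%s' does not contain both classes", s)
    }
  }
  out
}

#' Fit a min-max normalizer on training columns
#'
#' @param X numeric matrix or data.frame (training rows only).
#' @return object of class `minmax_transform` (per-column min and range).
#' @export
minmax_fit <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  const <- hi - lo <= 0
  if (any(const)) {
    warning("constant column(s) mapped to 0: ",
            paste(colnames(X)[const], collapse = ", "))
  }
  structure(list(lo = lo, range = ifelse(const, 1, hi - lo), const = const),
            class = "minmax_transform")
}

#' Apply a fitted min-max transform
#'
#' Training columns map to `[0, 1]`; values outside the training range (as
#' occur on validation/test rows) are clipped to `[0, 1]`. Constant training
#' columns map to 0.
#'
#' @param tf a `minmax_transform`.
#' @param X matrix/data.frame with the same columns.
#' @param clip clip to `[0,1]` (default TRUE).
#' @return normalized numeric matrix.
#' @export
minmax_apply <- function(tf, X, clip = TRUE) {
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, tf$lo[colnames(X)]), 2, tf$range[colnames(X)], "/")
  Z[, tf$const[colnames(X)]] <- 0
  if (clip) {
    Z[Z < 0] <- 0
    Z[Z > 1] <- 1
  }
  Z
}

## ---- Complement Naive Bayes -------------------------------------------

#' Fit a Complement Naive Bayes classifier
#'
#' Parameters are estimated from each class's complement (Rennie et al.'s
#' formulation): `theta_cj = (alpha + sum_{i not in c} w_i x_ij) /
#' (alpha * p + sum_{i not in c} w_i sum_j x_ij)`, scores
#' `s_c(x) = -sum_j x_j log(theta_cj)`, class probabilities by softmax over
#' the two class scores. Features must be non-negative (here: min-max
#' normalized to `[0, 1]`). Supports sample weights for boosting.
#'
#' @param X non-negative feature matrix.
#' @param y binary labels (0/1).
#' @param alpha additive (Laplace/Lidstone) smoothing, default 1.0.
#' @param weights optional non-negative sample weights.
#' @return object of class `swayrisk_cnb`.
#' @export
fit_cnb <- function(X, y, alpha = 1.0, weights = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("single-class y: cannot fit classifier")
  if (alpha <= 0) stopf("alpha must be positive")
  w <- weights %||% rep(1, nrow(X))
  p <- ncol(X)
  wlog <- matrix(0, p, 2)
  for (cls in 0:1) {
    comp <- y != cls
    cc <- colSums(X[comp, , drop = FALSE] * w[comp])
    theta <- (alpha + cc) / (alpha * p + sum(cc))
    wlog[, cls + 1] <- log(theta)
  }
  structure(list(wlog = wlog, cols = colnames(X), alpha = alpha),
            class = "swayrisk_cnb")
}

#' @export
predict.swayrisk_cnb <- function(object, newdata,
                                 type = c("prob", "class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(object$cols)) X <- X[, object$cols, drop = FALSE]
  # s_c = -X %*% wlog[, c]; positive-class prob = softmax
  margin <- as.numeric(X %*% (object$wlog[, 1] - object$wlog[, 2]))
  p1 <- stats::plogis(margin)
  switch(type,
         prob = p1,
         score = margin,
         class = as.integer(p1 >= 0.5))
}

## ---- AdaBoost (SAMME) over weighted CNB learners ----------------------

fit_adaboost_cnb <- function(X, y, n_rounds = 10, alpha = 1.0) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  w <- rep(1 / n, n)
  members <- list()
  betas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- fit_cnb(X, y, alpha = alpha, weights = w * n)
    pred <- predict(fit, X, type = "class")
    miss <- pred != y
    err <- sum(w[miss])
    if (err >= 0.5 && m > 1) break
    err <- min(max(err, 1e-10), 0.5 - 1e-10)
    beta <- log((1 - err) / err)
    members[[length(members) + 1]] <- fit
    betas <- c(betas, beta)
    w <- w * exp(beta * miss)
    w <- w / sum(w)
    if (sum(miss) == 0) break
  }
  structure(list(members = members, betas = betas),
            class = "swayrisk_adaboost")
}

#' @export
predict.swayrisk_adaboost <- function(object, newdata,
                                      type = c("prob", "class", "score"),
                                      ...) {
  type <- match.arg(type)
  # weighted vote margin in [-1, 1] scaled by total beta
  votes <- vapply(object$members, function(m)
    2 * predict(m, newdata, type = "prob") - 1, numeric(nrow(as.matrix(newdata))))
  votes <- matrix(votes, nrow = nrow(as.matrix(newdata)))
  margin <- as.numeric(votes %*% object$betas) / sum(object$betas)
  p1 <- (margin + 1) / 2
  switch(type, prob = p1, score = margin, class = as.integer(p1 >= 0.5))
}

## ---- Imbalance-aware ensembles ----------------------------------------

#' Fit an Easy Ensemble classifier
#'
#' Builds `n_estimators` AdaBoost learners, each grown from Complement NB
#' base estimators and trained on a balanced subset formed by keeping every
#' minority-class row and undersampling the majority class (without
#' replacement) to the minority size. Scores are averaged over members.
#'
#' @param X non-negative feature matrix.
#' @param y binary labels.
#' @param n_estimators number of AdaBoost learners (default 9).
#' @param ada_rounds boosting rounds inside each learner.
#' @param alpha CNB smoothing.
#' @param seed seed for the undersampling draws.
#' @return object of class `swayrisk_easy_ensemble`.
#' @export
fit_easy_ensemble <- function(X, y, n_estimators = 9, ada_rounds = 10,
                              alpha = 1.0, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("single-class y: cannot fit classifier")
  minority <- if (sum(y == 1) <= sum(y == 0)) 1L else 0L
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  members <- with_seed(seed, lapply(seq_len(n_estimators), function(m) {
    take <- sample(maj_idx, length(min_idx), replace = FALSE)
    idx <- c(min_idx, take)
    fit_adaboost_cnb(X[idx, , drop = FALSE], y[idx], n_rounds = ada_rounds,
                     alpha = alpha)
  }))
  structure(list(members = members), class = "swayrisk_easy_ensemble")
}

#' @export
predict.swayrisk_easy_ensemble <- function(object, newdata,
                                           type = c("prob", "class", "score"),
                                           ...) {
  type <- match.arg(type)
  probs <- vapply(object$members, function(m) predict(m, newdata, type = "prob"),
                  numeric(nrow(as.matrix(newdata))))
  p1 <- rowMeans(matrix(probs, nrow = nrow(as.matrix(newdata))))
  switch(type, prob = p1, score = p1, class = as.integer(p1 >= 0.5))
}

#' Fit a Balanced Bagging classifier
#'
#' `n_estimators` Complement NB base estimators, each trained on a balanced
#' bootstrap (the minority count drawn with replacement from every class)
#' and, when `bootstrap_features` is TRUE, on a feature multiset drawn with
#' replacement from the columns. Scores are averaged over members.
#'
#' @param X non-negative feature matrix.
#' @param y binary labels.
#' @param n_estimators number of base estimators (default 9).
#' @param bootstrap_features draw features with replacement (default TRUE).
#' @param alpha CNB smoothing.
#' @param seed seed for the resampling draws.
#' @return object of class `swayrisk_balanced_bagging`.
#' @export
fit_balanced_bagging <- function(X, y, n_estimators = 9,
                                 bootstrap_features = TRUE, alpha = 1.0,
                                 seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("single-class y: cannot fit classifier")
  n_min <- min(table(y))
  p <- ncol(X)
  members <- with_seed(seed, lapply(seq_len(n_estimators), function(m) {
    rows <- c(sample(which(y == 0), n_min, replace = TRUE),
              sample(which(y == 1), n_min, replace = TRUE))
    fidx <- if (bootstrap_features) sample(p, p, replace = TRUE) else seq_len(p)
    fit <- fit_cnb(X[rows, fidx, drop = FALSE], y[rows], alpha = alpha)
    list(fit = fit, fidx = fidx)
  }))
  structure(list(members = members), class = "swayrisk_balanced_bagging")
}

#' @export
predict.swayrisk_balanced_bagging <- function(object, newdata,
                                              type = c("prob", "class", "score"),
                                              ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  probs <- vapply(object$members, function(m)
    predict(m$fit, X[, m$fidx, drop = FALSE], type = "prob"),
    numeric(nrow(X)))
  p1 <- rowMeans(matrix(probs, nrow = nrow(X)))
  switch(type, prob = p1, score = p1, class = as.integer(p1 >= 0.5))
}

## ---- Traditional comparators ------------------------------------------

fit_svm_rbf <- function(X, y, cost = 1) {
  m <- e1071::svm(x = as.matrix(X), y = factor(y, levels = c(0, 1)),
                  kernel = "radial", cost = cost, scale = FALSE)
  structure(list(model = m), class = "swayrisk_svm")
}

#' @export
predict.swayrisk_svm <- function(object, newdata,
                                 type = c("prob", "class", "score"), ...) {
  type <- match.arg(type)
  pr <- predict(object$model, as.matrix(newdata), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm decision value is positive for the class named first in the
  # colname "a/b"; orient so larger = class 1
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  score <- if (first == "1") dv[, 1] else -dv[, 1]
  cls <- as.integer(as.character(pr))
  switch(type, score = as.numeric(score), prob = as.numeric(score),
         class = cls)
}

fit_tree <- function(X, y) {
  d <- data.frame(as.data.frame(X), .y = factor(y, levels = c(0, 1)))
  m <- rpart::rpart(.y ~ ., data = d, method = "class")
  structure(list(model = m, cols = colnames(X)), class = "swayrisk_tree")
}

#' @export
predict.swayrisk_tree <- function(object, newdata,
                                  type = c("prob", "class", "score"), ...) {
  type <- match.arg(type)
  nd <- as.data.frame(as.matrix(newdata))
  p1 <- predict(object$model, nd)[, "1"]
  switch(type, prob = p1, score = p1, class = as.integer(p1 >= 0.5))
}

fit_mlp <- function(X, y, size = 100, decay = 1e-4, maxit = 200, seed = 1L) {
  m <- with_seed(seed,
    nnet::nnet(as.matrix(X), as.numeric(y), size = size, decay = decay,
               maxit = maxit, MaxNWts = 100000, entropy = TRUE, trace = FALSE))
  structure(list(model = m), class = "swayrisk_mlp")
}

#' @export
predict.swayrisk_mlp <- function(object, newdata,
                                 type = c("prob", "class", "score"), ...) {
  type <- match.arg(type)
  p1 <- as.numeric(predict(object$model, as.matrix(newdata)))
  switch(type, prob = p1, score = p1, class = as.integer(p1 >= 0.5))
}

## ---- Unified interface -------------------------------------------------

#' Classifier specification
#'
#' Names and hyperparameters of the supported classifiers. Defaults follow
#' the ensemble settings used throughout: 9 learners, Complement NB base,
#' feature bootstrap on, smoothing alpha 1.0.
#'
#' @param name one of `easy_ensemble`, `balanced_bagging`, `complement_nb`,
#'   `svm`, `decision_tree`, `mlp`.
#' @param n_estimators ensemble size (>= 1).
#' @param ada_rounds boosting rounds inside each Easy Ensemble member.
#' @param bootstrap_features Balanced Bagging feature bootstrap flag.
#' @param alpha CNB additive smoothing (> 0).
#' @param svm_cost,mlp_size,mlp_maxit comparator settings.
#' @param seed seed for any resampling/initialization randomness.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("easy_ensemble", "balanced_bagging",
                                     "complement_nb", "svm", "decision_tree",
                                     "mlp"),
                            n_estimators = 9, ada_rounds = 10,
                            bootstrap_features = TRUE, alpha = 1.0,
                            svm_cost = 1, mlp_size = 100, mlp_maxit = 200,
                            seed = 1L) {
  name <- match.arg(name)
  if (n_estimators < 1) stopf("n_estimators must be >= 1")
  if (alpha <= 0) stopf("alpha must be > 0")
  structure(list(name = name, n_estimators = n_estimators,
                 ada_rounds = ada_rounds,
                 bootstrap_features = bootstrap_features, alpha = alpha,
                 svm_cost = svm_cost, mlp_size = mlp_size,
                 mlp_maxit = mlp_maxit, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Fit a classifier by specification
#'
#' @param spec a [classifier_spec()] (or a classifier name, using defaults).
#' @param X normalized feature matrix.
#' @param y binary labels (0/1).
#' @return a fitted model exposing `predict(..., type = "prob"/"class"/"score")`.
#' @export
fit_classifier <- function(spec, X, y) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("single-class y: cannot fit classifier")
  switch(spec$name,
    complement_nb = fit_cnb(X, y, alpha = spec$alpha),
    easy_ensemble = fit_easy_ensemble(X, y, n_estimators = spec$n_estimators,
                                      ada_rounds = spec$ada_rounds,
                                      alpha = spec$alpha, seed = spec$seed),
    balanced_bagging = fit_balanced_bagging(
      X, y, n_estimators = spec$n_estimators,
      bootstrap_features = spec$bootstrap_features, alpha = spec$alpha,
      seed = spec$seed),
    svm = fit_svm_rbf(X, y, cost = spec$svm_cost),
    decision_tree = fit_tree(X, y),
    mlp = fit_mlp(X, y, size = spec$mlp_size, maxit = spec$mlp_maxit,
                  seed = spec$seed))
}

## ---- Evaluation --------------------------------------------------------

#' Evaluation metrics from confusion counts
#'
#' @param tp,fp,tn,fn confusion counts.
#' @param auc optional AUC to attach.
#' @param roc optional ROC point data.frame to attach.
#' @return object of class `eval_metrics` with accuracy, sensitivity
#'   (recall), specificity, and `gm = sqrt(sensitivity * specificity)`.
#' @export
eval_metrics <- function(tp, fp, tn, fn, auc = NA_real_, roc = NULL) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NaN
  spec <- if (tn + fp > 0) tn / (tn + fp) else NaN
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = sens, specificity = spec,
                 gm = sqrt(sens * spec), auc = auc, roc_points = roc),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> acc=%.3f sens=%.3f spec=%.3f gm=%.3f auc=%.3f (tp=%d fp=%d tn=%d fn=%d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$gm, x$auc,
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

# ROC curve points from scores (thresholds = unique scores, descending).
roc_points <- function(scores, y) {
  ord <- order(scores, decreasing = TRUE)
  y <- as.integer(y)[ord]
  s <- scores[ord]
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  tps <- cumsum(y == 1)
  fps <- cumsum(y == 0)
  keep <- c(diff(s) != 0, TRUE)   # last point of each tied block
  data.frame(fpr = c(0, fps[keep] / n0), tpr = c(0, tps[keep] / n1))
}

#' Evaluate a fitted classifier on a labelled set
#'
#' Hard labels at the 0.5 probability threshold (decision-value sign for the
#' SVM), AUC from the score ranking (equivalent to the trapezoidal area
#' under the ROC, ties handled), and ROC points retained.
#'
#' @param model fitted model from [fit_classifier()].
#' @param X normalized feature matrix.
#' @param y binary labels.
#' @return an [eval_metrics()] object.
#' @export
evaluate_model <- function(model, X, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("AUC undefined: y contains a single class")
  scores <- predict(model, X, type = "score")
  labels <- predict(model, X, type = "class")
  tp <- sum(labels == 1 & y == 1)
  fp <- sum(labels == 1 & y == 0)
  tn <- sum(labels == 0 & y == 0)
  fn <- sum(labels == 0 & y == 1)
  eval_metrics(tp, fp, tn, fn, auc = auc_rank(scores, y),
               roc = roc_points(scores, y))
}
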