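# Shapley-value explanations of fitted pipeline models: an exact
# enumeration oracle for small feature counts and a permutation-sampling
# estimator for the full feature set. The value function is the
# interventional (background-substitution) expectation of the model score.

# Resolve a score function: either a function(matrix) -> numeric, or a
# fitted model exposing predict(..., type = "prob").
as_score_fn <- function(model) {
  if (is.function(model)) return(model)
  function(X) predict(model, X, type = "prob")
}

#' Exact Shapley attributions by coalition enumeration
#'
#' Classic Shapley values over all `2^m` coalitions. The value of a
#' coalition S is the mean model score over the background sample with the
#' features in S replaced by the instance's values (interventional
#' expectation). Exact for the given value function; refused for more than
#' 12 features.
#'
#' @param score_fn function taking a numeric matrix and returning a score
#'   per row (or a fitted model).
#' @param instance numeric vector (one row) to explain.
#' @param background numeric matrix of background rows (same columns).
#' @param max_features refusal bound (default 12).
#' @return numeric attribution vector; attribute `base_value` holds the
#'   mean background score, and `base_value + sum(attributions)` equals the
#'   instance score (efficiency).
#' @export
exact_shapley <- function(score_fn, instance, background, max_features = 12) {
  f <- as_score_fn(score_fn)
  background <- as.matrix(background)
  m <- length(instance)
  if (m > max_features) {
    stopf("exact Shapley enumeration refused for %d > %d features", m,
          max_features)
  }
  if (nrow(background) < 1) stopf("background sample must be non-empty")
  nb <- nrow(background)
  nsub <- 2^m
  # value of every coalition
  v <- numeric(nsub)
  for (code in 0:(nsub - 1)) {
    inS <- as.logical(bitwAnd(bitwShiftR(code, 0:(m - 1)), 1L))
    Xb <- background
    if (any(inS)) Xb[, inS] <- matrix(instance[inS], nb, sum(inS), byrow = TRUE)
    v[code + 1] <- mean(f(Xb))
  }
  sizes <- vapply(0:(nsub - 1), function(code) sum(
    bitwAnd(bitwShiftR(code, 0:(m - 1)), 1L)), 0L)
  wts <- factorial(0:(m - 1)) * factorial(m - 1 - (0:(m - 1))) / factorial(m)
  phi <- numeric(m)
  for (i in seq_len(m)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (code in 0:(nsub - 1)) {
      if (bitwAnd(code, bit) == 0L) {
        s <- sizes[code + 1]
        phi[i] <- phi[i] + wts[s + 1] * (v[code + bit + 1] - v[code + 1])
      }
    }
  }
  names(phi) <- colnames(background)
  attr(phi, "base_value") <- v[1]
  phi
}

#' Sampling-based Shapley attributions for a set of instances
#'
#' Permutation estimator: for each sampled feature permutation the features
#' are switched one by one from their background values to the instance's
#' values, and the successive differences of the background-averaged score
#' are credited to the switched feature. Attributions are averaged over
#' `nperm` permutations, so each instance's attributions sum exactly to
#' `score(instance) - base_value` (local accuracy), and the estimate
#' converges to [exact_shapley()] as `nperm` grows.
#'
#' @param model fitted model (or score function).
#' @param background numeric matrix of background rows; capped at
#'   `background_cap` rows by seeded sampling.
#' @param explain_set numeric matrix of instances to explain.
#' @param nperm permutations per instance.
#' @param seed seed.
#' @param background_cap maximum background rows retained.
#' @return object of class `shap_summary`: list with `attributions`
#'   (instances x features), `base_value`, and `feature_order` (descending
#'   mean absolute attribution).
#' @export
shap_values <- function(model, background, explain_set, nperm = 200,
                        seed = 1L, background_cap = 100) {
  f <- as_score_fn(model)
  background <- as.matrix(background)
  explain_set <- as.matrix(explain_set)
  if (nrow(explain_set) < 1) stopf("explain_set must be non-empty")
  m <- ncol(explain_set)
  with_seed(seed, {
    if (nrow(background) > background_cap) {
      background <- background[sample.int(nrow(background), background_cap), ,
                               drop = FALSE]
    }
    nb <- nrow(background)
    base_value <- mean(f(background))
    attributions <- matrix(0, nrow(explain_set), m,
                           dimnames = list(NULL, colnames(explain_set)))
    for (r in seq_len(nrow(explain_set))) {
      x <- explain_set[r, ]
      acc <- numeric(m)
      for (pp in seq_len(nperm)) {
        perm <- sample.int(m)
        Xb <- background
        prev <- mean(f(Xb))
        for (j in perm) {
          Xb[, j] <- x[j]
          cur <- mean(f(Xb))
          acc[j] <- acc[j] + (cur - prev)
          prev <- cur
        }
      }
      attributions[r, ] <- acc / nperm
    }
    order_idx <- order(-colMeans(abs(attributions)),
                       colnames(explain_set) %||% as.character(seq_len(m)))
    structure(list(attributions = attributions, base_value = base_value,
                   feature_order = (colnames(explain_set) %||%
                                      as.character(seq_len(m)))[order_idx]),
              class = "shap_summary")
  })
}

#' @export
print.shap_summary <- function(x, ...) {
  cat("<shap_summary>", nrow(x$attributions), "instances x",
      ncol(x$attributions), "features; base value",
      format(x$base_value, digits = 4), "\n")
  cat("  top features:", paste(utils::head(x$feature_order, 5),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Rank features by mean absolute Shapley attribution
#'
#' @param summary a `shap_summary`.
#' @param top_k number of rows to return (default: all).
#' @return data.frame with `feature`, `mean_abs_attr`, `mean_attr`, in
#'   descending `mean_abs_attr` order (ties broken by name).
#' @export
summarize_shap <- function(summary, top_k = NULL) {
  stopifnot(inherits(summary, "shap_summary"))
  a <- summary$attributions
  nm <- colnames(a) %||% as.character(seq_len(ncol(a)))
  d <- data.frame(feature = nm, mean_abs_attr = colMeans(abs(a)),
                  mean_attr = colMeans(a), stringsAsFactors = FALSE)
  d <- d[order(-d$mean_abs_attr, d$feature), ]
  rownames(d) <- NULL
  if (!is.null(top_k)) d <- utils::head(d, top_k)
  d
}
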