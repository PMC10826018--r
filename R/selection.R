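# Wrapper feature selection: composite fitness (geometric mean + AUC +
# sparsity) scored by stratified cross-validation of an inner classifier,
# searched with binary versions of the Slime Mould Algorithm, Harris Hawks
# Optimization and Artificial Bee Colony; plus mutual-information and
# ANOVA-F univariate filter baselines and a brute-force reference.

#' Fitness configuration for wrapper selection
#'
#' The fitness of a feature mask is
#' `w1 * GM + w2 * AUC + w3 * lambda`, where GM and AUC are the mean
#' cross-validated geometric mean and area under the curve of the inner
#' classifier restricted to the masked columns (personal metrics appended
#' when present), and `lambda = 1 - |selected| / |all|` rewards sparsity.
#' Classification terms dominate by default; sparsity acts as a mild
#' regularizer.
#'
#' @param w1,w2,w3 non-negative weights for GM, AUC and sparsity
#'   (default 0.4, 0.4, 0.2).
#' @param cv_folds stratified folds on the training set (default 3).
#' @param inner_classifier classifier name scoring the masks (default
#'   `complement_nb`: fast, and matches the ensembles' base learner).
#' @param include_personal append personal-metric columns (which bypass
#'   selection) when scoring a mask.
#' @param seed seed fixing the CV fold assignment (making the fitness a
#'   deterministic function of the mask).
#' @return object of class `fitness_config`.
#' @export
fitness_config <- function(w1 = 0.4, w2 = 0.4, w3 = 0.2, cv_folds = 3,
                           inner_classifier = "complement_nb",
                           include_personal = TRUE, seed = 1L) {
  if (any(c(w1, w2, w3) < 0) || w1 + w2 + w3 <= 0) {
    stopf("weights must be non-negative with positive sum")
  }
  if (cv_folds < 2) stopf("cv_folds must be >= 2")
  structure(list(w1 = w1, w2 = w2, w3 = w3, cv_folds = as.integer(cv_folds),
                 inner_classifier = inner_classifier,
                 include_personal = include_personal, seed = as.integer(seed)),
            class = "fitness_config")
}

#' Sparsity term of the wrapper fitness
#'
#' `lambda = 1 - |selected| / |all|`: 0 for the full mask, approaching 1 as
#' the mask empties.
#'
#' @param mask logical feature mask.
#' @return lambda in `[0, 1)`.
#' @export
sparsity_term <- function(mask) {
  1 - sum(mask) / length(mask)
}

#' Combine the fitness terms
#'
#' @param gm cross-validated geometric mean.
#' @param auc cross-validated AUC.
#' @param lambda sparsity term.
#' @param cfg a [fitness_config()] supplying the weights.
#' @return scalar fitness.
#' @export
combine_fitness <- function(gm, auc, lambda, cfg = fitness_config()) {
  cfg$w1 * gm + cfg$w2 * auc + cfg$w3 * lambda
}

#' Build a deterministic fitness function over feature masks
#'
#' Precomputes the design matrix and a fixed stratified fold assignment so
#' the returned closure is a deterministic function of the mask. The table
#' is expected to be normalized to `[0, 1]` already (fit the normalizer on
#' the training split).
#'
#' @param table a `feature_table` (training rows, normalized).
#' @param label label column to classify (`criteria_I` or `criteria_II`).
#' @param cfg a [fitness_config()].
#' @return function(mask) -> fitness; the closure also accepts
#'   `detail = TRUE` to return the GM/AUC/lambda components.
#' @export
make_fitness <- function(table, label, cfg = fitness_config()) {
  feat_cols <- attr(table, "feature_cols")
  pers_cols <- if (cfg$include_personal) attr(table, "personal_cols") else
    character(0)
  Xf <- as.matrix(as.data.frame(table)[, feat_cols, drop = FALSE])
  Xp <- if (length(pers_cols)) {
    as.matrix(as.data.frame(table)[, pers_cols, drop = FALSE])
  } else NULL
  y <- as.integer(table[[label]])
  if (length(unique(y)) < 2) stopf("label '%s' has a single class", label)
  fold <- stratified_folds(y, cfg$cv_folds, cfg$seed)
  inner <- cfg$inner_classifier

  function(mask, detail = FALSE) {
    mask <- as.logical(mask)
    if (length(mask) != ncol(Xf)) stopf("mask length != number of features")
    if (!any(mask)) stopf("fitness evaluated on an empty mask (repair first)")
    X <- Xf[, mask, drop = FALSE]
    if (!is.null(Xp)) X <- cbind(X, Xp)
    gms <- aucs <- numeric(cfg$cv_folds)
    for (k in seq_len(cfg$cv_folds)) {
      tr <- fold != k
      fit <- fit_classifier(inner, X[tr, , drop = FALSE], y[tr])
      sc <- predict(fit, X[!tr, , drop = FALSE], type = "score")
      cl <- predict(fit, X[!tr, , drop = FALSE], type = "class")
      yk <- y[!tr]
      sens <- sum(cl == 1 & yk == 1) / max(1, sum(yk == 1))
      spec <- sum(cl == 0 & yk == 0) / max(1, sum(yk == 0))
      gms[k] <- sqrt(sens * spec)
      aucs[k] <- auc_rank(sc, yk)
    }
    gm <- mean(gms)
    auc <- mean(aucs)
    lam <- sparsity_term(mask)
    fit <- combine_fitness(gm, auc, lam, cfg)
    if (detail) list(fitness = fit, gm = gm, auc = auc, lambda = lam) else fit
  }
}

#' Wrapper fitness of one mask
#'
#' Convenience wrapper around [make_fitness()].
#'
#' @param mask logical mask over the feature columns.
#' @param table normalized training `feature_table`.
#' @param label label column.
#' @param cfg a [fitness_config()].
#' @param detail return the components as a list.
#' @return scalar fitness (or component list).
#' @export
fitness <- function(mask, table, label, cfg = fitness_config(),
                    detail = FALSE) {
  make_fitness(table, label, cfg)(mask, detail = detail)
}

## ---- binary encoding ---------------------------------------------------

# S-shaped transfer: continuous position in [0,1] -> bit probability.
transfer_s <- function(v) 1 / (1 + exp(-10 * (v - 0.5)))

# Stochastic binarization of a position vector.
binarize <- function(pos) stats::runif(length(pos)) < transfer_s(pos)

# Repair: guarantee at least one selected bit.
repair_mask <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1)] <- TRUE
  mask
}

selection_result <- function(algorithm, mask, fitness, history, evaluations,
                             seed, feature_names = NULL) {
  if (!is.null(feature_names)) names(mask) <- feature_names
  structure(list(algorithm = algorithm, best_mask = mask,
                 best_fitness = fitness, history = history,
                 evaluations = evaluations, seed = seed,
                 selected_names = names(mask)[mask] %||% which(mask)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d/%d features, fitness %.4f (%d evaluations)\n",
              x$algorithm, sum(x$best_mask), length(x$best_mask),
              x$best_fitness, x$evaluations))
  invisible(x)
}

#' Plot the best-so-far fitness trace of a selection run
#' @param x a `selection_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.selection_result <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "s",
                 xlab = "epoch", ylab = "best-so-far fitness",
                 main = x$algorithm, ...)
  invisible(x)
}

## ---- metaheuristic cores -----------------------------------------------

# Shared machinery: population of continuous positions in [0,1]^n; masks are
# drawn through the S-shaped transfer, repaired, and scored; the global best
# (mask, fitness) is tracked, giving a monotone best-so-far history.
new_search_state <- function(fn, n, pop, seed) {
  env <- new.env(parent = emptyenv())
  env$evals <- 0L
  env$best_fit <- -Inf
  env$best_mask <- NULL
  env$score <- function(pos) {
    mask <- repair_mask(binarize(pos))
    f <- fn(mask)
    env$evals <- env$evals + 1L
    if (f > env$best_fit) {
      env$best_fit <- f
      env$best_mask <- mask
    }
    list(fitness = f, mask = mask)
  }
  env
}

# Binary Slime Mould Algorithm (Li et al. 2020 update rules, maximization).
binary_sma <- function(fn, n, pop = 100, epochs = 100, seed = 1L, z = 0.03) {
  if (epochs < 1) stopf("epochs must be >= 1")
  with_seed(seed, {
    st <- new_search_state(fn, n, pop, seed)
    X <- matrix(stats::runif(pop * n), pop, n)
    fit <- numeric(pop)
    history <- numeric(epochs)
    for (t in seq_len(epochs)) {
      for (i in seq_len(pop)) fit[i] <- st$score(X[i, ])$fitness
      ord <- order(fit, decreasing = TRUE)
      bF <- fit[ord[1]]
      wF <- fit[ord[pop]]
      Xb <- X[ord[1], ]
      denom <- max(bF - wF, 1e-12)
      W <- matrix(1, pop, n)
      half <- floor(pop / 2)
      for (r in seq_len(pop)) {
        i <- ord[r]
        lg <- log10((bF - fit[i]) / denom + 1)
        rr <- stats::runif(n)
        W[i, ] <- if (r <= half) 1 + rr * lg else 1 - rr * lg
      }
      a <- atanh(max(1e-12, 1 - t / epochs))
      b <- 1 - t / epochs
      p <- tanh(abs(fit - st$best_fit))
      for (i in seq_len(pop)) {
        if (stats::runif(1) < z) {
          X[i, ] <- stats::runif(n)
        } else {
          vb <- stats::runif(n, -a, a)
          vc <- stats::runif(n, -b, b)
          cond <- stats::runif(n) < p[i]
          A <- X[sample.int(pop, 1), ]
          B <- X[sample.int(pop, 1), ]
          upd <- Xb + vb * (W[i, ] * A - B)
          # oscillation contracted toward the best position: in the unit
          # bit-probability cube the original origin-centered vc*X branch
          # collapses every agent onto the empty mask, so the shrinking
          # oscillation is centered on the best-so-far position instead
          osc <- Xb + vc * (X[i, ] - Xb)
          X[i, ] <- ifelse(cond, upd, osc)
        }
      }
      X[X < 0] <- 0
      X[X > 1] <- 1
      history[t] <- st$best_fit
    }
    selection_result("SMA", st$best_mask, st$best_fit, history, st$evals, seed)
  })
}

# Mantegna Levy step used by HHO's rapid dives.
levy_step <- function(n, beta = 1.5) {
  num <- gamma(1 + beta) * sin(pi * beta / 2)
  den <- gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)
  sigma <- (num / den)^(1 / beta)
  u <- stats::rnorm(n) * sigma
  v <- stats::rnorm(n)
  u / abs(v)^(1 / beta)
}

# Binary Harris Hawks Optimization (Heidari et al. 2019 phases).
binary_hho <- function(fn, n, pop = 100, epochs = 100, seed = 1L) {
  if (epochs < 1) stopf("epochs must be >= 1")
  with_seed(seed, {
    st <- new_search_state(fn, n, pop, seed)
    X <- matrix(stats::runif(pop * n), pop, n)
    fit <- numeric(pop)
    history <- numeric(epochs)
    clamp <- function(v) pmin(1, pmax(0, v))
    for (t in seq_len(epochs)) {
      for (i in seq_len(pop)) fit[i] <- st$score(X[i, ])$fitness
      rabbit <- X[which.max(fit), ]
      Xm <- colMeans(X)
      for (i in seq_len(pop)) {
        E0 <- stats::runif(1, -1, 1)
        E <- 2 * E0 * (1 - t / epochs)
        J <- 2 * (1 - stats::runif(1))
        if (abs(E) >= 1) {
          if (stats::runif(1) >= 0.5) {
            Xr <- X[sample.int(pop, 1), ]
            X[i, ] <- Xr - stats::runif(1) * abs(Xr - 2 * stats::runif(1) * X[i, ])
          } else {
            X[i, ] <- (rabbit - Xm) - stats::runif(1) * stats::runif(n)
          }
        } else {
          r <- stats::runif(1)
          if (r >= 0.5 && abs(E) >= 0.5) {          # soft besiege
            X[i, ] <- (rabbit - X[i, ]) - E * abs(J * rabbit - X[i, ])
          } else if (r >= 0.5) {                    # hard besiege
            X[i, ] <- rabbit - E * abs(rabbit - X[i, ])
          } else if (abs(E) >= 0.5) {               # soft besiege, rapid dives
            Y <- clamp(rabbit - E * abs(J * rabbit - X[i, ]))
            Z <- clamp(Y + stats::runif(n) * levy_step(n))
            fy <- st$score(Y)$fitness
            fz <- st$score(Z)$fitness
            if (fy >= fz && fy > fit[i]) X[i, ] <- Y
            else if (fz > fit[i]) X[i, ] <- Z
          } else {                                  # hard besiege, rapid dives
            Y <- clamp(rabbit - E * abs(J * rabbit - Xm))
            Z <- clamp(Y + stats::runif(n) * levy_step(n))
            fy <- st$score(Y)$fitness
            fz <- st$score(Z)$fitness
            if (fy >= fz && fy > fit[i]) X[i, ] <- Y
            else if (fz > fit[i]) X[i, ] <- Z
          }
        }
      }
      X[X < 0] <- 0
      X[X > 1] <- 1
      history[t] <- st$best_fit
    }
    selection_result("HHO", st$best_mask, st$best_fit, history, st$evals, seed)
  })
}

# Binary Artificial Bee Colony (Karaboga): employed/onlooker/scout phases on
# continuous food-source positions, greedy per-source selection. Neighbor
# moves perturb a random fraction `mr` of dimensions (the modification rate
# of binary ABC variants); the classic one-dimension move stalls on
# feature-mask problems.
binary_abc <- function(fn, n, pop = 100, epochs = 100, seed = 1L,
                       limit = NULL, mr = 0.3) {
  if (epochs < 1) stopf("epochs must be >= 1")
  sn <- max(2, floor(pop / 2))                   # food sources
  limit <- limit %||% max(10, sn * n %/% 4)
  with_seed(seed, {
    st <- new_search_state(fn, n, pop, seed)
    X <- matrix(stats::runif(sn * n), sn, n)
    fit <- numeric(sn)
    trials <- integer(sn)
    for (i in seq_len(sn)) fit[i] <- st$score(X[i, ])$fitness
    history <- numeric(epochs)
    neighbor <- function(i) {
      k <- sample(setdiff(seq_len(sn), i), 1)
      dims <- which(stats::runif(n) < mr)
      if (!length(dims)) dims <- sample.int(n, 1)
      v <- X[i, ]
      v[dims] <- v[dims] + stats::runif(length(dims), -1, 1) *
        (v[dims] - X[k, dims])
      pmin(1, pmax(0, v))
    }
    greedy <- function(i, v) {
      fv <- st$score(v)$fitness
      if (fv > fit[i]) {
        X[i, ] <<- v
        fit[i] <<- fv
        trials[i] <<- 0L
      } else trials[i] <<- trials[i] + 1L
    }
    for (t in seq_len(epochs)) {
      for (i in seq_len(sn)) greedy(i, neighbor(i))        # employed bees
      shifted <- fit - min(fit)
      prob <- (shifted + 1e-12) / sum(shifted + 1e-12)
      picks <- sample.int(sn, sn, replace = TRUE, prob = prob)
      for (i in picks) greedy(i, neighbor(i))              # onlooker bees
      worn <- which(trials > limit)                        # scout bees
      for (i in worn) {
        X[i, ] <- stats::runif(n)
        fit[i] <- st$score(X[i, ])$fitness
        trials[i] <- 0L
      }
      history[t] <- st$best_fit
    }
    selection_result("ABC", st$best_mask, st$best_fit, history, st$evals, seed)
  })
}

## ---- public selection operations ---------------------------------------

run_wrapper <- function(algorithm, table, label, cfg, pop, epochs, seed) {
  fn <- make_fitness(table, label, cfg)
  n <- length(attr(table, "feature_cols"))
  core <- switch(algorithm, SMA = binary_sma, HHO = binary_hho,
                 ABC = binary_abc)
  res <- core(fn, n, pop = pop, epochs = epochs, seed = seed)
  names(res$best_mask) <- attr(table, "feature_cols")
  res$selected_names <- names(res$best_mask)[res$best_mask]
  res
}

#' Wrapper feature selection with the Slime Mould Algorithm
#'
#' Binary SMA over feature masks, scored by the composite cross-validated
#' fitness of [make_fitness()]. Continuous slime positions are mapped to
#' bits through an S-shaped transfer function; empty masks are repaired
#' before scoring; the best-so-far history is monotone non-decreasing.
#'
#' @param table normalized training `feature_table`.
#' @param label label column.
#' @param cfg a [fitness_config()].
#' @param pop population size (full-scale default: 100).
#' @param epochs epochs (full-scale default: 100).
#' @param seed optimizer seed.
#' @return a `selection_result`.
#' @export
select_sma <- function(table, label = "criteria_II", cfg = fitness_config(),
                       pop = 100, epochs = 100, seed = 1L) {
  run_wrapper("SMA", table, label, cfg, pop, epochs, seed)
}

#' Wrapper feature selection with Harris Hawks Optimization
#'
#' Same contract as [select_sma()], searching with the HHO
#' exploration/exploitation phases (soft/hard besiege with Levy-flight
#' rapid dives).
#'
#' @inheritParams select_sma
#' @return a `selection_result`.
#' @export
select_hho <- function(table, label = "criteria_II", cfg = fitness_config(),
                       pop = 100, epochs = 100, seed = 1L) {
  run_wrapper("HHO", table, label, cfg, pop, epochs, seed)
}

#' Wrapper feature selection with the Artificial Bee Colony
#'
#' Same contract as [select_sma()], searching with the standard bee-colony
#' employed/onlooker/scout phases.
#'
#' @inheritParams select_sma
#' @return a `selection_result`.
#' @export
select_abc <- function(table, label = "criteria_II", cfg = fitness_config(),
                       pop = 100, epochs = 100, seed = 1L) {
  run_wrapper("ABC", table, label, cfg, pop, epochs, seed)
}

#' Brute-force best mask over all non-empty subsets
#'
#' Exhaustive reference for small feature counts; used to verify that the
#' metaheuristics reach the global optimum.
#'
#' @param fn fitness closure from [make_fitness()].
#' @param n number of features (<= 20).
#' @return a `selection_result` with algorithm `"exhaustive"`.
#' @export
exhaustive_best <- function(fn, n) {
  if (n > 20) stopf("exhaustive search limited to 20 features")
  best_f <- -Inf
  best_mask <- NULL
  for (code in seq_len(2^n - 1)) {
    mask <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
    f <- fn(mask)
    if (f > best_f) {
      best_f <- f
      best_mask <- mask
    }
  }
  selection_result("exhaustive", best_mask, best_f, best_f, 2^n - 1, NA_integer_)
}

## ---- univariate filter baselines ---------------------------------------

# Mutual information between a continuous feature and a binary label via
# equal-frequency discretization (quantile bins, duplicate breaks dropped).
mi_score <- function(x, y, bins = 8) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 3) return(0)           # (near-)constant feature
  xb <- cut(x, breaks = br, include.lowest = TRUE)
  tab <- table(xb, y)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy)
  py <- colSums(pxy)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (pxy[i, j] > 0) mi <- mi + pxy[i, j] * log(pxy[i, j] / (px[i] * py[j]))
    }
  }
  max(0, mi)
}

# One-way ANOVA F statistic of a feature against a binary label.
f_score <- function(x, y) {
  y <- as.integer(y)
  n <- length(x)
  g <- split(x, y)
  k <- length(g)
  grand <- mean(x)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 0))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  if (ssw <= 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Univariate filter feature selection (MI or ANOVA F-value)
#'
#' Ranks the feature columns by their univariate score against the label
#' and keeps the top `k`. Ties are broken by column name (stable,
#' deterministic).
#'
#' @param table `feature_table` (training rows).
#' @param label label column.
#' @param method `"mi"` (mutual information, quantile-discretized) or
#'   `"f_value"` (one-way ANOVA F).
#' @param k number of features to keep, in `[1, n_features]`.
#' @param cfg optional [fitness_config()]; when given, the resulting mask's
#'   wrapper fitness is computed and recorded.
#' @return a `selection_result` (algorithm `"MI"` or `"F-value"`).
#' @export
select_filter_baseline <- function(table, label = "criteria_II",
                                   method = c("mi", "f_value"), k,
                                   cfg = NULL) {
  method <- match.arg(method)
  feat_cols <- attr(table, "feature_cols")
  if (!is_count(k) || k > length(feat_cols)) {
    stopf("k must be an integer in [1, %d]", length(feat_cols))
  }
  y <- as.integer(table[[label]])
  scores <- vapply(feat_cols, function(cn) {
    x <- as.numeric(table[[cn]])
    if (method == "mi") mi_score(x, y) else f_score(x, y)
  }, 0)
  ord <- order(-scores, feat_cols)
  mask <- feat_cols %in% feat_cols[ord[seq_len(k)]]
  names(mask) <- feat_cols
  bf <- NA_real_
  hist <- numeric(0)
  evals <- 0L
  if (!is.null(cfg)) {
    bf <- make_fitness(table, label, cfg)(mask)
    hist <- bf
    evals <- 1L
  }
  res <- selection_result(if (method == "mi") "MI" else "F-value",
                          mask, bf, hist, evals, NA_integer_)
  res$scores <- scores
  res
}
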