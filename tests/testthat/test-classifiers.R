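# Splitting, normalization, classifiers and evaluation metrics.

test_that("stratified 50/20/30 split reproduces the canonical sizes", {
  # class sizes 66 / 149 (n = 215)
  y <- c(rep(1, 66), rep(0, 149))
  idx <- split_dataset(y, split_spec(seed = 3))
  expect_equal(sapply(idx, length), c(train = 107, val = 43, test = 65))
  all_idx <- sort(unname(unlist(idx)))
  expect_identical(all_idx, seq_along(y))
  # stratification: each split holds both classes in near-target proportion
  for (s in idx) {
    expect_true(all(0:1 %in% y[s]))
    expect_lt(abs(mean(y[s]) - mean(y)), 0.05)
  }
})

test_that("splits are deterministic under seed and error on tiny classes", {
  y <- rbinom(50, 1, 0.5)
  a <- split_dataset(y, split_spec(seed = 9))
  b <- split_dataset(y, split_spec(seed = 9))
  expect_identical(a, b)
  d <- split_dataset(y, split_spec(seed = 10))
  expect_false(identical(a$train, d$train))
  expect_error(split_dataset(c(1, 1, 0, rep(0, 5)), split_spec(seed = 1)),
               "at least 3")
  # n = 10 balanced: both classes everywhere
  y10 <- rep(0:1, 5)
  idx10 <- split_dataset(y10, split_spec(seed = 2))
  for (s in idx10) expect_true(all(0:1 %in% y10[s]))
})

test_that("min-max normalization maps train to [0,1] and clips new data", {
  X <- cbind(a = c(2, 4, 6), b = c(1, 2, 3))
  tf <- minmax_fit(X)
  Z <- minmax_apply(tf, X)
  expect_equal(unname(Z[, "a"]), c(0, 0.5, 1))
  Znew <- minmax_apply(tf, cbind(a = c(8, 1), b = c(2.5, 2)))
  expect_equal(unname(Znew[, "a"]), c(1, 0))
  expect_equal(unname(Znew[, "b"]), c(0.75, 0.5))
  # invertible on non-clipped values
  back <- sweep(sweep(minmax_apply(tf, X, clip = FALSE), 2, tf$range, "*"),
                2, tf$lo, "+")
  expect_equal(unname(back), unname(X), tolerance = 1e-12)
  expect_warning(minmax_fit(cbind(c = rep(5, 3))), "constant")
})

test_that("every classifier separates linearly separable data", {
  blobs <- make_blobs(n = 160, p = 4, sep = 4, seed = 13)
  tr <- 1:100
  te <- 101:160
  for (clf in c("complement_nb", "easy_ensemble", "balanced_bagging", "svm",
                "decision_tree", "mlp")) {
    m <- fit_classifier(classifier_spec(clf, seed = 1), blobs$X[tr, ],
                        blobs$y[tr])
    acc <- mean(predict(m, blobs$X[te, ], type = "class") == blobs$y[te])
    expect_gte(acc, 0.95)
  }
})

test_that("classifier fits are reproducible under a fixed seed", {
  blobs <- make_blobs(n = 120, p = 4, sep = 1.5, seed = 7)
  for (clf in c("easy_ensemble", "balanced_bagging", "mlp")) {
    m1 <- fit_classifier(classifier_spec(clf, seed = 5), blobs$X, blobs$y)
    m2 <- fit_classifier(classifier_spec(clf, seed = 5), blobs$X, blobs$y)
    expect_identical(predict(m1, blobs$X, type = "prob"),
                     predict(m2, blobs$X, type = "prob"))
  }
  expect_error(fit_classifier("complement_nb", blobs$X, rep(1, 120)),
               "single-class")
})

test_that("evaluation identities hold for hand-computed confusion counts", {
  em <- eval_metrics(tp = 12, fp = 5, tn = 45, fn = 2)
  expect_equal(em$sensitivity, 12 / 14)
  expect_equal(em$specificity, 45 / 50)
  expect_equal(em$accuracy, 57 / 64)
  expect_equal(em$gm, sqrt((12 / 14) * (45 / 50)))
  expect_equal(round(em$sensitivity, 3), 0.857)
  expect_equal(round(em$specificity, 3), 0.900)
  expect_equal(round(em$accuracy, 3), 0.891)
  expect_equal(round(em$gm, 3), 0.878)
})

test_that("perfect separation yields accuracy = gm = auc = 1", {
  blobs <- make_blobs(n = 100, p = 3, sep = 6, seed = 3)
  m <- fit_classifier("complement_nb", blobs$X, blobs$y)
  em <- evaluate_model(m, blobs$X, blobs$y)
  expect_equal(em$accuracy, 1)
  expect_equal(em$gm, 1)
  expect_equal(em$auc, 1)
  # confusion identities recomputed independently
  expect_equal(em$accuracy, (em$tp + em$tn) / (em$tp + em$tn + em$fp + em$fn))
  expect_equal(em$gm, sqrt(em$sensitivity * em$specificity), tolerance = 1e-12)
})

test_that("rank AUC agrees with pROC and is invariant to monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(17)
  y <- rbinom(120, 1, 0.4)
  s <- rnorm(120) + 0.8 * y
  ours <- swayrisk:::auc_rank(s, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(swayrisk:::auc_rank(exp(3 * s) + 2, y), ours,
               tolerance = 1e-12)
  # tied scores
  st <- round(s, 1)
  expect_equal(swayrisk:::auc_rank(st, y),
               as.numeric(pROC::auc(pROC::roc(y, st, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("random scores give chance-level AUC", {
  set.seed(5)
  y <- rbinom(200, 1, 0.4)
  s <- rnorm(200)
  expect_lt(abs(swayrisk:::auc_rank(s, y) - 0.5), 0.1)
  expect_error(swayrisk:::auc_rank(s, rep(1, 200)), "single class")
})
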