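# Wrapper fitness, binary metaheuristics and filter baselines.

test_that("sparsity term matches its definition", {
  expect_equal(sparsity_term(rep(TRUE, 124)), 0)
  expect_equal(sparsity_term(c(rep(TRUE, 31), rep(FALSE, 93))), 0.75)
  expect_equal(sparsity_term(c(TRUE, rep(FALSE, 123))), 123 / 124)
})

test_that("fitness combination reproduces the substitution cases", {
  cfg <- fitness_config(w1 = 0.4, w2 = 0.4, w3 = 0.2)
  expect_equal(combine_fitness(1, 1, 0, cfg), 0.8)
  expect_equal(combine_fitness(0.8, 0.9, 0.5, cfg), 0.78)
})

test_that("informative masks out-score noise masks across seeds", {
  wins <- 0
  for (s in 1:10) {
    tab <- small_planted_table(n = 80, n_features = 10, n_informative = 3,
                               effect = 2, seed = s)
    cols <- attr(tab, "feature_cols")
    inf_mask <- cols %in% attr(tab, "informative")
    set.seed(100 + s)
    noise_mask <- rep(FALSE, 10)
    noise_mask[sample(which(!inf_mask), 3)] <- TRUE
    fn <- make_fitness(tab, "criteria_II", fitness_config(seed = s))
    if (fn(inf_mask) > fn(noise_mask)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("with zero sparsity weight, a noise feature moves fitness only within CV noise", {
  tab <- small_planted_table(n = 80, n_features = 10, n_informative = 3,
                             effect = 2, seed = 5)
  cols <- attr(tab, "feature_cols")
  cfg <- fitness_config(w1 = 0.4, w2 = 0.4, w3 = 0, seed = 2)
  fn <- make_fitness(tab, "criteria_II", cfg)
  base <- cols %in% attr(tab, "informative")
  deltas <- sapply(which(!base), function(j) {
    grown <- base
    grown[j] <- TRUE
    abs(fn(grown) - fn(base))
  })
  expect_lt(max(deltas), 0.15)
})

test_that("empty masks are refused by the fitness and repaired by the search", {
  tab <- small_planted_table(seed = 3)
  fn <- make_fitness(tab, "criteria_II", fitness_config(seed = 1))
  expect_error(fn(rep(FALSE, 10)), "empty mask")
  for (alg in list(select_sma, select_hho, select_abc)) {
    res <- alg(tab, "criteria_II", fitness_config(seed = 1), pop = 5,
               epochs = 3, seed = 9)
    expect_gte(sum(res$best_mask), 1)
  }
})

test_that("best-so-far histories are monotone and consistent", {
  tab <- small_planted_table(seed = 7)
  for (alg in list(select_sma, select_hho, select_abc)) {
    res <- alg(tab, "criteria_II", fitness_config(seed = 4), pop = 8,
               epochs = 6, seed = 2)
    expect_length(res$history, 6)
    expect_false(is.unsorted(res$history))
    expect_equal(res$best_fitness, res$history[length(res$history)])
    expect_gt(res$evaluations, 0)
  }
})

test_that("a one-feature search space returns that feature", {
  ft <- planted_feature_table(n = 60, n_features = 2, n_informative = 1,
                              effect = 2, prevalence = 0.4, seed = 2)
  d <- as.data.frame(ft)
  d$f002 <- NULL
  one <- feature_table(d, "f001", character(0), "criteria_II")
  for (alg in list(select_sma, select_hho, select_abc)) {
    res <- alg(one, "criteria_II", fitness_config(seed = 1), pop = 4,
               epochs = 2, seed = 5)
    expect_identical(unname(res$best_mask), TRUE)
  }
})

test_that("selection is reproducible under a fixed seed", {
  tab <- small_planted_table(seed = 11)
  a <- select_sma(tab, "criteria_II", fitness_config(seed = 3), pop = 8,
                  epochs = 5, seed = 21)
  b <- select_sma(tab, "criteria_II", fitness_config(seed = 3), pop = 8,
                  epochs = 5, seed = 21)
  expect_identical(a$best_mask, b$best_mask)
  expect_identical(a$history, b$history)
})

test_that("F-value filter ranks a planted separable feature first", {
  set.seed(6)
  n <- 100
  y <- rep(0:1, each = n / 2)
  d <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(d) <- sprintf("f%02d", 1:8)
  d$f05 <- d$f05 + 3 * y          # strongly separable
  d$criteria_II <- y
  tab <- feature_table(d, sprintf("f%02d", 1:8), character(0), "criteria_II")
  res <- select_filter_baseline(tab, "criteria_II", "f_value", k = 1)
  expect_identical(res$selected_names, "f05")
  expect_identical(res$algorithm, "F-value")

  all_res <- select_filter_baseline(tab, "criteria_II", "mi", k = 8)
  expect_true(all(all_res$best_mask))
  expect_error(select_filter_baseline(tab, "criteria_II", "mi", k = 9), "k must")
})

test_that("a constant feature has zero mutual information", {
  set.seed(1)
  n <- 80
  y <- rbinom(n, 1, 0.4)
  d <- data.frame(f1 = rep(2.5, n), f2 = rnorm(n) + y,
                  criteria_II = y)
  tab <- feature_table(d, c("f1", "f2"), character(0), "criteria_II")
  res <- select_filter_baseline(tab, "criteria_II", "mi", k = 1)
  expect_equal(unname(res$scores["f1"]), 0)
  expect_identical(res$selected_names, "f2")
})

test_that("filter ties break deterministically by column name", {
  n <- 40
  y <- rep(0:1, each = n / 2)
  x <- rnorm(n)
  d <- data.frame(b_dup = x, a_dup = x, criteria_II = y)
  tab <- feature_table(d, c("b_dup", "a_dup"), character(0), "criteria_II")
  res <- select_filter_baseline(tab, "criteria_II", "f_value", k = 1)
  expect_identical(res$selected_names, "a_dup")
})
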