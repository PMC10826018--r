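# Stabilogram parameter extraction: analytic closed forms, independent
# re-implementations, scale homogeneity, and table assembly.

# ---- closed forms --------------------------------------------------------

test_that("sinusoid closed forms hold for the distance measures", {
  tr <- sine_trial(f = 0.5, A = 10, fs = 90, dur = 30)
  dm <- distance_measures(tr$ml, tr$ap, tr$fs)
  expect_lt(abs(dm[["rms_dist_ap"]] - 10 / sqrt(2)) / (10 / sqrt(2)), 0.02)
  expect_lt(abs(dm[["range_ap"]] - 20) / 20, 0.02)
  expect_lt(abs(dm[["mean_dist_ap"]] - 20 / pi) / (20 / pi), 0.02)
  expect_lt(abs(dm[["mean_vel_ap"]] - 20) / 20, 0.02)
  # mean frequency of a sinusoid is its frequency
  mf <- mean_frequency(dm[["mean_vel_ap"]], dm[["mean_dist_ap"]])
  expect_lt(abs(mf - 0.5) / 0.5, 0.02)
})

test_that("circular path closed forms hold", {
  tr <- circle_trial(R = 5, f = 0.5, fs = 90, dur = 30)
  dm <- distance_measures(tr$ml, tr$ap, tr$fs)
  expect_equal(dm[["mean_dist_r"]], 5, tolerance = 1e-9)
  expect_equal(dm[["rms_dist_r"]], 5, tolerance = 1e-9)
  # sway area: revolutions per second x circle area
  sa <- sway_area_per_second(tr$ml, tr$ap, tr$fs)
  expect_lt(abs(sa - 0.5 * pi * 25) / (0.5 * pi * 25), 0.01)
  # radial mean frequency recovers the rotation rate
  mf <- mean_frequency(dm[["mean_vel_r"]], dm[["mean_dist_r"]])
  expect_lt(abs(mf - 0.5) / 0.5, 0.01)
})

test_that("degenerate inputs give zeros or flagged undefined values", {
  z <- rep(0, 100)
  expect_true(all(distance_measures(z, z, 90) == 0))
  expect_equal(ellipse_area_95(z, z), 0)
  expect_equal(sway_area_per_second(z, z, 90), 0)
  expect_true(is.nan(mean_frequency(0, 0)))
  expect_true(is.nan(fractal_dimension(z, z)))
  # pure 1-D motion encloses no area
  t <- seq(0, 10, by = 1 / 90)
  expect_equal(sway_area_per_second(rep(0, length(t)), sin(t), 90), 0)
  # collinear axes give a singular covariance
  x <- rnorm(500)
  expect_equal(ellipse_area_95(x, 2 * x), 0, tolerance = 1e-6)
  expect_error(distance_measures(1, 1, 90), "2 samples")
})

test_that("ellipse area matches the closed form for independent Gaussians", {
  areas <- sapply(1:5, function(s) {
    set.seed(s)
    ellipse_area_95(rnorm(2700, sd = 2), rnorm(2700, sd = 2))
  })
  expect_lt(abs(mean(areas) - 2 * pi * 3 * 4) / (2 * pi * 3 * 4), 0.10)
})

test_that("fractal dimension: straight traversal, scaling invariance, dual oracle", {
  # constant-speed straight line: L = d under the diameter convention
  ml <- seq(0, 10, length.out = 200)
  ap <- rep(0, 200)
  expect_equal(fractal_dimension(ml, ap, convention = "diameter"), 1)

  set.seed(8)
  wml <- cumsum(rnorm(2700))
  wap <- cumsum(rnorm(2700))
  fd <- fractal_dimension(wml, wap)
  expect_equal(fd, oracle_fd_radius(wml, wap), tolerance = 1e-12)
  expect_equal(fractal_dimension(3.7 * wml, 3.7 * wap), fd, tolerance = 1e-9)
})

test_that("spectral features match line-spectrum and Parseval expectations", {
  fs <- 90
  tr <- sine_trial(f = 1, A = 10, fs = fs, dur = 30)
  sf <- spectral_features(tr$ap, fs)
  res <- 0.125 + 1e-9  # frequency resolution of 8-s segments
  expect_lt(abs(sf[["f50"]] - 1), res)
  expect_lt(abs(sf[["f95"]] - 1), res)
  expect_lt(abs(sf[["centroid_freq"]] - 1), res)
  expect_lte(sf[["freq_disp"]], 0.1)
  expect_lt(abs(sf[["total_power"]] - 50) / 50, 0.05)  # A^2/2

  # broadband signal disperses more than a line spectrum
  set.seed(1)
  tr2 <- preprocess_trial(make_trial(ml = rnorm(2700), ap = rnorm(2700)))
  sf2 <- spectral_features(tr2$ap, fs)
  expect_gt(sf2[["freq_disp"]], sf[["freq_disp"]])
  expect_true(sf[["freq_disp"]] >= 0 && sf[["freq_disp"]] <= 1)
  expect_true(sf2[["freq_disp"]] >= 0 && sf2[["freq_disp"]] <= 1)
})

test_that("every formula agrees with its independent re-implementation", {
  set.seed(33)
  for (rep in 1:3) {
    ml <- as.numeric(arima.sim(list(ar = 0.95), 600))
    ap <- as.numeric(arima.sim(list(ar = 0.95), 600))
    ml <- ml - mean(ml)
    ap <- ap - mean(ap)
    expect_equal(distance_measures(ml, ap, 90), oracle_distance(ml, ap, 90),
                 tolerance = 1e-9)
    expect_equal(sway_area_per_second(ml, ap, 90),
                 oracle_sway_area(ml, ap, 90), tolerance = 1e-9)
    expect_equal(ellipse_area_95(ml, ap), oracle_ellipse(ml, ap),
                 tolerance = 1e-9)
    expect_equal(fractal_dimension(ml, ap), oracle_fd_radius(ml, ap),
                 tolerance = 1e-9)
  }
})

# ---- per-trial extraction and table assembly ----------------------------

test_that("extraction yields 31 finite, deterministic, scale-homogeneous values", {
  spec <- cohort_spec(n_participants = 2, seed = 19)
  p <- generate_participants(spec)[1, ]
  tr <- preprocess_trial(generate_sway_trial(p, "N-EO", 1, spec, seed = 3))
  fx <- extract_trial_features(tr)
  expect_identical(names(fx), trial_feature_names)
  expect_length(fx, 31)
  expect_true(all(is.finite(fx)))
  expect_identical(fx, extract_trial_features(tr))

  # doubling the amplitude doubles positional measures, leaves frequency
  # measures unchanged
  tr2 <- tr
  tr2$ml <- 2 * tr$ml
  tr2$ap <- 2 * tr$ap
  fx2 <- extract_trial_features(tr2)
  pos <- grep("dist|range|vel|^mean_dist", trial_feature_names, value = TRUE)
  expect_equal(unname(fx2[pos]), unname(2 * fx[pos]), tolerance = 1e-9)
  expect_equal(fx2[["ellipse_area_95"]], 4 * fx[["ellipse_area_95"]],
               tolerance = 1e-9)
  freq <- c("mean_freq_ml", "mean_freq_ap", "mean_freq_r", "fractal_dim",
            "f50_ml", "f50_ap", "f95_ml", "f95_ap", "centroid_freq_ml",
            "centroid_freq_ap", "freq_disp_ml", "freq_disp_ap")
  expect_equal(unname(fx2[freq]), unname(fx[freq]), tolerance = 1e-9)
})

test_that("feature table has 124 named columns and averages the two trials", {
  spec <- cohort_spec(n_participants = 10, duration = 10, seed = 23)
  co <- generate_cohort(spec)
  ft <- build_feature_table(co$participants, co$trials)
  expect_s3_class(ft, "feature_table")
  expect_equal(nrow(ft), 10)
  expect_length(attr(ft, "feature_cols"), 124)
  expect_false(anyDuplicated(names(ft)) > 0)
  expect_false(anyNA(as.data.frame(ft)[, attr(ft, "feature_cols")]))
  expect_true(all(c("age", "sex", "height", "weight", "bmi",
                    "criteria_I", "criteria_II") %in% names(ft)))

  # averaging definition, checked against per-trial extraction by hand
  p1 <- co$participants$id[1]
  tr_w <- Filter(function(t) t$participant_id == p1 && t$condition == "W-EO",
                 co$trials)
  f1 <- extract_trial_features(preprocess_trial(tr_w[[1]]))
  f2 <- extract_trial_features(preprocess_trial(tr_w[[2]]))
  expect_equal(ft[["weo__rms_dist_ml"]][ft$id == p1],
               unname((f1[["rms_dist_ml"]] + f2[["rms_dist_ml"]]) / 2),
               tolerance = 1e-12)
})

test_that("participants missing a condition are excluded and logged", {
  spec <- cohort_spec(n_participants = 6, duration = 10, seed = 29)
  co <- generate_cohort(spec)
  drop_id <- co$participants$id[3]
  trials <- Filter(function(t)
    !(t$participant_id == drop_id && t$condition == "N-EC"), co$trials)
  ft <- build_feature_table(co$participants, trials)
  expect_equal(nrow(ft), 5)
  excl <- attr(ft, "exclusions")
  expect_equal(excl$id, drop_id)
  expect_match(excl$reason, "N-EC")

  dup <- c(trials, trials[1])
  expect_error(build_feature_table(co$participants, dup), "duplicate")
})

test_that("feature table round-trips through CSV with its sidecar", {
  spec <- cohort_spec(n_participants = 4, duration = 10, seed = 31)
  co <- generate_cohort(spec)
  ft <- build_feature_table(co$participants, co$trials)
  path <- file.path(tempdir(), "ftab.csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(attr(back, "feature_cols"), attr(ft, "feature_cols"))
  expect_equal(as.data.frame(back)[attr(ft, "feature_cols")],
               as.data.frame(ft)[attr(ft, "feature_cols")],
               tolerance = 1e-12)
})
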