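# Synthetic cohort generator: determinism, label calibration, condition
# ordering and trial bookkeeping.

test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(prevalence_faller = 0), "prevalences")
  expect_error(cohort_spec(sampling_rate = 8), "sampling_rate")
  expect_error(cohort_spec(condition_gain = c("W-EO" = 1, "W-EC" = 0.9,
                                              "N-EO" = 1.8, "N-EC" = 2.4)),
               "strictly increasing")
  expect_error(cohort_spec(missing_fraction = 1), "missing_fraction")
})

test_that("participant generation is seeded-deterministic and calibrated", {
  spec <- cohort_spec(n_participants = 200, prevalence_slow_tug = 0.31,
                      seed = 7)
  p1 <- generate_participants(spec)
  p2 <- generate_participants(spec)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 200)
  expect_equal(p1$bmi, round(p1$weight / (p1$height / 100)^2, 2))
  expect_true(all(p1$tug_seconds > 0))

  # realized slow-TUG rate within the binomial 95% CI around 0.31 at n=200:
  # 0.31 +/- 1.96 * sqrt(0.31 * 0.69 / 200) = [0.246, 0.374]
  rate <- mean(p1$tug_seconds >= 10)
  expect_gt(rate, 0.246)
  expect_lt(rate, 0.374)

  # faller prevalence within its binomial 95% CI around 0.228:
  # 0.228 +/- 1.96 * sqrt(0.228 * 0.772 / 200) = [0.170, 0.286]
  frate <- mean(p1$fell_last_year)
  expect_gt(frate, 0.170)
  expect_lt(frate, 0.286)
})

test_that("full label noise decouples fall history from the latent deficit", {
  spec <- cohort_spec(n_participants = 200, label_noise_fall = 1, seed = 11)
  p <- generate_participants(spec)
  r <- cor(p$fell_last_year, p$latent_deficit)
  expect_lt(abs(r), 0.15)
})

test_that("fall label is noisier than the TUG label", {
  spec <- cohort_spec(n_participants = 400, seed = 3)
  p <- generate_participants(spec)
  r_tug <- cor(as.integer(p$tug_seconds >= 10), p$latent_deficit)
  r_fall <- cor(p$fell_last_year, p$latent_deficit)
  expect_gt(r_tug, r_fall)
})

test_that("trial length and count arithmetic hold", {
  spec <- cohort_spec(n_participants = 10, seed = 5)
  p <- generate_participants(spec)[1, ]
  tr <- generate_sway_trial(p, "W-EO", 1, spec, seed = 42)
  expect_equal(length(tr$t), 2700)
  expect_equal(length(tr$ml), length(tr$ap))
  expect_lt(abs(mean(tr$ml)), 1e-9)
  expect_lt(abs(mean(tr$ap)), 1e-9)

  co <- generate_cohort(spec)
  expect_equal(length(co$trials), 80)   # 10 participants x 4 conditions x 2
})

test_that("expected RMS increases along the condition order", {
  spec <- cohort_spec(n_participants = 1, seed = 9)
  p <- generate_participants(spec)[1, ]
  mean_rms <- sapply(stance_conditions, function(cond) {
    mean(sapply(1:50, function(i) {
      tr <- generate_sway_trial(p, cond, 1, spec, seed = 1000 + i)
      sqrt(mean(tr$ml^2))
    }))
  })
  expect_true(all(diff(mean_rms) > 0))
})

test_that("balance_effect = 0 equalizes the risk groups' sway", {
  spec <- cohort_spec(n_participants = 200, balance_effect = 0, seed = 13)
  p <- generate_participants(spec)
  hi <- p[order(-p$latent_deficit)[1:100], ]
  lo <- p[order(p$latent_deficit)[1:100], ]
  rms_of <- function(rows, off) sapply(seq_len(nrow(rows)), function(i) {
    tr <- generate_sway_trial(rows[i, ], "W-EO", 1, spec, seed = off + i)
    sqrt(mean(tr$ml^2))
  })
  ks <- suppressWarnings(ks.test(rms_of(hi, 2000), rms_of(lo, 3000)))
  expect_gt(ks$p.value, 0.01)
})

test_that("missing_fraction removes the hardest condition", {
  spec <- cohort_spec(n_participants = 200, missing_fraction = 0.05, seed = 21)
  co <- generate_cohort(spec)
  conds <- sapply(co$trials, `[[`, "condition")
  n_nec_missing <- 200 - sum(conds == "N-EC") / 2
  # expectation 10; allow binomial spread
  expect_gt(n_nec_missing, 1)
  expect_lt(n_nec_missing, 25)
  expect_equal(sum(conds == "W-EO"), 400)
})

test_that("cohort CSV export is byte-identical across runs", {
  spec <- cohort_spec(n_participants = 4, duration = 5, seed = 17)
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  write_cohort_csv(generate_cohort(spec), d1)
  write_cohort_csv(generate_cohort(spec), d2)
  for (f in c("participants.csv", "trajectories.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  # round trip
  trials <- read_trajectories_csv(file.path(d1, "trajectories.csv"), fs = 90)
  expect_equal(length(trials), 32)
  expect_s3_class(trials[[1]], "sway_trial")
})
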