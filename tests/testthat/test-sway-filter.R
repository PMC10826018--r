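# Zero-phase Butterworth filtering and trial validation.

# Amplitude of a sinusoid at frequency f extracted by least squares on the
# sin/cos basis over the middle of the record (forward-backward filtering
# leaves a small transient within ~1 s of each edge, exactly as any
# zero-phase implementation does).
fit_amplitude <- function(x, f, fs, trim = 150) {
  keep <- (trim + 1):(length(x) - trim)
  t <- (keep - 1) / fs
  x <- x[keep]
  co <- coef(lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t) - 1))
  sqrt(sum(co^2))
}

test_that("DC and constant series pass unchanged", {
  tr <- make_trial(ml = rep(3, 500), ap = rep(-2, 500))
  out <- lowpass_zero_phase(tr)
  expect_equal(out$ml, rep(3, 500), tolerance = 1e-10)
  expect_equal(out$ap, rep(-2, 500), tolerance = 1e-10)
})

test_that("passband sinusoid is preserved with zero lag", {
  fs <- 90
  tr <- sine_trial(f = 1, A = 5, fs = fs)
  out <- lowpass_zero_phase(tr)
  a <- fit_amplitude(out$ap, 1, fs)
  expect_lt(abs(a - 5) / 5, 0.01)
  # zero net phase shift: cross-correlation peak at lag 0
  cc <- ccf(out$ap, tr$ap, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("stopband attenuation matches the squared Butterworth response", {
  fs <- 90
  f_stop <- 15
  tr <- sine_trial(f = f_stop, A = 5, fs = fs)
  out <- lowpass_zero_phase(tr)
  # independent oracle: evaluate the digital transfer function of the
  # 4th-order design at 15 Hz; forward-backward squares it.  (The bilinear
  # transform warps frequencies, so the digital response is stronger than
  # the analog-prototype value 1/(1 + (15/5)^8) = 1.5e-4, which still
  # bounds it from above.)
  bf <- signal::butter(4, 5 / (fs / 2))
  z <- exp(-1i * 2 * pi * f_stop / fs)
  expected <- Mod(sum(bf$b * z^(0:4)) / sum(bf$a * z^(0:4)))^2
  a <- fit_amplitude(out$ap, f_stop, fs)
  expect_lt(abs(a / 5 - expected) / expected, 0.05)
  expect_lt(a / 5, 1 / (1 + (f_stop / 5)^8))
})

test_that("filtering is idempotent for band-limited signals and never adds energy", {
  set.seed(4)
  fs <- 90
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- 3 * sin(2 * pi * 0.4 * t) + sin(2 * pi * 1.1 * t)
  tr <- make_trial(ml = x, ap = rnorm(length(t)))
  once <- lowpass_zero_phase(tr)
  twice <- lowpass_zero_phase(once)
  mid <- 150:2550
  expect_equal(twice$ml[mid], once$ml[mid], tolerance = 1e-5)
  expect_lte(var(once$ap), var(tr$ap) * (1 + 1e-6))
  expect_lte(var(once$ml), var(tr$ml) * (1 + 1e-6))
})

test_that("short series are rejected with a clear error", {
  tr <- make_trial(ml = rnorm(10), ap = rnorm(10))
  expect_error(lowpass_zero_phase(tr), "too short")
})

test_that("demeaning zeroes the axis means and is a no-op on centered data", {
  set.seed(2)
  tr <- make_trial(ml = rnorm(200, mean = 5), ap = rnorm(200, mean = -3))
  out <- demean_trial(tr)
  expect_lt(abs(mean(out$ml)), 1e-9 * sd(out$ml))
  expect_lt(abs(mean(out$ap)), 1e-9 * sd(out$ap))
  again <- demean_trial(out)
  expect_equal(again$ml, out$ml)
  con <- demean_trial(make_trial(ml = rep(7, 50), ap = rep(7, 50)))
  expect_equal(con$ml, rep(0, 50))
})

test_that("validate_trial reports NaNs, duration and sampling violations", {
  spec <- cohort_spec(n_participants = 2, seed = 1)
  p <- generate_participants(spec)[1, ]
  good <- generate_sway_trial(p, "W-EO", 1, spec, seed = 5)
  expect_length(validate_trial(good, spec), 0)

  bad <- good
  bad$ml[10] <- NaN
  expect_length(validate_trial(bad, spec), 1)
  expect_match(validate_trial(bad, spec), "non-finite")

  short <- make_trial(ml = rnorm(900), ap = rnorm(900))  # 10 s at 90 Hz
  expect_match(paste(validate_trial(short, spec), collapse = ";"), "duration")

  jitter <- good
  jitter$t[100] <- jitter$t[100] + 0.003
  expect_match(paste(validate_trial(jitter, spec), collapse = ";"),
               "non-uniform")
})
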