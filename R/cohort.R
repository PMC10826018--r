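# Synthetic cohort generator: participants, trunk-sway trajectories and risk
# labels with the statistical structure the downstream analysis assumes
# (condition-ordered sway amplitude, a latent balance deficit that drives the
# Timed-Up-and-Go time more strongly than the fall-history label, and
# imbalanced label prevalences typical of community-dwelling older adults).

#' Stance conditions in increasing order of difficulty
#'
#' Feet apart / feet together ("wide"/"narrow") crossed with eyes open/closed.
#' @export
stance_conditions <- c("W-EO", "W-EC", "N-EO", "N-EC")

# CSV/column-safe short codes for the four conditions.
condition_codes <- c("W-EO" = "weo", "W-EC" = "wec", "N-EO" = "neo",
                     "N-EC" = "nec")

#' Specification of a synthetic cohort
#'
#' Bundles every knob of the generator. Defaults emulate a community
#' cohort: 22.8% fallers, 30.7% slow-TUG (>= 10 s) prevalence, four
#' stance conditions with strictly increasing sway amplitude, two 30-s
#' trials per condition, and a fall-history label deliberately noisier than
#' the TUG label.
#'
#' @param n_participants number of participants.
#' @param seed master seed for the whole cohort.
#' @param sampling_rate tracker sampling rate in Hz (> 10 Hz).
#' @param duration trial duration in seconds.
#' @param prevalence_slow_tug target fraction with TUG >= 10 s.
#' @param prevalence_faller target fraction reporting a fall in the past year.
#' @param balance_effect ratio scaling how strongly the latent balance
#'   deficit inflates sway amplitude (0 switches the effect off).
#' @param label_noise_fall probability that the fall-history label is drawn
#'   independently of the latent deficit (1 makes the label pure noise).
#' @param condition_gain named amplitude multipliers, strictly increasing
#'   along `stance_conditions`.
#' @param ap_ml_corr correlation of the M-L and A-P noise processes.
#' @param base_amplitude_mm baseline RMS sway amplitude (mm) of a low-risk
#'   participant in the easiest condition.
#' @param missing_fraction fraction of participants missing the hardest
#'   condition (N-EC), to exercise exclusion logic downstream.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 215,
                        seed = 1L,
                        sampling_rate = 90,
                        duration = 30,
                        prevalence_slow_tug = 0.307,
                        prevalence_faller = 0.228,
                        balance_effect = 0.8,
                        label_noise_fall = 0.4,
                        condition_gain = c("W-EO" = 1, "W-EC" = 1.35,
                                           "N-EO" = 1.8, "N-EC" = 2.4),
                        ap_ml_corr = 0.25,
                        base_amplitude_mm = 4,
                        missing_fraction = 0) {
  if (!is_count(n_participants)) stopf("n_participants must be a positive integer")
  if (!is.numeric(sampling_rate) || sampling_rate <= 10) {
    stopf("sampling_rate must exceed 10 Hz (Nyquist above the 5 Hz cutoff)")
  }
  if (!is.numeric(duration) || duration <= 0) stopf("duration must be positive")
  for (p in c(prevalence_slow_tug, prevalence_faller)) {
    if (!is.numeric(p) || p <= 0 || p >= 1) stopf("prevalences must lie in (0,1)")
  }
  if (label_noise_fall < 0 || label_noise_fall > 1) {
    stopf("label_noise_fall must lie in [0,1]")
  }
  if (!identical(names(condition_gain), stance_conditions)) {
    stopf("condition_gain must be named by: %s",
          paste(stance_conditions, collapse = ", "))
  }
  if (any(diff(condition_gain) <= 0)) {
    stopf("condition_gain must be strictly increasing along W-EO < W-EC < N-EO < N-EC")
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stopf("missing_fraction must lie in [0,1)")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    sampling_rate = sampling_rate,
    duration = duration,
    prevalence_slow_tug = prevalence_slow_tug,
    prevalence_faller = prevalence_faller,
    balance_effect = balance_effect,
    label_noise_fall = label_noise_fall,
    condition_gain = condition_gain,
    ap_ml_corr = ap_ml_corr,
    base_amplitude_mm = base_amplitude_mm,
    missing_fraction = missing_fraction
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_participants, "participants,",
      x$sampling_rate, "Hz,", x$duration, "s trials, seed", x$seed, "\n")
  cat("  prevalence: slow TUG", x$prevalence_slow_tug,
      "| fallers", x$prevalence_faller, "\n")
  cat("  condition gains:", paste(sprintf("%s=%.2f", names(x$condition_gain),
                                          x$condition_gain), collapse = " "), "\n")
  invisible(x)
}

#' Generate synthetic participants
#'
#' Draws personal metrics around the marginals typical of community-dwelling
#' cohorts (mean age ~72 y, ~1/3 male), a continuous latent balance deficit,
#' a TUG time that is monotone in the deficit plus noise (calibrated so that
#' `P(TUG >= 10 s)` equals `prevalence_slow_tug` in distribution), and a
#' fall-history label correlated with the deficit but degraded by
#' `label_noise_fall`.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame with one row per participant: id, age, sex (0 female /
#'   1 male), height (cm), weight (kg), bmi, uses_aid, tug_seconds,
#'   fell_last_year, and the hidden latent_deficit retained for ground-truth
#'   tests.
#' @export
generate_participants <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  with_seed(derive_seed(spec$seed, 1), {
    latent <- rnorm(n)
    sex <- rbinom(n, 1, 1 / 3)                       # 1 = male
    height <- ifelse(sex == 1, rnorm(n, 165, 6), rnorm(n, 153, 6.5))
    bmi_draw <- pmax(15, rnorm(n, 24.8, 4.1))
    weight <- round(bmi_draw * (height / 100)^2, 1)
    height <- round(height, 1)
    bmi <- round(weight / (height / 100)^2, 2)
    age <- pmax(60, round(72 + 7 * (0.35 * latent + sqrt(1 - 0.35^2) * rnorm(n))))

    # TUG: log-normal in a standard-normal risk score z correlated 0.8 with
    # the latent deficit; thresholding z at its (1 - prevalence) quantile
    # makes P(TUG >= 10) equal the target prevalence in distribution.
    z_tug <- 0.8 * latent + 0.6 * rnorm(n)
    z0 <- qnorm(1 - spec$prevalence_slow_tug)
    tug <- round(10 * exp(0.30 * (z_tug - z0)), 1)

    # Fall history: weaker latent correlation, further degraded by an
    # independent-noise mixture.
    z_fall <- 0.55 * latent + sqrt(1 - 0.55^2) * rnorm(n)
    informative <- as.integer(z_fall >= qnorm(1 - spec$prevalence_faller))
    noisy <- rbinom(n, 1, spec$prevalence_faller)
    use_noise <- rbinom(n, 1, spec$label_noise_fall) == 1
    fell <- ifelse(use_noise, noisy, informative)

    uses_aid <- rbinom(n, 1, plogis(-2.8 + 1.1 * latent)) == 1

    data.frame(
      id = sprintf("P%03d", seq_len(n)),
      age = age,
      sex = sex,
      height = height,
      weight = weight,
      bmi = bmi,
      uses_aid = uses_aid,
      tug_seconds = tug,
      fell_last_year = as.integer(fell),
      latent_deficit = latent,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate one synthetic sway trial
#'
#' Signal model: Gaussian white noise on both axes (correlation
#' `ap_ml_corr`), shaped by a second-order low-pass Butterworth filter at
#' 1.2 Hz so power concentrates below ~2 Hz, then scaled so the per-axis RMS
#' equals `base_amplitude_mm * condition_gain[condition] *
#' max(0.1, 1 + balance_effect * latent_deficit)` times a small log-normal
#' trial-to-trial jitter; the A-P axis is 25% larger than M-L. Series are
#' demeaned. No physiological model is claimed.
#'
#' @param participant one-row data.frame (or list) with `id` and
#'   `latent_deficit`.
#' @param condition one of [stance_conditions].
#' @param trial_index 1 or 2.
#' @param spec a [cohort_spec()].
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return An object of class `sway_trial`: list with participant_id,
#'   condition, trial, t (s), ml (mm), ap (mm), fs (Hz).
#' @export
generate_sway_trial <- function(participant, condition, trial_index, spec,
                                seed = NULL) {
  if (!condition %in% stance_conditions) {
    stopf("unknown condition '%s'", condition)
  }
  gen <- function() {
    fs <- spec$sampling_rate
    n <- round(spec$duration * fs)
    risk <- max(0.1, 1 + spec$balance_effect * participant$latent_deficit)
    amp <- spec$base_amplitude_mm * spec$condition_gain[[condition]] * risk
    jitter <- exp(rnorm(1, 0, 0.1))
    rho <- spec$ap_ml_corr

    e_ml <- rnorm(n)
    e_ap <- rho * e_ml + sqrt(1 - rho^2) * rnorm(n)
    bf <- signal::butter(2, min(0.95, 1.2 / (fs / 2)))
    shape <- function(e) {
      y <- as.numeric(signal::filter(bf$b, bf$a, e,
                                     init.x = rep(e[1], length(bf$b) - 1),
                                     init.y = rep(e[1], length(bf$a) - 1)))
      y - mean(y)
    }
    ml <- shape(e_ml)
    ap <- shape(e_ap)
    ml <- ml / stats::sd(ml) * amp * jitter
    ap <- ap / stats::sd(ap) * amp * jitter * 1.25
    structure(list(
      participant_id = participant$id,
      condition = condition,
      trial = as.integer(trial_index),
      t = (seq_len(n) - 1) / fs,
      ml = ml - mean(ml),
      ap = ap - mean(ap),
      fs = fs
    ), class = "sway_trial")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' @export
print.sway_trial <- function(x, ...) {
  cat(sprintf("<sway_trial> %s %s trial %d: %d samples @ %g Hz, RMS ml=%.2f ap=%.2f mm\n",
              x$participant_id, x$condition, x$trial, length(x$t), x$fs,
              sqrt(mean(x$ml^2)), sqrt(mean(x$ap^2))))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Participants plus 4 conditions x 2 trials per participant (8 bi-axis
#' trajectories each). A fraction `spec$missing_fraction` of participants is
#' marked as unable to complete the hardest condition (N-EC) and lacks those
#' two trials, to exercise downstream exclusion logic.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `sway_cohort` with elements `participants`
#'   (data.frame) and `trials` (list of `sway_trial`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  participants <- generate_participants(spec)
  n <- nrow(participants)
  missing_nec <- with_seed(derive_seed(spec$seed, 2),
                           runif(n) < spec$missing_fraction)
  trials <- list()
  for (i in seq_len(n)) {
    p <- participants[i, ]
    for (ci in seq_along(stance_conditions)) {
      cond <- stance_conditions[ci]
      if (cond == "N-EC" && missing_nec[i]) next
      for (tr in 1:2) {
        salt <- i * 17 + ci * 3 + tr
        trials[[length(trials) + 1]] <- generate_sway_trial(
          p, cond, tr, spec, seed = derive_seed(spec$seed, 100 + salt))
      }
    }
  }
  structure(list(participants = participants, trials = trials, spec = spec),
            class = "sway_cohort")
}

#' @export
print.sway_cohort <- function(x, ...) {
  cat("<sway_cohort>", nrow(x$participants), "participants,",
      length(x$trials), "trials\n")
  cat(sprintf("  fallers: %.1f%%  slow TUG (>=10 s): %.1f%%\n",
              100 * mean(x$participants$fell_last_year),
              100 * mean(x$participants$tug_seconds >= 10)))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' `participants.csv` holds one row per participant; `trajectories.csv` is
#' long-form with columns participant_id, condition, trial, t, ml_mm, ap_mm.
#' Output is byte-identical across runs for a fixed cohort seed.
#'
#' @param cohort a `sway_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pf <- file.path(dir, "participants.csv")
  tf <- file.path(dir, "trajectories.csv")
  utils::write.csv(cohort$participants, pf, row.names = FALSE)
  traj <- do.call(rbind, lapply(cohort$trials, function(tr) {
    data.frame(participant_id = tr$participant_id, condition = tr$condition,
               trial = tr$trial, t = tr$t, ml_mm = tr$ml, ap_mm = tr$ap,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(traj, tf, row.names = FALSE)
  invisible(c(participants = pf, trajectories = tf))
}

#' Read sway trials from a long-form trajectory CSV
#'
#' @param path path to a CSV written by [write_cohort_csv()].
#' @param fs sampling rate (Hz); if `NULL`, inferred from the time column.
#' @return list of `sway_trial` objects.
#' @export
read_trajectories_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stopf("trajectory file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "condition", "trial", "t", "ml_mm", "ap_mm")
  if (!all(needed %in% names(d))) {
    stopf("trajectory CSV must have columns: %s", paste(needed, collapse = ", "))
  }
  keys <- interaction(d$participant_id, d$condition, d$trial, drop = TRUE)
  lapply(split(d, keys), function(g) {
    g <- g[order(g$t), ]
    rate <- fs %||% (1 / stats::median(diff(g$t)))
    structure(list(participant_id = g$participant_id[1],
                   condition = g$condition[1], trial = g$trial[1],
                   t = g$t, ml = g$ml_mm, ap = g$ap_mm, fs = rate),
              class = "sway_trial")
  })
}

#' Read participants from CSV
#' @param path path to `participants.csv`.
#' @return data.frame of participants.
#' @export
read_participants_csv <- function(path) {
  if (!file.exists(path)) stopf("participant file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Synthetic feature table with planted informative columns
#'
#' Builds a participants-by-features table in the shape produced by
#' [build_feature_table()] but with known ground truth: `n_informative`
#' columns are shifted by `effect` standard deviations in the positive
#' class, with alternating shift signs (a balance deficit raises distance
#' and area measures while moving frequency measures in either direction),
#' and the rest are pure noise. The default effect size puts the
#' Bayes-level AUC of the informative set near 0.94, the performance regime
#' reported for posturographic classification of slow-TUG status. Used to
#' test whether wrapper selection recovers the informative set.
#'
#' @param n rows (participants).
#' @param n_features total feature columns (default 124).
#' @param n_informative number of informative columns.
#' @param effect class-mean separation of informative columns, in SD units.
#' @param prevalence positive-class prevalence of the `criteria_II` label.
#' @param seed seed.
#' @return A `feature_table` with attribute `informative` holding the names
#'   of the planted columns.
#' @export
planted_feature_table <- function(n = 300, n_features = 124, n_informative = 5,
                                  effect = 1.25, prevalence = 0.307, seed = 1L) {
  stopifnot(n_informative >= 1, n_informative < n_features)
  with_seed(seed, {
    y <- rbinom(n, 1, prevalence)
    # guarantee both classes
    if (sum(y) < 3) y[sample(which(y == 0), 3)] <- 1L
    if (sum(1 - y) < 3) y[sample(which(y == 1), 3)] <- 0L
    X <- matrix(rnorm(n * n_features), n, n_features)
    inf_idx <- sort(sample(n_features, n_informative))
    sgn <- rep(c(1, -1), length.out = n_informative)
    X[, inf_idx] <- X[, inf_idx] +
      matrix(sgn * effect, n, n_informative, byrow = TRUE) * y
    cols <- sprintf("f%03d", seq_len(n_features))
    df <- as.data.frame(X)
    names(df) <- cols
    df$criteria_II <- as.integer(y)
    ft <- feature_table(df, feature_cols = cols,
                        personal_cols = character(0),
                        label_cols = "criteria_II")
    attr(ft, "informative") <- cols[inf_idx]
    ft
  })
}
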