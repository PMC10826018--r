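# Stabilogram parameters: the 31 per-trial measures (time-domain distance,
# area, hybrid and frequency-domain groups), trial averaging per condition,
# and assembly of the participants x features table. Formula definitions
# follow the standard center-of-pressure analysis literature.

#' Names of the 31 per-trial stabilogram parameters
#'
#' Grouped as distance (5 measures x M-L/A-P/radius), area (95% confidence
#' ellipse), hybrid (sway area per second, mean frequency x 3, fractal
#' dimension) and frequency (5 spectral measures x M-L/A-P).
#' @export
trial_feature_names <- c(
  "mean_dist_ml", "mean_dist_ap", "mean_dist_r",
  "max_dist_ml", "max_dist_ap", "max_dist_r",
  "rms_dist_ml", "rms_dist_ap", "rms_dist_r",
  "range_ml", "range_ap", "range_r",
  "mean_vel_ml", "mean_vel_ap", "mean_vel_r",
  "ellipse_area_95",
  "sway_area_per_sec",
  "mean_freq_ml", "mean_freq_ap", "mean_freq_r",
  "fractal_dim",
  "total_power_ml", "total_power_ap",
  "f50_ml", "f50_ap",
  "f95_ml", "f95_ap",
  "centroid_freq_ml", "centroid_freq_ap",
  "freq_disp_ml", "freq_disp_ap"
)

#' Feature extraction configuration
#'
#' @param filter a [filter_config()] applied before extraction.
#' @param f_const F-statistic constant of the 95% confidence ellipse
#'   (large-sample F(0.05; 2, n-2) = 3.00).
#' @param fd_convention normalization distance of the fractal dimension:
#'   `"radius"` (max distance from the mean point) or `"diameter"` (max
#'   pairwise distance on the path).
#' @param psd_seg_sec Welch segment length in seconds (8 s gives 0.125 Hz
#'   resolution on 30-s records, fine enough to keep line-spectrum
#'   dispersion small while still averaging several segments).
#' @param psd_overlap Welch segment overlap fraction.
#' @param band spectral analysis band in Hz (matched to the 5-Hz filter).
#' @return object of class `feature_config`.
#' @export
feature_config <- function(filter = filter_config(), f_const = 3.0,
                           fd_convention = c("radius", "diameter"),
                           psd_seg_sec = 8, psd_overlap = 0.5,
                           band = c(0.15, 5)) {
  fd_convention <- match.arg(fd_convention)
  structure(list(filter = filter, f_const = f_const,
                 fd_convention = fd_convention, psd_seg_sec = psd_seg_sec,
                 psd_overlap = psd_overlap, band = band),
            class = "feature_config")
}

#' Time-domain distance measures
#'
#' For demeaned axes `ml`, `ap` and the radial series
#' `r[i] = sqrt(ml[i]^2 + ap[i]^2)`: mean distance (mean absolute deviation
#' for axes, mean radius), maximal distance, RMS distance, range (max - min
#' per axis; maximal radius for the radial series) and mean velocity (path
#' length over duration per axis, planar path length for the radial series).
#'
#' @param ml,ap demeaned displacement series (mm).
#' @param fs sampling rate (Hz).
#' @return named numeric vector of 15 values (mm, mm/s).
#' @export
distance_measures <- function(ml, ap, fs) {
  n <- length(ml)
  if (n < 2 || length(ap) != n) stopf("need >= 2 samples on both axes")
  r <- sqrt(ml^2 + ap^2)
  dur <- (n - 1) / fs
  c(
    mean_dist_ml = mean(abs(ml)),
    mean_dist_ap = mean(abs(ap)),
    mean_dist_r = mean(r),
    max_dist_ml = max(abs(ml)),
    max_dist_ap = max(abs(ap)),
    max_dist_r = max(r),
    rms_dist_ml = sqrt(mean(ml^2)),
    rms_dist_ap = sqrt(mean(ap^2)),
    rms_dist_r = sqrt(mean(r^2)),
    range_ml = max(ml) - min(ml),
    range_ap = max(ap) - min(ap),
    range_r = max(r),
    mean_vel_ml = sum(abs(diff(ml))) / dur,
    mean_vel_ap = sum(abs(diff(ap))) / dur,
    mean_vel_r = sum(sqrt(diff(ml)^2 + diff(ap)^2)) / dur
  )
}

#' 95% confidence ellipse area
#'
#' `2 * pi * F * sqrt(s_ap^2 * s_ml^2 - s_apml^2)` with sample (co)variances
#' and F = 3.00 (large-sample F(0.05; 2, n-2)). Degenerate (near-singular)
#' covariance yields 0 rather than an error.
#'
#' @param ml,ap demeaned axes (mm).
#' @param f_const the F constant.
#' @return area in mm^2.
#' @export
ellipse_area_95 <- function(ml, ap, f_const = 3.0) {
  disc <- stats::var(ml) * stats::var(ap) - stats::cov(ml, ap)^2
  if (!is.finite(disc) || disc <= 0) return(0)
  2 * pi * f_const * sqrt(disc)
}

#' Sway area per second
#'
#' Sum of the triangle areas swept by the trajectory about the mean point,
#' per unit time: `(1 / (2 * T)) * sum(|ap[i+1] * ml[i] - ap[i] * ml[i+1]|)`.
#'
#' @param ml,ap demeaned axes (mm).
#' @param fs sampling rate (Hz).
#' @return mm^2 per second.
#' @export
sway_area_per_second <- function(ml, ap, fs) {
  n <- length(ml)
  if (n < 2) return(0)
  dur <- (n - 1) / fs
  sum(abs(ap[-1] * ml[-n] - ap[-n] * ml[-1])) / (2 * dur)
}

#' Mean frequency
#'
#' Frequency of a sinusoid (or circular path, for the radial series) whose
#' mean distance and mean velocity match the observed values:
#' `MFREQ = MVELO / (2 * pi * MDIST)`. Zero motion (MDIST = 0) yields `NaN`,
#' flagged downstream by the undefined-value policy.
#'
#' @param mean_velocity mean velocity (mm/s).
#' @param mean_dist mean distance (mm).
#' @return frequency in Hz.
#' @export
mean_frequency <- function(mean_velocity, mean_dist) {
  if (mean_dist <= 0) return(NaN)
  mean_velocity / (2 * pi * mean_dist)
}

#' Fractal dimension of the planar sway path
#'
#' `FD = log(N) / log(N * d / L)` with N samples, L the total planar path
#' length and d a normalizing extent: the maximal distance from the mean
#' point (`"radius"`, default) or the maximal pairwise distance on the path
#' (`"diameter"`). Zero path length yields `NaN`.
#'
#' @param ml,ap displacement axes (mm).
#' @param convention `"radius"` or `"diameter"`.
#' @return unitless fractal dimension.
#' @export
fractal_dimension <- function(ml, ap, convention = c("radius", "diameter")) {
  convention <- match.arg(convention)
  n <- length(ml)
  L <- sum(sqrt(diff(ml)^2 + diff(ap)^2))
  if (L <= 0) return(NaN)
  if (convention == "radius") {
    cx <- ml - mean(ml)
    cy <- ap - mean(ap)
    d <- max(sqrt(cx^2 + cy^2))
  } else {
    # diameter of the point set = diameter of its convex hull
    h <- grDevices::chull(ml, ap)
    hx <- ml[h]; hy <- ap[h]
    d <- sqrt(max(outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2))
  }
  if (d <= 0) return(NaN)
  log(n) / log(n * d / L)
}

#' Welch power spectral density estimate
#'
#' Hann-windowed, linearly detrended, overlapping segments; one-sided PSD
#' scaled so that the integral over frequency equals the signal variance
#' (Parseval). Stable on 30-s records with ~8-s segments at 50% overlap.
#'
#' @param x series.
#' @param fs sampling rate (Hz).
#' @param seg_sec segment length in seconds.
#' @param overlap overlap fraction in `[0,1)`.
#' @return list with `freq` (Hz) and `psd` (units^2/Hz).
#' @export
welch_psd <- function(x, fs, seg_sec = 8, overlap = 0.5) {
  n <- length(x)
  nseg <- min(n, max(8, round(seg_sec * fs)))
  step <- max(1, floor(nseg * (1 - overlap)))
  starts <- seq(1, n - nseg + 1, by = step)
  k <- seq_len(nseg) - 1
  w <- 0.5 * (1 - cos(2 * pi * k / (nseg - 1)))       # Hann
  scale <- fs * sum(w^2)
  tt <- k - mean(k)
  stt <- sum(tt^2)
  nfreq <- floor(nseg / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- seg - mean(seg) - tt * (sum(tt * seg) / stt)  # linear detrend
    X <- stats::fft(seg * w)[seq_len(nfreq)]
    p <- (Mod(X)^2) / scale
    # one-sided: double everything except DC (and Nyquist when nseg even)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nseg, psd = acc / length(starts))
}

#' Frequency-domain measures of one axis
#'
#' Spectral moments `mu_k = sum(f^k * P(f) * df)` over the analysis band:
#' total power (`mu_0`), 50% and 95% power frequencies (smallest frequency
#' whose cumulative band power reaches 50%/95%), centroid frequency
#' `sqrt(mu_2 / mu_0)` and frequency dispersion
#' `sqrt(1 - mu_1^2 / (mu_0 * mu_2))` (0 for a pure line spectrum).
#'
#' @param x filtered, demeaned series.
#' @param fs sampling rate (Hz).
#' @param band analysis band `c(lo, hi)` in Hz.
#' @param seg_sec,overlap Welch settings, see [welch_psd()].
#' @return named numeric vector: total_power, f50, f95, centroid_freq,
#'   freq_disp.
#' @export
spectral_features <- function(x, fs, band = c(0.15, 5), seg_sec = 8,
                              overlap = 0.5) {
  est <- welch_psd(x, fs, seg_sec = seg_sec, overlap = overlap)
  sel <- est$freq >= band[1] & est$freq <= band[2]
  f <- est$freq[sel]
  P <- est$psd[sel]
  df <- est$freq[2] - est$freq[1]
  m0 <- sum(P) * df
  if (m0 <= 0) {
    return(c(total_power = 0, f50 = NaN, f95 = NaN, centroid_freq = NaN,
             freq_disp = NaN))
  }
  m1 <- sum(f * P) * df
  m2 <- sum(f^2 * P) * df
  cum <- cumsum(P) / sum(P)
  c(total_power = m0,
    f50 = f[which(cum >= 0.50)[1]],
    f95 = f[which(cum >= 0.95)[1]],
    centroid_freq = sqrt(m2 / m0),
    freq_disp = sqrt(max(0, 1 - m1^2 / (m0 * m2))))
}

#' Extract the 31 stabilogram parameters from one preprocessed trial
#'
#' The trial must already be filtered and demeaned (see
#' [preprocess_trial()]). Deterministic: the same trial always yields the
#' same values.
#'
#' @param trial a preprocessed `sway_trial`.
#' @param cfg a [feature_config()].
#' @return named numeric vector of length 31 (names = [trial_feature_names]).
#' @export
extract_trial_features <- function(trial, cfg = feature_config()) {
  ml <- trial$ml
  ap <- trial$ap
  fs <- trial$fs
  dm <- distance_measures(ml, ap, fs)
  out <- c(
    dm,
    ellipse_area_95 = ellipse_area_95(ml, ap, cfg$f_const),
    sway_area_per_sec = sway_area_per_second(ml, ap, fs),
    mean_freq_ml = mean_frequency(dm[["mean_vel_ml"]], dm[["mean_dist_ml"]]),
    mean_freq_ap = mean_frequency(dm[["mean_vel_ap"]], dm[["mean_dist_ap"]]),
    mean_freq_r = mean_frequency(dm[["mean_vel_r"]], dm[["mean_dist_r"]]),
    fractal_dim = fractal_dimension(ml, ap, cfg$fd_convention)
  )
  sml <- spectral_features(ml, fs, cfg$band, cfg$psd_seg_sec, cfg$psd_overlap)
  sap <- spectral_features(ap, fs, cfg$band, cfg$psd_seg_sec, cfg$psd_overlap)
  out <- c(out,
           total_power_ml = sml[["total_power"]],
           total_power_ap = sap[["total_power"]],
           f50_ml = sml[["f50"]], f50_ap = sap[["f50"]],
           f95_ml = sml[["f95"]], f95_ap = sap[["f95"]],
           centroid_freq_ml = sml[["centroid_freq"]],
           centroid_freq_ap = sap[["centroid_freq"]],
           freq_disp_ml = sml[["freq_disp"]],
           freq_disp_ap = sap[["freq_disp"]])
  out[trial_feature_names]
}

#' Construct a feature table
#'
#' A data.frame carrying the posturographic feature columns, the personal
#' metric columns and the binary label columns, with the roles recorded as
#' attributes so downstream stages (normalization, selection, fitting) can
#' address them by role.
#'
#' @param df data.frame.
#' @param feature_cols names of posturographic feature columns.
#' @param personal_cols names of personal metric columns.
#' @param label_cols names of binary label columns.
#' @return object of class `feature_table` (a data.frame).
#' @export
feature_table <- function(df, feature_cols, personal_cols = character(0),
                          label_cols) {
  miss <- setdiff(c(feature_cols, personal_cols, label_cols), names(df))
  if (length(miss)) stopf("columns missing from table: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(names(df))) stopf("column names must be unique")
  structure(df, feature_cols = feature_cols, personal_cols = personal_cols,
            label_cols = label_cols,
            class = c("feature_table", "data.frame"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table>", nrow(x), "participants x",
      length(attr(x, "feature_cols")), "posturographic +",
      length(attr(x, "personal_cols")), "personal features;",
      "labels:", paste(attr(x, "label_cols"), collapse = ", "), "\n")
  invisible(x)
}

#' Build the participants x features table from raw trials
#'
#' Each trial is filtered, demeaned and reduced to 31 parameters; the two
#' trials of each stance condition are averaged; the four conditions give
#' 124 posturographic columns named `<condition>__<parameter>` (condition
#' codes weo, wec, neo, nec). Personal metrics (age, sex, height, weight,
#' bmi) and both risk labels (`criteria_I` = fall in past year,
#' `criteria_II` = TUG >= 10 s) are attached. Participants missing any
#' condition are excluded and recorded in the `exclusions` attribute.
#'
#' @param participants data.frame from [generate_participants()] (or read
#'   from CSV).
#' @param trials list of `sway_trial` objects.
#' @param cfg a [feature_config()].
#' @return a `feature_table` with attributes `exclusions` (data.frame) and
#'   the column roles.
#' @export
build_feature_table <- function(participants, trials, cfg = feature_config()) {
  keys <- vapply(trials, function(tr)
    paste(tr$participant_id, tr$condition, tr$trial, sep = "|"), "")
  if (anyDuplicated(keys)) {
    stopf("duplicate (participant, condition, trial) keys in trial list")
  }
  by_participant <- split(trials, vapply(trials, `[[`, "", "participant_id"))

  feat_names <- as.vector(t(outer(unname(condition_codes),
                                  trial_feature_names,
                                  function(a, b) paste0(a, "__", b))))
  rows <- list()
  excl <- list()
  for (pid in participants$id) {
    ptrials <- by_participant[[pid]]
    conds <- vapply(ptrials %||% list(), `[[`, "", "condition")
    have <- vapply(stance_conditions, function(cn) sum(conds == cn), 0L)
    if (any(have < 2)) {
      missing_conds <- stance_conditions[have < 2]
      excl[[length(excl) + 1]] <- data.frame(
        id = pid, reason = paste("missing condition:",
                                 paste(missing_conds, collapse = ", ")),
        stringsAsFactors = FALSE)
      next
    }
    vals <- numeric(0)
    for (cn in stance_conditions) {
      ts <- ptrials[conds == cn]
      fx <- vapply(ts, function(tr)
        extract_trial_features(preprocess_trial(tr, cfg$filter), cfg),
        numeric(length(trial_feature_names)))
      avg <- rowMeans(fx)
      names(avg) <- paste0(condition_codes[[cn]], "__", trial_feature_names)
      vals <- c(vals, avg)
    }
    rows[[pid]] <- vals[feat_names]
  }
  if (!length(rows)) stopf("no participant has the complete 4 x 2 trial set")
  mat <- do.call(rbind, rows)
  kept <- participants[match(rownames(mat), participants$id), ]
  df <- data.frame(id = kept$id, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$age <- kept$age
  df$sex <- kept$sex
  df$height <- kept$height
  df$weight <- kept$weight
  df$bmi <- kept$bmi
  df$criteria_I <- as.integer(kept$fell_last_year)
  df$criteria_II <- as.integer(kept$tug_seconds >= 10)
  rownames(df) <- NULL
  ft <- feature_table(df, feature_cols = feat_names,
                      personal_cols = c("age", "sex", "height", "weight", "bmi"),
                      label_cols = c("criteria_I", "criteria_II"))
  attr(ft, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = character(0), reason = character(0))
  ft
}

#' Write a feature table to CSV with a JSON sidecar
#'
#' The sidecar records the extraction configuration, the column roles and
#' the exclusion log so a table can be audited and re-read losslessly.
#'
#' @param ft a `feature_table`.
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return invisibly, the two paths.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE)
  meta <- list(
    feature_cols = attr(ft, "feature_cols"),
    personal_cols = attr(ft, "personal_cols"),
    label_cols = attr(ft, "label_cols"),
    exclusions = attr(ft, "exclusions")
  )
  mpath <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, mpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(table = path, meta = mpath))
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path (expects `<path>.meta.json` alongside).
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("feature table not found: %s", path)
  mpath <- paste0(path, ".meta.json")
  if (!file.exists(mpath)) stopf("sidecar not found: %s", mpath)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  ft <- feature_table(df, feature_cols = as.character(unlist(meta$feature_cols)),
                      personal_cols = as.character(unlist(meta$personal_cols)),
                      label_cols = as.character(unlist(meta$label_cols)))
  attr(ft, "exclusions") <- meta$exclusions
  ft
}
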