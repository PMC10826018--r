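# Independent naive re-implementations (deliberately simple, loop-based)
# used as dual oracles for the stabilogram formulas.

# ---- independent naive oracles (deliberately simple, loop-based) --------

oracle_distance <- function(ml, ap, fs) {
  n <- length(ml)
  r <- numeric(n)
  for (i in seq_len(n)) r[i] <- sqrt(ml[i]^2 + ap[i]^2)
  dur <- (n - 1) / fs
  path_ml <- path_ap <- path_r <- 0
  for (i in 2:n) {
    path_ml <- path_ml + abs(ml[i] - ml[i - 1])
    path_ap <- path_ap + abs(ap[i] - ap[i - 1])
    path_r <- path_r + sqrt((ml[i] - ml[i - 1])^2 + (ap[i] - ap[i - 1])^2)
  }
  c(mean_dist_ml = mean(abs(ml)), mean_dist_ap = mean(abs(ap)),
    mean_dist_r = mean(r), max_dist_ml = max(abs(ml)),
    max_dist_ap = max(abs(ap)), max_dist_r = max(r),
    rms_dist_ml = sqrt(sum(ml^2) / n), rms_dist_ap = sqrt(sum(ap^2) / n),
    rms_dist_r = sqrt(sum(r^2) / n), range_ml = max(ml) - min(ml),
    range_ap = max(ap) - min(ap), range_r = max(r),
    mean_vel_ml = path_ml / dur, mean_vel_ap = path_ap / dur,
    mean_vel_r = path_r / dur)
}

oracle_sway_area <- function(ml, ap, fs) {
  n <- length(ml)
  acc <- 0
  for (i in 1:(n - 1)) {
    acc <- acc + abs(ap[i + 1] * ml[i] - ap[i] * ml[i + 1])
  }
  acc / (2 * (n - 1) / fs)
}

oracle_fd_radius <- function(ml, ap) {
  n <- length(ml)
  L <- 0
  for (i in 2:n) L <- L + sqrt((ml[i] - ml[i - 1])^2 + (ap[i] - ap[i - 1])^2)
  cx <- ml - mean(ml)
  cy <- ap - mean(ap)
  d <- 0
  for (i in seq_len(n)) d <- max(d, sqrt(cx[i]^2 + cy[i]^2))
  log(n) / log(n * d / L)
}

oracle_ellipse <- function(ml, ap, f_const = 3) {
  s2ml <- sum((ml - mean(ml))^2) / (length(ml) - 1)
  s2ap <- sum((ap - mean(ap))^2) / (length(ap) - 1)
  sml_ap <- sum((ml - mean(ml)) * (ap - mean(ap))) / (length(ml) - 1)
  2 * pi * f_const * sqrt(s2ap * s2ml - sml_ap^2)
}

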