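# Shared fixtures, built in code at test time.

# A sway_trial wrapping given axis series.
make_trial <- function(ml, ap, fs = 90, id = "T01", condition = "W-EO",
                       trial = 1L) {
  structure(list(participant_id = id, condition = condition,
                 trial = trial, t = (seq_along(ml) - 1) / fs,
                 ml = ml, ap = ap, fs = fs),
            class = "sway_trial")
}

sine_trial <- function(f = 0.5, A = 10, fs = 90, dur = 30, axis = "ap") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  s <- A * sin(2 * pi * f * t)
  if (axis == "ap") make_trial(ml = rep(0, length(t)), ap = s, fs = fs)
  else make_trial(ml = s, ap = rep(0, length(t)), fs = fs)
}

circle_trial <- function(R = 5, f = 0.5, fs = 90, dur = 30) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  make_trial(ml = R * cos(2 * pi * f * t), ap = R * sin(2 * pi * f * t),
             fs = fs)
}

# Two Gaussian blobs, class-separated on every feature with alternating
# shift signs; linearly separable for sep large. Returns list(X, y) with X
# min-max normalized to [0,1].
make_blobs <- function(n = 120, p = 4, sep = 4, prev = 0.5, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, prev)
  while (length(unique(y)) < 2) y <- rbinom(n, 1, prev)
  sgn <- rep(c(1, -1), length.out = p)
  X <- matrix(rnorm(n * p), n, p) + outer(y, sgn) * sep
  X <- apply(X, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  colnames(X) <- paste0("x", seq_len(p))
  list(X = X, y = y)
}

# Small normalized feature_table with a few informative columns, for fast
# wrapper/fitness tests.
small_planted_table <- function(n = 60, n_features = 10, n_informative = 3,
                                effect = 2, seed = 1) {
  ft <- planted_feature_table(n = n, n_features = n_features,
                              n_informative = n_informative, effect = effect,
                              prevalence = 0.4, seed = seed)
  cols <- attr(ft, "feature_cols")
  d <- as.data.frame(ft)
  d[cols] <- lapply(d[cols], function(v) (v - min(v)) / (max(v) - min(v)))
  out <- feature_table(d, cols, character(0), "criteria_II")
  attr(out, "informative") <- attr(ft, "informative")
  out
}
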