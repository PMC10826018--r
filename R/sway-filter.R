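# Preprocessing of raw sway trials: zero-phase Butterworth low-pass
# filtering, demeaning, and validity checks.

#' Low-pass filter configuration
#'
#' Fourth-order zero-phase Butterworth low-pass with a 5-Hz cutoff, realized
#' as forward-backward filtering (so the effective magnitude response is the
#' squared single-pass response). Edges are handled by odd-reflection padding
#' of `padlen` samples combined with steady-state initial filter conditions,
#' which removes start-up transients even with a short pad.
#'
#' @param order filter order (>= 1).
#' @param cutoff cutoff frequency in Hz.
#' @param padlen reflection pad length per edge; default `3 * order`.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(order = 4, cutoff = 5, padlen = NULL) {
  if (!is_count(order)) stopf("filter order must be a positive integer")
  if (!is.numeric(cutoff) || cutoff <= 0) stopf("cutoff must be positive")
  padlen <- padlen %||% (3L * order)
  structure(list(order = as.integer(order), cutoff = cutoff,
                 padlen = as.integer(padlen), mode = "zero-phase"),
            class = "filter_config")
}

# One-pass IIR filter with steady-state initial conditions for a unit-DC-gain
# filter: past inputs and outputs seeded with the first sample, so a constant
# signal passes through exactly.
iir_steady <- function(b, a, x) {
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1),
                            init.y = rep(x[1], length(a) - 1)))
}

# Zero-phase Butterworth low-pass of a single series.
butter_filtfilt <- function(x, fs, cfg) {
  if (cfg$cutoff >= fs / 2) {
    stopf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cfg$cutoff, fs / 2)
  }
  n <- length(x)
  pad <- cfg$padlen
  if (n <= pad + 1) {
    stopf("series too short (%d samples) for edge padding of %d", n, pad)
  }
  bf <- signal::butter(cfg$order, cfg$cutoff / (fs / 2))
  # odd (point-symmetric) reflection about the end samples
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(front, x, back)
  y <- iir_steady(bf$b, bf$a, xp)
  y <- rev(iir_steady(bf$b, bf$a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Apply the zero-phase low-pass filter to a sway trial
#'
#' Both axes are filtered identically; passband gain is ~1 and the net phase
#' shift is zero.
#'
#' @param trial a `sway_trial`.
#' @param cfg a [filter_config()].
#' @return The filtered `sway_trial`.
#' @export
lowpass_zero_phase <- function(trial, cfg = filter_config()) {
  stopifnot(inherits(trial, "sway_trial"))
  trial$ml <- butter_filtfilt(trial$ml, trial$fs, cfg)
  trial$ap <- butter_filtfilt(trial$ap, trial$fs, cfg)
  trial
}

#' Remove the per-axis mean of a sway trial
#'
#' Positional sway measures are defined about the mean point, so both axes
#' are re-referenced to zero mean.
#'
#' @param trial a `sway_trial`.
#' @return The demeaned `sway_trial`.
#' @export
demean_trial <- function(trial) {
  stopifnot(inherits(trial, "sway_trial"))
  trial$ml <- trial$ml - mean(trial$ml)
  trial$ap <- trial$ap - mean(trial$ap)
  trial
}

#' Validate a sway trial against a cohort specification
#'
#' Reporting operation: returns a character vector of violations (empty if
#' the trial is valid). Checks equal axis/time lengths, absence of
#' non-finite values, uniform sampling, and duration within one sample of
#' the specified duration.
#'
#' @param trial a `sway_trial`.
#' @param spec a [cohort_spec()] (or any list with `sampling_rate` and
#'   `duration`).
#' @return character vector of violation messages.
#' @export
validate_trial <- function(trial, spec) {
  v <- character(0)
  n <- length(trial$t)
  if (length(trial$ml) != n || length(trial$ap) != n) {
    v <- c(v, "axis/time vectors differ in length")
    return(v)
  }
  if (anyNA(trial$ml) || anyNA(trial$ap) ||
      any(!is.finite(trial$ml)) || any(!is.finite(trial$ap))) {
    v <- c(v, "non-finite values in displacement series")
  }
  dt <- diff(trial$t)
  if (n > 1) {
    target <- 1 / spec$sampling_rate
    if (max(abs(dt - target)) > 1e-6 * target) {
      v <- c(v, "non-uniform sampling or wrong sampling rate")
    }
  }
  dur <- (n - 1) / spec$sampling_rate
  if (abs(dur - spec$duration) > 1.5 / spec$sampling_rate) {
    v <- c(v, sprintf("duration %.3f s differs from specified %g s", dur,
                      spec$duration))
  }
  v
}

#' Filter and demean a trial in the standard preprocessing order
#'
#' Filtering first, then demeaning, so positional measures are taken about
#' the mean of the filtered trajectory.
#'
#' @param trial a `sway_trial`.
#' @param cfg a [filter_config()].
#' @return preprocessed `sway_trial`.
#' @export
preprocess_trial <- function(trial, cfg = filter_config()) {
  demean_trial(lowpass_zero_phase(trial, cfg))
}
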