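#' Multichannel analog signal set
#'
#' Sampled extracellular traces, either wide-band raw data (10 kHz) or
#' low-pass filtered and decimated local field potentials (1 kHz). Samples are
#' in microvolts, one row per channel.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param sampling_rate sampling frequency in Hz. Must be 10000 for
#'   `kind = "raw"` and 1000 for `kind = "lfp"`.
#' @param t_start time of the first sample in seconds.
#' @param kind `"raw"` or `"lfp"`.
#' @return object of class `analog_signal_set`.
#' @export
analog_signal_set <- function(samples, sampling_rate, t_start = 0,
                              kind = c("raw", "lfp")) {
  kind <- match.arg(kind)
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  expected <- c(raw = 10000, lfp = 1000)[[kind]]
  if (sampling_rate != expected) {
    stop(sprintf("kind '%s' requires sampling_rate %g Hz", kind, expected))
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 t_start = t_start, kind = kind),
            class = "analog_signal_set")
}

#' @export
print.analog_signal_set <- function(x, ...) {
  cat(sprintf("Analog signal set (%s): %d channels, %.1f s at %g Hz\n",
              x$kind, nrow(x$samples), ncol(x$samples) / x$sampling_rate,
              x$sampling_rate))
  invisible(x)
}

#' Stimulation record
#'
#' Onset times of a train of identical biphasic voltage pulses delivered to a
#' single electrode. The default pulse matches the standard MEA protocol:
#' 600 us biphasic pulse of 750 mV half-amplitude delivered every 5 s
#' (0.2 Hz), 120 trials per session.
#'
#' @param site stimulated electrode id (0-based).
#' @param onsets sorted stimulus onset times in seconds.
#' @param inter_stimulus_interval nominal onset spacing in seconds.
#' @param jitter_tol tolerated relative deviation of consecutive onset
#'   differences from `inter_stimulus_interval` before a warning is raised.
#' @param pulse list describing the pulse (duration in us, half amplitude in
#'   mV, shape).
#' @return object of class `stimulation_record` with `n_trials` field.
#' @export
stimulation_record <- function(site, onsets, inter_stimulus_interval = 5,
                               jitter_tol = 0.1,
                               pulse = list(duration_us = 600,
                                            half_amplitude_mV = 750,
                                            shape = "biphasic")) {
  onsets <- as.numeric(onsets)
  if (length(onsets) < 1) stop("at least one stimulus onset required")
  if (is.unsorted(onsets, strictly = TRUE)) stop("onsets must be strictly increasing")
  if (length(onsets) > 1) {
    d <- diff(onsets)
    if (any(abs(d - inter_stimulus_interval) >
            jitter_tol * inter_stimulus_interval)) {
      warning("consecutive onsets deviate from the nominal inter-stimulus interval")
    }
  }
  structure(list(site = as.integer(site), onsets = onsets,
                 n_trials = length(onsets),
                 inter_stimulus_interval = inter_stimulus_interval,
                 pulse = pulse),
            class = "stimulation_record")
}

#' @export
print.stimulation_record <- function(x, ...) {
  cat(sprintf("Stimulation record: site %d, %d trials every %g s\n",
              x$site, x$n_trials, x$inter_stimulus_interval))
  invisible(x)
}
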