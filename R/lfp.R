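#' Frequency-band presets
#'
#' Band edges in Hz for the low-frequency LFP bands. `lfp_bands("methods")`
#' is the operative definition (delta 1-4, theta 4-11, beta 11-30);
#' `lfp_bands("figure")` is the alternative labelling sometimes used in
#' figure captions (theta 5-9, beta 10-30). Gamma is deliberately excluded.
#'
#' @param which `"methods"` (default) or `"figure"`.
#' @return named list of `c(f_lo, f_hi)` pairs.
#' @export
lfp_bands <- function(which = c("methods", "figure")) {
  which <- match.arg(which)
  if (which == "methods") {
    list(delta = c(1, 4), theta = c(4, 11), beta = c(11, 30))
  } else {
    list(delta = c(1, 4), theta = c(5, 9), beta = c(10, 30))
  }
}

#' Extract local field potentials from wide-band data
#'
#' Zero-phase Butterworth filtering of the raw 10 kHz signal into the
#' 1-300 Hz LFP band, then decimation by 10 to 1 kHz. The band-pass is
#' realized as a cascade — 4th-order low-pass at the upper edge applied at
#' the native rate (this is also the anti-alias filter for the new 500 Hz
#' Nyquist frequency), decimation, then 4th-order high-pass at the lower
#' edge at 1 kHz — because a direct transfer-function band-pass spanning
#' nearly four decades below Nyquist is numerically unstable. Both stages
#' use [signal::filtfilt()] (forward-backward), so evoked latencies are
#' preserved.
#'
#' @param raw an [analog_signal_set()] of kind `"raw"`.
#' @param band filter pass band in Hz.
#' @param order Butterworth order of each stage (applied twice by filtfilt).
#' @return an [analog_signal_set()] of kind `"lfp"` at 1 kHz.
#' @export
extract_lfp <- function(raw, band = c(1, 300), order = 4) {
  stopifnot(inherits(raw, "analog_signal_set"))
  if (raw$kind != "raw") stop("extract_lfp expects raw wide-band input")
  fs <- raw$sampling_rate
  if (fs < 2 * band[2]) stop("sampling rate below twice the upper cutoff")
  lp <- signal::butter(order, band[2] / (fs / 2), type = "low")
  dec <- 10L
  fs_out <- fs / dec
  hp <- signal::butter(order, band[1] / (fs_out / 2), type = "high")
  keep <- seq(1, ncol(raw$samples), by = dec)
  out <- matrix(0, nrow(raw$samples), length(keep))
  for (ch in seq_len(nrow(raw$samples))) {
    low <- signal::filtfilt(lp, raw$samples[ch, ])
    out[ch, ] <- signal::filtfilt(hp, low[keep])
  }
  analog_signal_set(out, fs_out, raw$t_start, kind = "lfp")
}

#' Welch power spectral density
#'
#' One-sided PSD (uV^2/Hz) by Welch's method: the signal is split into
#' overlapping segments, each detrended (mean removed), Hann-windowed and
#' periodogram-averaged. Defaults match spontaneous-LFP analysis: 5 s
#' windows with 50% overlap.
#'
#' @param x an [analog_signal_set()] or a channels x time numeric matrix.
#' @param fs sampling rate in Hz (ignored when `x` is an
#'   `analog_signal_set`).
#' @param window segment length in seconds.
#' @param overlap overlap fraction in `[0, 1)`.
#' @param max_freq optional upper frequency limit of the output (Hz).
#' @return object of class `mea_psd`: list with `freq` (Hz) and `psd`
#'   (channels x frequency matrix, uV^2/Hz).
#' @export
welch_psd <- function(x, fs = NULL, window = 5, overlap = 0.5,
                      max_freq = NULL) {
  if (inherits(x, "analog_signal_set")) {
    fs <- x$sampling_rate
    x <- x$samples
  }
  x <- rbind(x)
  if (is.null(fs)) stop("fs required for matrix input")
  nseg <- round(window * fs)
  if (nseg > ncol(x)) stop("window longer than signal")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1, ncol(x) - nseg + 1, by = step)
  win <- signal::hanning(nseg)
  scale <- fs * sum(win^2)
  n_freq <- nseg %/% 2 + 1
  freq <- (seq_len(n_freq) - 1) * fs / nseg
  # one-sided scaling: double all bins except DC (and Nyquist for even nseg)
  dbl <- rep(2, n_freq); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[n_freq] <- 1
  psd <- matrix(0, nrow(x), n_freq)
  seg_idx <- outer(seq_len(nseg) - 1L, starts, `+`)  # nseg x nsegments
  for (ch in seq_len(nrow(x))) {
    segs <- matrix(x[ch, seg_idx], nrow = nseg)
    segs <- sweep(segs, 2, colMeans(segs)) * win
    p <- Mod(stats::mvfft(segs)[seq_len(n_freq), , drop = FALSE])^2 / scale
    psd[ch, ] <- rowMeans(p) * dbl
  }
  if (!is.null(max_freq)) {
    keep <- freq <= max_freq
    freq <- freq[keep]; psd <- psd[, keep, drop = FALSE]
  }
  structure(list(freq = freq, psd = psd), class = "mea_psd")
}

#' @export
print.mea_psd <- function(x, ...) {
  cat(sprintf("Welch PSD: %d channels, %.2f-%.1f Hz (df = %.3f Hz)\n",
              nrow(x$psd), min(x$freq), max(x$freq), diff(x$freq[1:2])))
  invisible(x)
}

#' Integrate spectral power over a frequency band
#'
#' Trapezoidal integral of the PSD over `[f_lo, f_hi]`, with linear
#' interpolation at band edges that fall between frequency grid points. Band
#' edges are shared single points between adjacent bands, so power is
#' additive over disjoint bands without double counting.
#'
#' @param psd a [welch_psd()] result.
#' @param band numeric `c(f_lo, f_hi)` in Hz with `f_lo < f_hi`, inside the
#'   PSD's frequency range.
#' @return numeric vector of per-channel band power (uV^2).
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "mea_psd"))
  if (band[2] <= band[1]) stop("inverted band")
  if (band[1] < min(psd$freq) - 1e-9 || band[2] > max(psd$freq) + 1e-9) {
    stop("band outside PSD frequency range")
  }
  inner <- psd$freq > band[1] & psd$freq < band[2]
  apply(psd$psd, 1, function(p) {
    f <- c(band[1], psd$freq[inner], band[2])
    y <- c(stats::approx(psd$freq, p, band[1])$y, p[inner],
           stats::approx(psd$freq, p, band[2])$y)
    pracma::trapz(f, y)
  })
}

#' Band-power table for a multichannel LFP
#'
#' Convenience wrapper: Welch PSD then band integration for each preset
#' band; returns per-channel and channel-averaged powers.
#'
#' @param lfp an [analog_signal_set()] of kind `"lfp"`.
#' @param bands named list of bands as from [lfp_bands()].
#' @param window,overlap Welch parameters (see [welch_psd()]).
#' @return object of class `band_power_result`: list with `per_channel`
#'   (channels x band matrix) and `mean` (named vector of channel-averaged
#'   power per band).
#' @export
band_power_table <- function(lfp, bands = lfp_bands(), window = 5,
                             overlap = 0.5) {
  psd <- welch_psd(lfp, window = window, overlap = overlap)
  per_ch <- vapply(bands, function(b) band_power(psd, b),
                   numeric(nrow(psd$psd)))
  per_ch <- rbind(per_ch)  # keep matrix shape for single-channel input
  structure(list(per_channel = per_ch, mean = colMeans(per_ch)),
            class = "band_power_result")
}

#' @export
print.band_power_result <- function(x, ...) {
  cat("Band power (channel mean, uV^2):\n")
  print(signif(x$mean, 4))
  invisible(x)
}

#' PSD of the mean evoked LFP response
#'
#' Averages the stimulus-locked LFP windows (default 100 ms before to 900 ms
#' after onset) per channel, after linearly interpolating over the 10 ms
#' artifact-blanking interval in every trial, and computes the Welch PSD of
#' the mean evoked response (200 ms windows, 50% overlap, reported up to
#' 100 Hz). Analysis channels are the top `n_top` ranked by spontaneous
#' basal mean firing rate when `basal_spikes` is supplied; if fewer active
#' channels are available, all are used with a warning.
#'
#' @param lfp an [analog_signal_set()] of kind `"lfp"` (1 kHz).
#' @param stim a [stimulation_record()].
#' @param pre,post window extent in seconds around onset.
#' @param blank artifact interval after onset, linearly interpolated (s).
#' @param basal_spikes optional [spike_train_set()] of the spontaneous basal
#'   phase used to rank channels by MFR.
#' @param channels optional explicit 0-based channel ids (overrides ranking).
#' @param n_top number of top-MFR channels to keep.
#' @param window,overlap,max_freq Welch parameters.
#' @return list with `psd` (a `mea_psd` over selected channels), `mean_psd`
#'   (channel-averaged density), `evoked` (channels x time mean response),
#'   and `channels` (0-based ids used).
#' @export
evoked_psd <- function(lfp, stim, pre = 0.1, post = 0.9, blank = 0.01,
                       basal_spikes = NULL, channels = NULL, n_top = 20,
                       window = 0.2, overlap = 0.5, max_freq = 100) {
  stopifnot(inherits(lfp, "analog_signal_set"), lfp$kind == "lfp",
            inherits(stim, "stimulation_record"))
  fs <- lfp$sampling_rate
  n_ch <- nrow(lfp$samples)
  if (is.null(channels)) {
    if (!is.null(basal_spikes)) {
      mfr <- lengths(basal_spikes$trains) /
        (basal_spikes$t_stop - basal_spikes$t_start)
      active <- which(mfr > 0)
      if (length(active) < n_top) {
        warning("fewer than ", n_top, " active channels; using all ",
                length(active))
        channels <- unname(active) - 1L
      } else {
        channels <- order(mfr, decreasing = TRUE)[seq_len(n_top)] - 1L
      }
    } else {
      channels <- seq_len(n_ch) - 1L
    }
  }
  ch_idx <- channels + 1L
  n_pre <- round(pre * fs); n_post <- round(post * fs)
  n_win <- n_pre + n_post
  blank_idx <- n_pre + seq_len(round(blank * fs))
  evoked <- matrix(0, length(ch_idx), n_win)
  for (on in stim$onsets) {
    i0 <- round((on - lfp$t_start) * fs) + 1L - n_pre
    if (i0 < 1 || i0 + n_win - 1 > ncol(lfp$samples)) {
      stop("trial window outside recording")
    }
    seg <- lfp$samples[ch_idx, i0:(i0 + n_win - 1), drop = FALSE]
    # bridge the stimulation artifact
    a <- min(blank_idx) - 1L; b <- max(blank_idx) + 1L
    w <- (blank_idx - a) / (b - a)
    seg[, blank_idx] <- seg[, a] %o% (1 - w) + seg[, b] %o% w
    evoked <- evoked + seg
  }
  evoked <- evoked / stim$n_trials
  psd <- welch_psd(evoked, fs = fs, window = window, overlap = overlap,
                   max_freq = max_freq)
  list(psd = psd, mean_psd = colMeans(psd$psd), evoked = evoked,
       channels = channels)
}
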