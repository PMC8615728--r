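#' Bin spike counts on a fixed grid
#'
#' Counts spikes of every electrode in half-open bins `[t, t + bin_size)`
#' covering `interval`. The last bin is truncated at the interval end when the
#' interval length is not a multiple of the bin size, so the total count
#' always equals the number of spikes inside the interval.
#'
#' @param spikes a [spike_train_set()]
#' @param bin_size bin width in seconds (> 0).
#' @param interval `c(t0, t1)` inside the recording; defaults to the full
#'   recording.
#' @return integer matrix, channels x bins, with electrode ids as row names.
#' @export
bin_spike_counts <- function(spikes, bin_size,
                             interval = c(spikes$t_start, spikes$t_stop)) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (bin_size <= 0) stop("bin_size must be positive")
  t0 <- interval[1]; t1 <- interval[2]
  span <- t1 - t0
  if (span <= 0) stop("empty interval")
  if (bin_size > span + 1e-12) stop("bin larger than interval")
  if (t0 < spikes$t_start - 1e-9 || t1 > spikes$t_stop + 1e-9) {
    stop("interval outside recording bounds")
  }
  n_bins <- as.integer(ceiling(span / bin_size - 1e-9))
  counts <- matrix(0L, nrow = length(spikes$trains), ncol = n_bins,
                   dimnames = list(names(spikes$trains), NULL))
  for (i in seq_along(spikes$trains)) {
    tr <- spikes$trains[[i]]
    tr <- tr[tr >= t0 & tr < t1]
    if (length(tr)) {
      idx <- pmin(floor((tr - t0) / bin_size) + 1, n_bins)
      counts[i, ] <- tabulate(idx, nbins = n_bins)
    }
  }
  counts
}

#' Align spikes to stimulus onsets into a trial tensor
#'
#' Builds the trial x channel x bin spike-count array used by the PSTH and
#' the perturbational-complexity pipeline: every trial covers `[-pre, post)`
#' seconds around a stimulus onset, in half-open bins of `bin_size`. Spikes in
#' the artifact-blanking interval `[onset, onset + blank)` are removed before
#' binning (the same 10 ms blanking used for the evoked LFP is applied to
#' spiking by default).
#'
#' @param spikes a [spike_train_set()]
#' @param stim a [stimulation_record()]
#' @param pre,post window extent in seconds before/after onset;
#'   `(pre + post) / bin_size` must be an integer.
#' @param bin_size bin width in seconds.
#' @param blank artifact-blanking interval after onset, in seconds
#'   (`blank < post`).
#' @return object of class `trial_tensor`: list with `counts`
#'   (trial x channel x bin array), `bin_size`, `pre`, `post`, `blank`,
#'   `onsets`, and `channels`.
#' @export
align_trials <- function(spikes, stim, pre = 1.0, post = 0.5,
                         bin_size = 0.005, blank = 0.010) {
  stopifnot(inherits(spikes, "spike_train_set"),
            inherits(stim, "stimulation_record"))
  if (blank >= post) stop("blank must be smaller than post")
  n_bins_f <- (pre + post) / bin_size
  n_bins <- as.integer(round(n_bins_f))
  if (abs(n_bins_f - n_bins) > 1e-9) {
    stop("window (pre + post) must be divisible by bin_size")
  }
  onsets <- stim$onsets
  if (any(onsets - pre < spikes$t_start - 1e-9) ||
      any(onsets + post > spikes$t_stop + 1e-9)) {
    stop("trial windows must fit inside the recording")
  }
  if (length(onsets) > 1 && any(diff(onsets) < pre + post)) {
    stop("trial windows overlap")
  }
  n_tr <- length(onsets)
  n_ch <- length(spikes$trains)
  counts <- array(0L, dim = c(n_tr, n_ch, n_bins))
  starts <- onsets - pre
  for (ch in seq_len(n_ch)) {
    tt <- spikes$trains[[ch]]
    if (!length(tt)) next
    trial <- findInterval(tt, starts)
    ok <- trial >= 1
    rel <- tt - onsets[pmax(trial, 1L)]
    ok <- ok & rel < post & rel >= -pre
    ok <- ok & !(rel >= 0 & rel < blank)
    if (!any(ok)) next
    rel <- rel[ok]; trial <- trial[ok]
    bin <- pmin(floor((rel + pre) / bin_size) + 1, n_bins)
    for (j in seq_along(rel)) {
      counts[trial[j], ch, bin[j]] <- counts[trial[j], ch, bin[j]] + 1L
    }
  }
  structure(list(counts = counts, bin_size = bin_size, pre = pre, post = post,
                 blank = blank, onsets = onsets,
                 channels = as.integer(names(spikes$trains))),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "Trial tensor: %d trials x %d channels x %d bins of %g ms ([-%g, %g] s)\n",
    d[1], d[2], d[3], 1000 * x$bin_size, x$pre, x$post))
  invisible(x)
}

#' Bin start times of a trial tensor, relative to stimulus onset
#' @param tensor a [align_trials()] result
#' @return numeric vector of bin start times in seconds (negative = pre-stimulus)
#' @export
bin_times <- function(tensor) {
  seq(-tensor$pre, tensor$post - tensor$bin_size, by = tensor$bin_size)
}

# indices of pre-stimulus (bin entirely before onset) and post-stimulus bins
pre_bins <- function(tensor) which(bin_times(tensor) < -1e-12)
post_bins <- function(tensor) which(bin_times(tensor) >= -1e-12)
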