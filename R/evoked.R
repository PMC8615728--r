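#' Post-stimulus time histogram
#'
#' Trial-averaged evoked firing profile per channel: the post-stimulus window
#' (default 400 ms in 4 ms bins) is binned per trial and the spike count per
#' bin is divided by `n_trials * bin_size`, giving a rate in spikes/s. The
#' PSTH area (rate summed times bin width) is the mean number of evoked
#' spikes per trial and is invariant to the binning of the window. The
#' stimulus-artifact blanking of [align_trials()] applies (default 10 ms).
#'
#' @param spikes a [spike_train_set()]
#' @param stim a [stimulation_record()]
#' @param bin_size bin width in seconds (default 4 ms).
#' @param window post-stimulus window length in seconds (default 400 ms).
#' @param blank artifact-blanking interval (s).
#' @return object of class `mea_psth`: list with `rate` (channels x bins
#'   matrix, spikes/s), `area` (per-channel spikes/trial), `bin_size`,
#'   `n_trials`, `channels`.
#' @export
compute_psth <- function(spikes, stim, bin_size = 0.004, window = 0.4,
                         blank = 0.01) {
  stopifnot(inherits(stim, "stimulation_record"))
  if (stim$n_trials == 0) stop("no trials")
  tensor <- align_trials(spikes, stim, pre = 0, post = window,
                         bin_size = bin_size, blank = blank)
  counts <- apply(tensor$counts, c(2, 3), sum)  # channels x bins
  rate <- counts / (stim$n_trials * bin_size)
  structure(list(rate = rate, area = rowSums(rate) * bin_size,
                 bin_size = bin_size, window = window,
                 n_trials = stim$n_trials, channels = tensor$channels),
            class = "mea_psth")
}

#' @export
print.mea_psth <- function(x, ...) {
  cat(sprintf(
    "PSTH: %d channels, %d bins of %g ms, %d trials; median area %.2f spikes/trial\n",
    nrow(x$rate), ncol(x$rate), 1000 * x$bin_size, x$n_trials,
    stats::median(x$area)))
  invisible(x)
}

#' @export
plot.mea_psth <- function(x, channel = NULL, ...) {
  tt <- (seq_len(ncol(x$rate)) - 0.5) * x$bin_size * 1000
  y <- if (is.null(channel)) colMeans(x$rate) else
    x$rate[match(channel, x$channels), ]
  graphics::plot(tt, y, type = "s", xlab = "time after stimulus (ms)",
                 ylab = "rate (spikes/s)", ...)
  invisible(x)
}

#' Select active channels by PSTH area
#'
#' Channels whose PSTH area is below one spike per trial are removed before
#' response statistics; the boundary (exactly 1) is retained.
#'
#' @param psth a [compute_psth()] result.
#' @param min_area retention threshold in spikes/trial.
#' @return integer vector of retained 0-based channel ids.
#' @export
filter_active_channels <- function(psth, min_area = 1) {
  stopifnot(inherits(psth, "mea_psth"))
  keep <- psth$channels[psth$area >= min_area]
  if (length(keep) == 0) warning("no channels reach the PSTH area threshold")
  keep
}

#' Percent variation of the PSTH area
#'
#' `delta_pa = 100 * (pa_cch - pa_bas) / pa_bas`, the signed percent change
#' of the evoked response between the drug and the basal stimulation
#' session. Channels with zero basal area are returned as `NA` (excluded).
#'
#' @param pa_bas,pa_cch PSTH areas (spikes/trial), vectorized.
#' @return signed percentage(s).
#' @export
delta_pa <- function(pa_bas, pa_cch) {
  out <- 100 * (pa_cch - pa_bas) / pa_bas
  out[pa_bas == 0] <- NA_real_
  out
}

#' Stability threshold from a basal stimulation session
#'
#' Quantifies the natural trial-to-trial drift of the evoked response: a
#' stimulation session is split into two equal halves (by trial order), the
#' PSTH area is computed per channel in each half, and the per-channel
#' variation `100 * (PA_second - PA_first) / PA_first` is pooled. The
#' classification band is `mean +/- sd` of that distribution. When no
#' stability session is available, call with `spikes = NULL` to obtain the
#' empirical fallback of `0 +/- 20` percent.
#'
#' @param spikes a [spike_train_set()] of the basal stimulation session, or
#'   `NULL` for the fallback.
#' @param stim the session's [stimulation_record()].
#' @param min_area channel-activity threshold (spikes/trial over the full
#'   session).
#' @param ... passed to [compute_psth()].
#' @return object of class `stability_threshold`: list with `center`, `sd`,
#'   `lower`, `upper` (percent) and the pooled `deltas`.
#' @export
stability_threshold <- function(spikes = NULL, stim = NULL, min_area = 1,
                                ...) {
  if (is.null(spikes)) {
    return(structure(list(center = 0, sd = 20, lower = -20, upper = 20,
                          deltas = NULL, fallback = TRUE),
                     class = "stability_threshold"))
  }
  stopifnot(inherits(stim, "stimulation_record"))
  n <- stim$n_trials
  if (n < 2) stop("too few trials to split the session")
  half <- n %/% 2
  s1 <- stimulation_record(stim$site, stim$onsets[seq_len(half)],
                           stim$inter_stimulus_interval)
  s2 <- stimulation_record(stim$site, stim$onsets[(half + 1):n],
                           stim$inter_stimulus_interval)
  full <- compute_psth(spikes, stim, ...)
  act <- filter_active_channels(full, min_area)
  p1 <- compute_psth(spikes, s1, ...)
  p2 <- compute_psth(spikes, s2, ...)
  i <- match(act, full$channels)
  deltas <- delta_pa(p1$area[i], p2$area[i])
  deltas <- deltas[is.finite(deltas)]
  m <- mean(deltas); s <- stats::sd(deltas)
  structure(list(center = m, sd = s, lower = m - s, upper = m + s,
                 deltas = deltas, fallback = FALSE),
            class = "stability_threshold")
}

#' @export
print.stability_threshold <- function(x, ...) {
  cat(sprintf("Stability threshold: %.1f +/- %.1f%% -> band [%.1f, %.1f]%%%s\n",
              x$center, x$sd, x$lower, x$upper,
              if (isTRUE(x$fallback)) " (fallback)" else ""))
  invisible(x)
}

#' Classify channels by evoked-response change
#'
#' Three-way classification of the per-channel percent PSTH-area variation
#' against a stability threshold band: `decreased` below the band,
#' `increased` above it, `unchanged` inside.
#'
#' @param deltas named or plain numeric vector of percent variations
#'   ([delta_pa()] on active channels); `NA` entries are dropped.
#' @param threshold a [stability_threshold()], or `NULL` for the `+/- 20`
#'   percent fallback.
#' @param channels optional 0-based channel ids matching `deltas`.
#' @return object of class `channel_change`: data.frame `channel`,
#'   `delta_pa`, `class`, with a `summary` attribute (fractions per class
#'   in percent and the median variation).
#' @export
classify_channels <- function(deltas, threshold = NULL, channels = NULL) {
  if (is.null(threshold)) threshold <- stability_threshold(NULL)
  if (is.null(channels)) {
    channels <- if (!is.null(names(deltas))) as.integer(names(deltas)) else
      seq_along(deltas) - 1L
  }
  ok <- is.finite(deltas)
  deltas <- deltas[ok]; channels <- channels[ok]
  cls <- ifelse(deltas < threshold$lower, "decreased",
                ifelse(deltas > threshold$upper, "increased", "unchanged"))
  out <- data.frame(channel = channels, delta_pa = deltas,
                    class = factor(cls, levels = c("decreased", "unchanged",
                                                   "increased")))
  attr(out, "summary") <- list(
    pct_decreased = 100 * mean(cls == "decreased"),
    pct_increased = 100 * mean(cls == "increased"),
    pct_unchanged = 100 * mean(cls == "unchanged"),
    median_delta_pa = stats::median(deltas))
  class(out) <- c("channel_change", "data.frame")
  out
}

#' @export
print.channel_change <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "Channel changes (n = %d): %.0f%% decreased, %.0f%% unchanged, %.0f%% increased; median dPA %.1f%%\n",
    nrow(x), s$pct_decreased, s$pct_unchanged, s$pct_increased,
    s$median_delta_pa))
  invisible(x)
}
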