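#' Threshold-based spike detection on wide-band data
#'
#' High-pass filters each channel above 300 Hz (zero-phase Butterworth),
#' estimates the noise SD robustly as `median(|x|) / 0.6745`, and detects
#' single over-threshold peaks of either polarity at `k` times the noise SD.
#' Each contiguous supra-threshold excursion yields one spike at its absolute
#' peak; events closer than the dead time are merged (the larger peak is
#' kept).
#'
#' @param raw an [analog_signal_set()] of kind `"raw"` (10 kHz).
#' @param k threshold multiplier on the robust noise SD (default 7).
#' @param f_hp high-pass cutoff in Hz, or `NULL` to skip filtering (input
#'   already spike-band). On a trace with a silent (exact-zero) noise floor
#'   the robust SD is zero and the threshold falls back to half the largest
#'   absolute deflection.
#' @param dead_time minimal separation between detected spikes (s).
#' @param order Butterworth order.
#' @return a [spike_train_set()] of detected spike times.
#' @export
detect_spikes <- function(raw, k = 7, f_hp = 300, dead_time = 0.001,
                          order = 4) {
  stopifnot(inherits(raw, "analog_signal_set"))
  if (raw$kind != "raw") stop("detect_spikes expects raw wide-band input")
  fs <- raw$sampling_rate
  bf <- if (!is.null(f_hp)) signal::butter(order, f_hp / (fs / 2),
                                           type = "high")
  n_ch <- nrow(raw$samples)
  trains <- rep(list(numeric(0)), n_ch)
  for (ch in seq_len(n_ch)) {
    x <- if (is.null(f_hp)) raw$samples[ch, ] else
      signal::filtfilt(bf, raw$samples[ch, ])
    sigma <- stats::median(abs(x)) / 0.6745
    if (sigma == 0 && all(x == 0)) next  # flat channel
    # zero noise floor (median-silent trace): any deflection is signal
    thr <- if (sigma == 0) max(abs(x)) / 2 else k * sigma
    over <- abs(x) > thr
    if (!any(over)) next
    # contiguous supra-threshold runs -> peak sample each
    r <- rle(over)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- cbind(starts[r$values], ends[r$values])
    peaks <- apply(runs, 1, function(ab) {
      seg <- ab[1]:ab[2]
      seg[which.max(abs(x[seg]))]
    })
    amps <- abs(x[peaks])
    # enforce dead time, keeping the larger of two close events
    min_gap <- dead_time * fs
    keep <- logical(length(peaks))
    last <- -Inf; last_i <- 0
    for (i in seq_along(peaks)) {
      if (peaks[i] - last >= min_gap) {
        keep[i] <- TRUE; last <- peaks[i]; last_i <- i
      } else if (amps[i] > amps[last_i]) {
        keep[last_i] <- FALSE; keep[i] <- TRUE
        last <- peaks[i]; last_i <- i
      }
    }
    trains[[ch]] <- raw$t_start + (peaks[keep] - 1) / fs
  }
  dur <- ncol(raw$samples) / fs
  spike_train_set(trains, raw$t_start, raw$t_start + dur)
}

#' ISI-threshold burst detection
#'
#' Bursts are maximal runs of spikes whose inter-spike intervals never exceed
#' `max_isi`, containing at least `min_spikes` spikes (defaults 100 ms and 5
#' spikes, the common MEA setting).
#'
#' @param spikes a [spike_train_set()]
#' @param max_isi maximal intra-burst inter-spike interval (s).
#' @param min_spikes minimal number of spikes per burst.
#' @return object of class `burst_set`: data.frame with columns `electrode`,
#'   `start_s`, `end_s`, `n_spikes`; detector parameters kept as attributes.
#' @export
detect_bursts <- function(spikes, max_isi = 0.1, min_spikes = 5L) {
  stopifnot(inherits(spikes, "spike_train_set"))
  res <- list()
  for (i in seq_along(spikes$trains)) {
    tr <- spikes$trains[[i]]
    if (length(tr) < min_spikes) next
    grp <- cumsum(c(1, diff(tr) > max_isi))
    sizes <- tabulate(grp)
    for (g in which(sizes >= min_spikes)) {
      tt <- tr[grp == g]
      res[[length(res) + 1]] <- data.frame(
        electrode = as.integer(names(spikes$trains)[i]),
        start_s = tt[1], end_s = tt[length(tt)],
        n_spikes = length(tt))
    }
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(electrode = integer(0), start_s = numeric(0),
               end_s = numeric(0), n_spikes = integer(0))
  }
  attr(out, "max_isi") <- max_isi
  attr(out, "min_spikes") <- min_spikes
  class(out) <- c("burst_set", "data.frame")
  out
}

#' Firing-rate statistics
#'
#' Per-electrode mean firing rate (spikes/s), inverse burst ratio (IBR, the
#' percentage of spikes not inside any detected burst) and the coefficient of
#' variation of the per-electrode MFRs (CV(MFR) = SD/mean across electrodes
#' with any activity considered; silent electrodes contribute rate 0).
#'
#' @param spikes a [spike_train_set()]
#' @param bursts optional [detect_bursts()] result; computed when missing.
#' @param interval optional `c(t0, t1)` restricting the analysis.
#' @return list with `mfr` (per electrode), `mfr_mean`, `ibr` (percent),
#'   `cv_mfr`, `n_spikes`.
#' @export
firing_stats <- function(spikes, bursts = NULL, interval = NULL) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (!is.null(interval)) spikes <- crop_spikes(spikes, interval)
  dur <- spikes$t_stop - spikes$t_start
  if (dur <= 0) stop("zero-duration phase")
  if (is.null(bursts)) bursts <- detect_bursts(spikes)
  ns <- lengths(spikes$trains)
  mfr <- ns / dur
  total <- sum(ns)
  in_burst <- 0
  if (nrow(bursts)) {
    for (r in seq_len(nrow(bursts))) {
      tr <- spikes$trains[[as.character(bursts$electrode[r])]]
      in_burst <- in_burst +
        sum(tr >= bursts$start_s[r] & tr <= bursts$end_s[r])
    }
  }
  ibr <- if (total > 0) 100 * (total - in_burst) / total else NA_real_
  cv <- if (mean(mfr) > 0) stats::sd(mfr) / mean(mfr) else NA_real_
  list(mfr = stats::setNames(mfr, names(spikes$trains)),
       mfr_mean = mean(mfr), ibr = ibr, cv_mfr = cv, n_spikes = total)
}

#' Burstiness index
#'
#' Whole-network spike counts are binned (1 s bins); `f15` is the fraction of
#' all spikes falling in the 15% fullest bins, and
#' `BI = (f15 - 0.15) / 0.85`, clipped to `[0, 1]`: 0 for a uniformly firing
#' network, 1 for a fully burst-dominated one.
#'
#' @param spikes a [spike_train_set()]
#' @param bin bin width in seconds.
#' @param top_fraction fraction of fullest bins considered.
#' @return burstiness index in `[0, 1]`, or `NA` when there are no spikes.
#' @export
burstiness_index <- function(spikes, bin = 1, top_fraction = 0.15) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (n_spikes_total(spikes) == 0) return(NA_real_)
  counts <- colSums(bin_spike_counts(spikes, bin))
  n_top <- max(1L, round(top_fraction * length(counts)))
  f_top <- sum(sort(counts, decreasing = TRUE)[seq_len(n_top)]) / sum(counts)
  min(1, max(0, (f_top - top_fraction) / (1 - top_fraction)))
}

#' Spike time tiling coefficient
#'
#' Firing-rate-robust pairwise spike-train correlation in `[-1, 1]`:
#' `STTC = 1/2 * ((P_A - T_B)/(1 - P_A T_B) + (P_B - T_A)/(1 - P_B T_A))`
#' where `P_A` is the fraction of A-spikes within `dt` of any B-spike and
#' `T_B` the fraction of total recording time tiled by `+/-dt` windows around
#' B-spikes (window edges clipped to the recording). Symmetric in its
#' arguments.
#'
#' @param a,b numeric sorted spike-time vectors (s).
#' @param dt coincidence half-window in seconds (default 10 ms).
#' @param t_range recording interval `c(t0, T)` both trains live in.
#' @return STTC value, or `NA` when either train is empty.
#' @export
sttc <- function(a, b, dt = 0.01, t_range) {
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  pa <- tiling_prop(a, b, dt)
  pb <- tiling_prop(b, a, dt)
  ta <- tiled_time(a, dt, t_range) / diff(t_range)
  tb <- tiled_time(b, dt, t_range) / diff(t_range)
  part <- function(p, tt) if (p == 1 && tt == 1) 0 else (p - tt) / (1 - p * tt)
  0.5 * (part(pa, tb) + part(pb, ta))
}

# fraction of spikes in a lying within dt of some spike in b
tiling_prop <- function(a, b, dt) {
  idx <- findInterval(a, b)
  d_prev <- ifelse(idx >= 1, a - b[pmax(idx, 1)], Inf)
  d_next <- ifelse(idx < length(b), b[pmin(idx + 1, length(b))] - a, Inf)
  mean(pmin(d_prev, d_next) <= dt + 1e-12)
}

# total time covered by the union of [t - dt, t + dt] windows, clipped
tiled_time <- function(t, dt, t_range) {
  lo <- pmax(t - dt, t_range[1])
  hi <- pmin(t + dt, t_range[2])
  if (length(t) == 1) return(hi - lo)
  gaps <- pmax(lo[-1] - hi[-length(hi)], 0)
  (hi[length(hi)] - lo[1]) - sum(gaps)
}

#' Mean pairwise STTC of a spike-train set
#'
#' @param spikes a [spike_train_set()]
#' @param dt coincidence half-window (s).
#' @return list with `mean` (over pairs with both trains nonempty; pairs with
#'   an empty train are excluded, not zero-filled) and `matrix` (full
#'   symmetric pairwise matrix with `NA` for excluded pairs).
#' @export
sttc_matrix <- function(spikes, dt = 0.01) {
  stopifnot(inherits(spikes, "spike_train_set"))
  tr <- spikes$trains
  n <- length(tr)
  t_range <- c(spikes$t_start, spikes$t_stop)
  m <- matrix(NA_real_, n, n, dimnames = list(names(tr), names(tr)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- sttc(tr[[i]], tr[[j]], dt, t_range)
      m[i, j] <- m[j, i] <- v
    }
  }
  vals <- m[upper.tri(m)]
  list(mean = mean(vals, na.rm = TRUE), matrix = m)
}

#' Multivariate SPIKE synchronization
#'
#' Parameter-free coincidence measure in `[0, 1]`: for each spike and each
#' other train, the spike is coincident if its distance to the nearest spike
#' of the other train is below the adaptive window
#' `tau = 1/2 * min` of the four surrounding inter-spike intervals (the ISIs
#' before/after the spike and before/after its nearest neighbour; undefined
#' edge ISIs are ignored). The index is the average coincidence indicator
#' over all spikes of all trains and all partner trains.
#'
#' @param spikes a [spike_train_set()] (at least two nonempty trains).
#' @return SPIKE-synchronization value in `[0, 1]`, `NA` if fewer than two
#'   trains contain spikes.
#' @export
spike_synchronization <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train_set"))
  tr <- Filter(length, spikes$trains)
  if (length(tr) < 2) return(NA_real_)
  n <- length(tr)
  hits <- lapply(tr, function(t) numeric(length(t)))  # coincidence counters
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cc <- pair_coincidences(tr[[i]], tr[[j]])
      hits[[i]] <- hits[[i]] + cc$a
      hits[[j]] <- hits[[j]] + cc$b
    }
  }
  total <- sum(unlist(hits))
  total / ((n - 1) * sum(lengths(tr)))
}

# pairwise coincidence indicators for each spike of a and of b
pair_coincidences <- function(a, b) {
  ind <- function(x, y) {
    isi_x <- diff(x)
    isi_y <- diff(y)
    idx <- findInterval(x, y)
    d_prev <- ifelse(idx >= 1, x - y[pmax(idx, 1)], Inf)
    d_next <- ifelse(idx < length(y), y[pmin(idx + 1, length(y))] - x, Inf)
    nearest <- ifelse(d_prev <= d_next, pmax(idx, 1), pmin(idx + 1, length(y)))
    d <- pmin(d_prev, d_next)
    k <- seq_along(x)
    tau <- pmin(
      ifelse(k > 1, isi_x[pmax(k - 1, 1)], Inf),
      ifelse(k < length(x), isi_x[pmin(k, max(length(isi_x), 1))], Inf),
      ifelse(nearest > 1, isi_y[pmax(nearest - 1, 1)], Inf),
      ifelse(nearest < length(y), isi_y[pmin(nearest, max(length(isi_y), 1))],
             Inf)) / 2
    as.numeric(d < tau)
  }
  list(a = ind(a, b), b = ind(b, a))
}

#' Spontaneous network metrics for one phase
#'
#' Bundles the multi-unit metrics computed on a (phase of a) recording:
#' MFR, IBR, CV(MFR), burstiness index, mean pairwise STTC and SPIKE
#' synchronization.
#'
#' @param spikes a [spike_train_set()]
#' @param interval optional `c(t0, t1)` phase restriction.
#' @param sttc_dt STTC coincidence half-window (s).
#' @return object of class `network_metrics` (named list).
#' @export
network_metrics <- function(spikes, interval = NULL, sttc_dt = 0.01) {
  if (!is.null(interval)) spikes <- crop_spikes(spikes, interval)
  fs <- firing_stats(spikes)
  structure(list(
    mfr_mean = fs$mfr_mean, mfr = fs$mfr, ibr = fs$ibr, cv_mfr = fs$cv_mfr,
    bi = burstiness_index(spikes),
    sttc_mean = sttc_matrix(spikes, dt = sttc_dt)$mean,
    spike_sync = spike_synchronization(spikes)),
    class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "MFR %.2f sp/s | IBR %.1f%% | BI %.3f | STTC %.3f | SPIKE-sync %.3f | CV(MFR) %.3f\n",
    x$mfr_mean, x$ibr, x$bi, x$sttc_mean, x$spike_sync, x$cv_mfr))
  invisible(x)
}
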