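#' Lempel-Ziv (1976) complexity of a binary sequence
#'
#' Number of words in the exhaustive-history production parsing
#' (Kaspar-Schuster scanning procedure). Deterministic; the first symbol is
#' always one word, so `C >= 1` for nonempty input.
#'
#' @param x binary vector (0/1, or logical), or a character string of 0s and
#'   1s.
#' @return integer word count.
#' @export
lz76 <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1)
    x <- as.integer(strsplit(x, "")[[1]])
  }
  if (length(x) == 0) stop("empty sequence")
  .lz76_count(as.integer(x))
}

#' Binary source entropy
#'
#' Entropy of the fraction of significant activations:
#' `Hsrc = -p0 log(p0) - p1 log(p1)`, with `Hsrc = 0` at `p1` of 0 or 1.
#' Maximal (1 bit) at `p1 = 0.5` and symmetric about it.
#'
#' @param p1 fraction of ones in `[0, 1]`.
#' @param base logarithm base (2 for bits).
#' @return entropy value.
#' @export
source_entropy <- function(p1, base = 2) {
  stopifnot(p1 >= 0, p1 <= 1)
  p <- c(p1, 1 - p1)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

# Panzeri-Treves expected-occupancy estimate of the number of relevant
# response bins, used by the analytic bias correction. Pr: full probability
# vector over the bin space (zeros included); Nt: number of samples.
pt_bayescount <- function(Pr, Nt) {
  PrNZ <- Pr[Pr > .Machine$double.eps]
  Rnaive <- length(PrNZ)
  R <- Rnaive
  if (Rnaive < length(Pr) && Nt > 1) {
    Rexpected <- Rnaive - sum((1 - PrNZ)^Nt)
    deltaR_prev <- length(Pr)
    deltaR <- abs(Rnaive - Rexpected)
    xtr <- 0
    while (deltaR < deltaR_prev && (Rnaive + xtr) < length(Pr)) {
      xtr <- xtr + 1
      gamma <- xtr * (1 - (Nt / (Nt + Rnaive))^(1 / Nt))
      Pbayes <- ((1 - gamma) / (Nt + Rnaive)) * (PrNZ * Nt + 1)
      Rexpected <- sum(1 - (1 - Pbayes)^Nt) +
        xtr * (1 - (1 - gamma / xtr)^Nt)
      deltaR_prev <- deltaR
      deltaR <- abs(Rnaive - Rexpected)
    }
    R <- Rnaive + xtr - 1
    if (deltaR < deltaR_prev) R <- R + 1
  }
  R
}

#' Mutual information with Panzeri-Treves bias correction
#'
#' Plug-in mutual information (bits) between two discrete series, minus the
#' analytic first-order bias `(R_xy - R_x - R_y + 1) / (2 N ln 2)`, where the
#' relevant-bin counts `R` are estimated with the Panzeri-Treves
#' expected-occupancy rule rather than naive occupancy.
#'
#' @param x,y integer level codes in `1:n_levels`, equal length `>= 100`.
#' @param n_levels size of the level alphabet.
#' @return bias-corrected mutual information in bits (0 for degenerate
#'   single-level input).
#' @export
mutual_information_pt <- function(x, y, n_levels = max(x, y)) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 100) stop("series too short for a stable MI estimate (need >= 100)")
  pxy <- tabulate((x - 1L) * n_levels + y, nbins = n_levels^2) / n
  px <- tabulate(x, nbins = n_levels) / n
  py <- tabulate(y, nbins = n_levels) / n
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  mi <- h(px) + h(py) - h(pxy)
  bias <- (pt_bayescount(pxy, n) - pt_bayescount(px, n) -
             pt_bayescount(py, n) + 1) / (2 * n * log(2))
  mi - bias
}

#' Discretize a signal into levels
#'
#' Equipopulated (quantile) levels by default, robust to heavy-tailed
#' distributions; equally-spaced bins available as an option. Duplicate
#' quantile breaks (e.g. for near-binary signals) collapse to fewer
#' effective levels; a constant signal maps to a single level.
#'
#' @param x numeric vector.
#' @param n_levels number of levels.
#' @param method `"quantile"` or `"uniform"`.
#' @return integer codes in `1:n_levels`.
#' @export
discretize_levels <- function(x, n_levels = 6,
                              method = c("quantile", "uniform")) {
  method <- match.arg(method)
  u <- sort(unique(x))
  if (length(u) == 1) return(rep(1L, length(x)))
  # few-valued signals (e.g. mostly-silent rate traces) are coded exactly
  if (length(u) <= n_levels) return(match(x, u))
  breaks <- if (method == "quantile") {
    unique(stats::quantile(x, probs = seq(0, 1, length.out = n_levels + 1),
                           names = FALSE))
  } else {
    seq(min(x), max(x), length.out = n_levels + 1)
  }
  if (length(breaks) < 3) {
    # mass so concentrated that the quantile grid degenerates: fall back to
    # equally spaced levels so distinct extremes stay distinguishable
    breaks <- seq(min(x), max(x), length.out = n_levels + 1)
  }
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Neural complexity of spontaneous activity
#'
#' Integration/segregation measure on the instantaneous firing rates: the
#' spike trains are binned (20 ms), and for each bipartition size `n` the
#' network is split into random complementary subsets of `n` and `N - n`
#' electrodes; the electrode-averaged rate signal of each part is
#' discretized (6 equipopulated levels) and their bias-corrected mutual
#' information computed. With 100 random bipartitions per `n` and `n`
#' ranging over 5, 10, ..., 30, the neural complexity is the sum over `n` of
#' the average MI. Computed per recording segment (default 5 min).
#'
#' @param spikes a [spike_train_set()]
#' @param ifr_bin firing-rate bin width (s).
#' @param partition_sizes vector of bipartition sizes `n`.
#' @param n_samples random bipartitions per size.
#' @param n_levels discretization levels.
#' @param segment_length segment length in seconds; the recording is split
#'   into consecutive segments of this length (a final partial segment is
#'   dropped unless it is the only one).
#' @param seed RNG seed for the bipartition draws.
#' @param method discretization method (see [discretize_levels()]).
#' @return object of class `neural_complexity`: list with `nc` (bits, one
#'   value per segment), `per_n` (segments x partition-size matrix of mean
#'   MI), `segments` (start times) and the parameters.
#' @export
neural_complexity <- function(spikes, ifr_bin = 0.02,
                              partition_sizes = seq(5, 30, by = 5),
                              n_samples = 100, n_levels = 6,
                              segment_length = 300, seed = 1,
                              method = "quantile") {
  stopifnot(inherits(spikes, "spike_train_set"))
  n_ch <- length(spikes$trains)
  if (n_ch <= max(partition_sizes)) {
    stop("need more electrodes than the largest partition size")
  }
  dur <- spikes$t_stop - spikes$t_start
  n_seg <- max(1L, floor(dur / segment_length))
  seg_starts <- spikes$t_start + segment_length * (seq_len(n_seg) - 1)
  seg_len <- min(segment_length, dur)
  if (seg_len / ifr_bin < 100) stop("segment shorter than 100 rate bins")
  set.seed(seed)
  per_n <- matrix(NA_real_, n_seg, length(partition_sizes),
                  dimnames = list(NULL, partition_sizes))
  for (s in seq_len(n_seg)) {
    counts <- bin_spike_counts(spikes, ifr_bin,
                               c(seg_starts[s], seg_starts[s] + seg_len))
    ifr <- counts / ifr_bin
    total <- colSums(ifr)
    for (k in seq_along(partition_sizes)) {
      n <- partition_sizes[k]
      # batch the 100 bipartition sums into one matrix product
      Z <- matrix(0, n_samples, n_ch)
      for (j in seq_len(n_samples)) Z[j, sample.int(n_ch, n)] <- 1
      part_sums <- Z %*% ifr
      mis <- numeric(n_samples)
      for (j in seq_len(n_samples)) {
        xa <- part_sums[j, ] / n
        xb <- (total - part_sums[j, ]) / (n_ch - n)
        # negative bias-corrected estimates are truncated to zero so the
        # summed complexity stays non-negative
        mis[j] <- max(0, mutual_information_pt(
          discretize_levels(xa, n_levels, method),
          discretize_levels(xb, n_levels, method), n_levels))
      }
      per_n[s, k] <- mean(mis)
    }
  }
  structure(list(nc = rowSums(per_n), per_n = per_n, segments = seg_starts,
                 ifr_bin = ifr_bin, partition_sizes = partition_sizes,
                 n_samples = n_samples, n_levels = n_levels, seed = seed),
            class = "neural_complexity")
}

#' @export
print.neural_complexity <- function(x, ...) {
  cat(sprintf("Neural complexity: %.3f bits (mean over %d segment%s)\n",
              mean(x$nc), length(x$nc), if (length(x$nc) > 1) "s" else ""))
  invisible(x)
}

#' Bootstrap threshold for significant evoked activation
#'
#' Builds the per-channel null from the pre-stimulus window: on each of
#' `n_boot` bootstrap repetitions, trials are resampled with replacement and
#' the maximum over pre-stimulus bins of the trial-mean count is recorded
#' (the max statistic controls the family-wise error over post-stimulus
#' bins); the threshold is the `1 - alpha` quantile of the `n_boot` maxima.
#' Channels silent in the pre-stimulus window receive a threshold from the
#' channel-pooled null and are flagged.
#'
#' @param tensor a [align_trials()] trial tensor (spiking counts or LFP
#'   amplitudes) whose window includes a pre-stimulus part.
#' @param n_boot bootstrap repetitions.
#' @param alpha acceptance level.
#' @param seed RNG seed.
#' @return list with `threshold` (per channel), `flagged` (0-based ids of
#'   channels given the pooled null), `n_boot`, `alpha`.
#' @export
bootstrap_activation_threshold <- function(tensor, n_boot = 500,
                                           alpha = 0.05, seed = 1) {
  stopifnot(inherits(tensor, "trial_tensor"))
  pre <- pre_bins(tensor)
  if (length(pre) == 0) stop("tensor has no pre-stimulus window")
  set.seed(seed)
  n_tr <- dim(tensor$counts)[1]
  n_ch <- dim(tensor$counts)[2]
  boot_thr <- function(M) {
    idx <- matrix(sample.int(n_tr, n_tr * n_boot, replace = TRUE), n_boot)
    W <- t(apply(idx, 1, tabulate, nbins = n_tr))
    maxima <- apply((W %*% M) / n_tr, 1, max)
    stats::quantile(maxima, 1 - alpha, names = FALSE)
  }
  thr <- numeric(n_ch)
  silent <- logical(n_ch)
  for (ch in seq_len(n_ch)) {
    M <- tensor$counts[, ch, pre, drop = TRUE]
    if (n_tr == 1) M <- matrix(M, nrow = 1)
    if (all(M == 0)) { silent[ch] <- TRUE; next }
    thr[ch] <- boot_thr(M)
  }
  if (any(silent)) {
    pooled <- apply(tensor$counts[, , pre, drop = FALSE], c(1, 3), mean)
    thr[silent] <- boot_thr(pooled)
  }
  list(threshold = thr, flagged = which(silent) - 1L,
       n_boot = n_boot, alpha = alpha)
}

#' Binary matrix of significant evoked sources
#'
#' `SS(x, t) = 1` when the trial-mean activity of channel `x` in
#' post-stimulus bin `t` exceeds that channel's bootstrap threshold. Rows
#' (channels) are then sorted by total activity, least active first
#' (bottom-to-top ordering); sorting makes the matrix invariant to channel
#' relabeling. Ties are broken by channel id.
#'
#' @param tensor a [align_trials()] trial tensor.
#' @param thresholds a [bootstrap_activation_threshold()] result computed on
#'   the same tensor.
#' @return object of class `significant_sources`: list with `matrix`
#'   (channels x post-stimulus bins, 0/1, rows in sorted order),
#'   `channel_order` (0-based ids, least active first), `p1`, `p0`.
#' @export
significant_sources <- function(tensor, thresholds) {
  stopifnot(inherits(tensor, "trial_tensor"))
  post <- post_bins(tensor)
  post_mean <- apply(tensor$counts[, , post, drop = FALSE], c(2, 3), mean)
  ss <- 1L * (post_mean > thresholds$threshold)
  act <- rowSums(ss)
  ord <- order(act, tensor$channels)
  ss <- ss[ord, , drop = FALSE]
  p1 <- mean(ss)
  structure(list(matrix = ss, channel_order = tensor$channels[ord],
                 p1 = p1, p0 = 1 - p1,
                 flagged = thresholds$flagged),
            class = "significant_sources")
}

#' @export
print.significant_sources <- function(x, ...) {
  cat(sprintf("Significant sources: %d x %d matrix, p1 = %.3f\n",
              nrow(x$matrix), ncol(x$matrix), x$p1))
  invisible(x)
}

#' @export
plot.significant_sources <- function(x, ...) {
  graphics::image(t(x$matrix), col = c("white", "black"), axes = FALSE,
                  xlab = "post-stimulus bin", ylab = "channel (sorted)", ...)
  graphics::box()
  invisible(x)
}

#' Perturbational complexity index of a significant-source matrix
#'
#' The sorted binary matrix is flattened (time-major by default: successive
#' time columns concatenated across channels) and compressed with [lz76()];
#' the word count `C` is normalized by the source entropy and the asymptotic
#' Lempel-Ziv bound: `pci = C * log2(L) / (L * Hsrc)` with
#' `L = channels * bins` (6000 for the 60-channel, 100-bin matrix). By
#' convention `pci = 0` when `Hsrc = 0` (no significant activations, or all
#' bins active).
#'
#' @param ss a [significant_sources()] result, or a plain 0/1 matrix.
#' @param flatten `"time-major"` (default) or `"row-major"`.
#' @param base logarithm base of the normalization and of `Hsrc`.
#' @param L normalization constant; defaults to the number of matrix
#'   entries.
#' @param modality label stored in the result (`"spiking"` or `"lfp"`).
#' @return object of class `pci_result`: list with `pci`, `C`, `Hsrc`, `L`,
#'   `p1`, `flatten`, `modality`.
#' @export
pci <- function(ss, flatten = c("time-major", "row-major"), base = 2,
                L = NULL, modality = "spiking") {
  flatten <- match.arg(flatten)
  m <- if (inherits(ss, "significant_sources")) ss$matrix else as.matrix(ss)
  if (is.null(L)) L <- length(m)
  seqv <- if (flatten == "time-major") as.vector(m) else as.vector(t(m))
  p1 <- mean(seqv)
  hsrc <- source_entropy(p1, base = base)
  C <- if (hsrc == 0) NA_integer_ else lz76(seqv)
  val <- if (hsrc == 0) 0 else C * log(L, base = base) / (L * hsrc)
  structure(list(pci = val, C = C, Hsrc = hsrc, L = L, p1 = p1,
                 flatten = flatten, modality = modality),
            class = "pci_result")
}

#' @export
print.pci_result <- function(x, ...) {
  cat(sprintf("PCI (%s): %.3f (C = %s, Hsrc = %.3f, L = %d)\n",
              x$modality, x$pci,
              if (is.na(x$C)) "-" else x$C, x$Hsrc, x$L))
  invisible(x)
}

#' Spiking perturbational complexity index from a stimulation session
#'
#' Full pipeline: align trials (1000 ms pre, 500 ms post, 5 ms bins, 10 ms
#' artifact blanking), bootstrap activation thresholds (500 repetitions,
#' alpha 0.05), significant-source extraction, sorting, and Lempel-Ziv
#' normalization.
#'
#' @param spikes a [spike_train_set()]
#' @param stim a [stimulation_record()]
#' @param pre,post,bin_size,blank trial-alignment parameters (s).
#' @param n_boot,alpha bootstrap parameters.
#' @param seed RNG seed for the bootstrap.
#' @param flatten,base see [pci()].
#' @return a `pci_result` with the `significant_sources` object attached as
#'   attribute `"sources"`.
#' @export
perturbational_complexity <- function(spikes, stim, pre = 1.0, post = 0.5,
                                      bin_size = 0.005, blank = 0.01,
                                      n_boot = 500, alpha = 0.05, seed = 1,
                                      flatten = "time-major", base = 2) {
  tensor <- align_trials(spikes, stim, pre, post, bin_size, blank)
  thr <- bootstrap_activation_threshold(tensor, n_boot, alpha, seed)
  ss <- significant_sources(tensor, thr)
  out <- pci(ss, flatten = flatten, base = base, modality = "spiking")
  attr(out, "sources") <- ss
  out
}

#' Align LFP trials into an amplitude tensor
#'
#' LFP counterpart of [align_trials()]: for every trial, channel and 5 ms
#' bin, the mean absolute baseline-corrected amplitude (baseline = the
#' trial's pre-stimulus mean per channel) replaces the spike count. Bins in
#' the artifact-blanking interval are zeroed.
#'
#' @param lfp an [analog_signal_set()] of kind `"lfp"`.
#' @param stim a [stimulation_record()].
#' @param pre,post,bin_size,blank window parameters (s).
#' @return a `trial_tensor` with real-valued `counts`.
#' @export
align_analog_trials <- function(lfp, stim, pre = 1.0, post = 0.5,
                                bin_size = 0.005, blank = 0.01) {
  stopifnot(inherits(lfp, "analog_signal_set"))
  fs <- lfp$sampling_rate
  n_bins <- as.integer(round((pre + post) / bin_size))
  spb <- round(bin_size * fs)
  n_pre <- round(pre * fs); n_win <- n_pre + round(post * fs)
  n_ch <- nrow(lfp$samples)
  n_tr <- stim$n_trials
  counts <- array(0, dim = c(n_tr, n_ch, n_bins))
  bt <- seq(-pre, post - bin_size, by = bin_size)
  blank_bins <- which(bt >= -1e-12 & bt < blank - 1e-12)
  for (tr in seq_len(n_tr)) {
    i0 <- round((stim$onsets[tr] - lfp$t_start) * fs) + 1L - n_pre
    if (i0 < 1 || i0 + n_win - 1 > ncol(lfp$samples)) {
      stop("trial window outside recording")
    }
    seg <- lfp$samples[, i0:(i0 + n_win - 1), drop = FALSE]
    base_mean <- rowMeans(seg[, seq_len(n_pre), drop = FALSE])
    seg <- abs(seg - base_mean)
    dim(seg) <- c(n_ch, spb, n_bins)
    counts[tr, , ] <- apply(seg, c(1, 3), mean)
    counts[tr, , blank_bins] <- 0
  }
  structure(list(counts = counts, bin_size = bin_size, pre = pre,
                 post = post, blank = blank, onsets = stim$onsets,
                 channels = seq_len(n_ch) - 1L),
            class = "trial_tensor")
}

#' LFP-based perturbational complexity index
#'
#' Identical bootstrap / significant-source / Lempel-Ziv pipeline as the
#' spiking PCI, applied to per-bin mean absolute baseline-corrected LFP
#' amplitudes instead of spike counts.
#'
#' @inheritParams perturbational_complexity
#' @param lfp an [analog_signal_set()] of kind `"lfp"` (band-passed
#'   1-300 Hz).
#' @return a `pci_result` with modality `"lfp"`.
#' @export
pci_lfp <- function(lfp, stim, pre = 1.0, post = 0.5, bin_size = 0.005,
                    blank = 0.01, n_boot = 500, alpha = 0.05, seed = 1,
                    flatten = "time-major", base = 2) {
  tensor <- align_analog_trials(lfp, stim, pre, post, bin_size, blank)
  thr <- bootstrap_activation_threshold(tensor, n_boot, alpha, seed)
  ss <- significant_sources(tensor, thr)
  out <- pci(ss, flatten = flatten, base = base, modality = "lfp")
  attr(out, "sources") <- ss
  out
}
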