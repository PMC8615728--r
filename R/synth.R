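#' Spontaneous-regime configuration for the synthetic culture generator
#'
#' Parameterizes the two spontaneous regimes the generator emulates:
#' \describe{
#'   \item{basal}{synchronized slow-oscillation-like activity: network bursts
#'     (a mother Poisson process of burst events; each electrode joins an
#'     event with `recruitment_prob`, with jittered onset) riding on sparse,
#'     homogeneous tonic firing.}
#'   \item{cch}{cholinergically desynchronized activity: bursts nearly
#'     abolished, firing dominated by heterogeneous tonic trains
#'     (log-normal rate distribution across electrodes) driven by a shared
#'     slow multiplicative rate modulation (log-Gaussian process), the
#'     minimal common-input mechanism that preserves some slow covariation
#'     while removing fine-time synchrony.}
#' }
#' The overall mean firing rate is matched across regimes (`target_mfr`): the
#' tonic rate scale is set to `target_mfr` minus the expected per-electrode
#' burst contribution, so regime contrasts are never a rate confound.
#'
#' @param regime `"basal"` or `"cch"`; selects the preset defaults below.
#' @param burst_rate network-burst events per second (basal 0.2, cch 0.02).
#' @param recruitment_prob probability an electrode joins a burst event
#'   (basal 0.9, cch 0.3).
#' @param intra_burst_rate within-burst firing rate, spikes/s (80).
#' @param burst_duration,burst_duration_sd mean and SD of burst duration (s).
#' @param burst_decay time constant (s) of the within-burst firing-rate
#'   decay from the sharp burst onset.
#' @param spike_copy_prob probability an electrode copies a given mother
#'   spike during a burst it joined (thinning).
#' @param spike_jitter_sd SD of the per-spike copy jitter (s).
#' @param onset_jitter_sd SD of per-electrode burst-onset jitter (s).
#' @param tonic_sdlog SD of log tonic rate across electrodes (basal 0.2,
#'   cch 0.8; the cch regime has the wider, heavier-tailed rate
#'   distribution).
#' @param rate_modulation_sd strength `s` of the shared log-Gaussian rate
#'   modulation `m(t) = exp(s z(t) - s^2/2)` (basal 0, cch 1).
#' @param rate_modulation_tau correlation time of the modulation (s).
#' @param target_mfr network mean firing rate both regimes are calibrated to
#'   (spikes/s per electrode).
#' @param duration recording duration in seconds.
#' @param n_electrodes number of electrodes (60-slot MEA by default).
#' @param seed RNG seed for reproducible generation.
#' @return object of class `regime_config`.
#' @export
regime_config <- function(regime = c("basal", "cch"),
                          burst_rate = NULL,
                          recruitment_prob = NULL,
                          intra_burst_rate = 80,
                          burst_duration = 0.3,
                          burst_duration_sd = 0.05,
                          burst_decay = 0.08,
                          spike_copy_prob = 0.6,
                          spike_jitter_sd = 0.002,
                          onset_jitter_sd = 0.01,
                          tonic_sdlog = NULL,
                          rate_modulation_sd = NULL,
                          rate_modulation_tau = 0.3,
                          target_mfr = 4.8,
                          duration = 600,
                          n_electrodes = 60L,
                          seed = 1L) {
  regime <- match.arg(regime)
  preset <- if (regime == "basal") {
    list(burst_rate = 0.2, recruitment_prob = 0.9, tonic_sdlog = 0.2,
         rate_modulation_sd = 0)
  } else {
    list(burst_rate = 0.02, recruitment_prob = 0.3, tonic_sdlog = 0.8,
         rate_modulation_sd = 1.0)
  }
  if (is.null(burst_rate)) burst_rate <- preset$burst_rate
  if (is.null(recruitment_prob)) recruitment_prob <- preset$recruitment_prob
  if (is.null(tonic_sdlog)) tonic_sdlog <- preset$tonic_sdlog
  if (is.null(rate_modulation_sd)) rate_modulation_sd <- preset$rate_modulation_sd
  stopifnot(burst_rate >= 0, intra_burst_rate >= 0,
            recruitment_prob >= 0, recruitment_prob <= 1,
            tonic_sdlog >= 0, rate_modulation_sd >= 0,
            target_mfr > 0, duration > 0)
  burst_contrib <- burst_rate * recruitment_prob * intra_burst_rate *
    burst_duration
  if (burst_contrib >= target_mfr) {
    stop("expected burst firing alone exceeds target_mfr; lower burst parameters")
  }
  structure(list(regime = regime, burst_rate = burst_rate,
                 recruitment_prob = recruitment_prob,
                 intra_burst_rate = intra_burst_rate,
                 burst_duration = burst_duration,
                 burst_duration_sd = burst_duration_sd,
                 burst_decay = burst_decay,
                 spike_copy_prob = spike_copy_prob,
                 spike_jitter_sd = spike_jitter_sd,
                 onset_jitter_sd = onset_jitter_sd,
                 tonic_sdlog = tonic_sdlog,
                 tonic_mean = target_mfr - burst_contrib,
                 rate_modulation_sd = rate_modulation_sd,
                 rate_modulation_tau = rate_modulation_tau,
                 target_mfr = target_mfr, duration = duration,
                 n_electrodes = as.integer(n_electrodes), seed = seed),
            class = "regime_config")
}

#' @export
print.regime_config <- function(x, ...) {
  cat(sprintf(
    "Regime config '%s': %g bursts/s (recruit %.2f), tonic %.2f sp/s (sdlog %.2f), %g s\n",
    x$regime, x$burst_rate, x$recruitment_prob, x$tonic_mean, x$tonic_sdlog,
    x$duration))
  invisible(x)
}

# smooth standardized Gaussian process on a grid: white noise convolved with a
# Gaussian kernel of SD tau, then standardized
smooth_gp <- function(n, dt, tau) {
  if (n < 2) return(rep(0, n))
  half <- max(1L, ceiling(3 * tau / dt))
  kern <- stats::dnorm(seq(-half, half) * dt, sd = tau)
  kern <- kern / sqrt(sum(kern^2))
  z <- stats::rnorm(n + 2 * half)
  z <- stats::convolve(z, rev(kern), type = "filter")
  (z - mean(z)) / stats::sd(z)
}

#' Generate spontaneous multichannel spiking activity
#'
#' Simulates a synthetic culture recording under a [regime_config()]. Network
#' bursts are a doubly stochastic mother process: burst events arrive as a
#' Poisson process; each electrode joins an event with the recruitment
#' probability, fires at the intra-burst rate for the (jittered) burst
#' duration, with per-electrode onset jitter. Tonic firing is per-electrode
#' Poisson with log-normal rates, optionally driven by a shared slow
#' multiplicative modulation (thinning algorithm).
#'
#' @param config a [regime_config()]
#' @return a [spike_train_set()] of `config$duration` seconds.
#' @export
generate_spontaneous <- function(config) {
  stopifnot(inherits(config, "regime_config"))
  set.seed(config$seed)
  n_ch <- config$n_electrodes
  dur <- config$duration
  if (config$regime == "basal" && config$burst_rate * dur < 1) {
    warning("duration too short for one expected network burst")
  }

  trains <- rep(list(numeric(0)), n_ch)

  # network bursts: a mother spike train per event, copied into each
  # recruited electrode with thinning and spike-time jitter (doubly
  # stochastic), so fine-time synchrony is a real, tunable property
  n_events <- stats::rpois(1, config$burst_rate * dur)
  if (n_events > 0 && config$intra_burst_rate > 0) {
    ev_onset <- sort(stats::runif(n_events, 0, dur))
    p_copy <- config$spike_copy_prob
    for (e in seq_len(n_events)) {
      bd <- max(0.05, stats::rnorm(1, config$burst_duration,
                                   config$burst_duration_sd))
      # mother spikes: rate decays from a sharp onset (truncated
      # exponential profile with time constant burst_decay)
      k <- stats::rpois(1, config$intra_burst_rate * bd / p_copy)
      tau <- config$burst_decay
      u <- stats::runif(k)
      mother <- -tau * log(1 - u * (1 - exp(-bd / tau)))
      member <- stats::runif(n_ch) < config$recruitment_prob
      for (ch in which(member)) {
        on <- ev_onset[e] + stats::rnorm(1, 0, config$onset_jitter_sd)
        keep <- stats::runif(k) < p_copy
        if (any(keep)) {
          tt <- mother[keep] +
            stats::rnorm(sum(keep), 0, config$spike_jitter_sd)
          trains[[ch]] <- c(trains[[ch]], on + pmax(tt, 0))
        }
      }
    }
  }

  # tonic firing: log-normal rates, shared slow modulation, thinning
  if (config$tonic_mean > 0) {
    mulog <- log(config$tonic_mean) - config$tonic_sdlog^2 / 2
    rates <- stats::rlnorm(n_ch, mulog, config$tonic_sdlog)
    # matched-MFR constraint: pin the realized tonic mean to its target so
    # regime contrasts are not confounded by rate-sampling noise
    rates <- rates * (config$tonic_mean / mean(rates))
    s <- config$rate_modulation_sd
    grid_dt <- 0.02
    n_grid <- ceiling(dur / grid_dt)
    m <- if (s > 0) {
      exp(s * smooth_gp(n_grid, grid_dt, config$rate_modulation_tau) - s^2 / 2)
    } else rep(1, n_grid)
    m_max <- max(m)
    for (ch in seq_len(n_ch)) {
      lam_max <- rates[ch] * m_max
      if (lam_max <= 0) next
      k <- stats::rpois(1, lam_max * dur)
      if (k == 0) next
      tt <- stats::runif(k, 0, dur)
      keep <- stats::runif(k) < m[pmin(floor(tt / grid_dt) + 1, n_grid)] / m_max
      trains[[ch]] <- c(trains[[ch]], tt[keep])
    }
  }

  trains <- lapply(trains, function(tr) {
    tr <- sort(tr[tr >= 0 & tr < dur])
    tr[!duplicated(tr)]
  })
  spike_train_set(trains, 0, dur)
}

#' Synthesize a local-field-potential proxy from spiking activity
#'
#' Builds a per-channel LFP-like trace at 1 kHz as the channel's spike train
#' convolved with a causal post-synaptic-potential-like kernel (difference
#' of exponentials: sharp rise, slow decay; overall width 0.2-0.5 s), plus
#' 1/f (pink) background noise. Under the basal regime the coherent
#' burst-driven rate transients put most spectral power in the delta band,
#' as in slow-oscillation-dominated cultures, while retaining measurable
#' theta-band power from the sharp burst onsets.
#'
#' @param spikes a [spike_train_set()]
#' @param kernel_decay decay time constant of the kernel in seconds; the
#'   kernel is effectively `~4 * kernel_decay` wide.
#' @param kernel_rise rise time constant in seconds.
#' @param gain microvolts per (spike/s) of instantaneous rate.
#' @param noise_sd SD of the pink background noise in microvolts (0 disables).
#' @return an [analog_signal_set()] of kind `"lfp"` at 1 kHz.
#' @export
generate_lfp_proxy <- function(spikes, kernel_decay = 0.08,
                               kernel_rise = 0.005, gain = 5,
                               noise_sd = 2) {
  stopifnot(inherits(spikes, "spike_train_set"))
  fs <- 1000
  dur <- spikes$t_stop - spikes$t_start
  n <- round(dur * fs)
  klen <- ceiling(6 * kernel_decay * fs)
  tt <- seq_len(klen) / fs
  kern <- exp(-tt / kernel_decay) - exp(-tt / kernel_rise)
  kern <- kern / (sum(kern) / fs)  # unit area: counts -> rate in spikes/s
  n_ch <- length(spikes$trains)
  out <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    tr <- spikes$trains[[ch]] - spikes$t_start
    if (length(tr)) {
      idx <- pmin(floor(tr * fs) + 1L, n)
      out[ch, ] <- gain * .spike_kernel_sum(as.integer(idx), kern, n)
    }
  }
  if (noise_sd > 0) out <- out + pink_noise(n, noise_sd, n_ch)
  analog_signal_set(out, fs, spikes$t_start, kind = "lfp")
}

# approximately 1/f-shaped Gaussian noise with SD sd; sum of three AR(1)
# processes with staggered poles (economy pink-noise filter), per channel.
# Returns an n_ch x n matrix.
pink_noise <- function(n, sd, n_ch = 1) {
  white <- matrix(stats::rnorm(n * n_ch), n, n_ch)
  x <- .pink_filter(white)
  x <- sweep(x, 2, colMeans(x))
  t(sweep(x, 2, apply(x, 2, stats::sd), `/`)) * sd
}

#' Evoked-response configuration for the synthetic generator
#'
#' Channel identities (which channels respond, with what probability and
#' latency) are drawn once from `seed` and reused across regimes, so that the
#' carbachol-like session is an amplitude-scaled version of the basal one:
#' response probabilities are multiplied by `response_scale_cch` while the
#' spatio-temporal structure (latencies, windows) is unchanged.
#'
#' @param n_channels number of electrodes.
#' @param responsive_frac fraction of channels with a stimulus-locked
#'   response.
#' @param p_early per-trial probability of the early (5-50 ms) single-spike
#'   response for responsive channels; per-channel values are drawn uniformly
#'   from `p_early * c(0.7, 1)`.
#' @param latency_range range the per-channel early latency is drawn from (s).
#' @param latency_jitter_sd Gaussian trial-to-trial latency jitter (s).
#' @param p_late per-trial probability of a late reverberant burst.
#' @param p_spread range of the per-channel multiplicative spread applied to
#'   `p_early` and `p_late` (draw once per channel); `c(1, 1)` makes all
#'   responsive channels identical.
#' @param late_window window of the late component, seconds after onset.
#' @param late_n_spikes mean spike count of a late burst.
#' @param background_rate ongoing Poisson rate per channel (spikes/s).
#' @param response_scale_cch multiplicative factor in (0, 1] applied to the
#'   early and late response probabilities under the cch regime.
#' @param n_trials number of stimuli per session.
#' @param isi inter-stimulus interval (s).
#' @param site stimulated electrode id.
#' @param seed channel-structure seed.
#' @return object of class `evoked_config`.
#' @export
evoked_config <- function(n_channels = 60L, responsive_frac = 0.7,
                          p_early = 0.8, latency_range = c(0.005, 0.05),
                          latency_jitter_sd = 0.003,
                          p_late = 0.35, p_spread = c(0.7, 1),
                          late_window = c(0.1, 0.4),
                          late_n_spikes = 8, background_rate = 0.5,
                          response_scale_cch = 0.5, n_trials = 120L,
                          isi = 5, site = 26L, seed = 1L) {
  stopifnot(responsive_frac >= 0, responsive_frac <= 1,
            p_early >= 0, p_early <= 1, p_late >= 0, p_late <= 1,
            response_scale_cch > 0, response_scale_cch <= 1,
            n_trials >= 1)
  structure(as.list(environment()), class = "evoked_config")
}

#' Generate a synthetic stimulation session
#'
#' Simulates stimulus-locked spiking: responsive channels emit an early
#' single spike at a channel-specific latency (with Gaussian jitter) and,
#' with lower probability, a late reverberant burst in the 100-400 ms window,
#' on top of ongoing Poisson background firing. Under `regime = "cch"` the
#' response probabilities are scaled by `response_scale_cch`, emulating an
#' amplitude decrease without a change in response shape.
#'
#' @param config an [evoked_config()]
#' @param regime `"basal"` or `"cch"`.
#' @param trial_seed seed for the trial-level randomness (channel structure
#'   always derives from `config$seed`); defaults to a regime-specific offset
#'   of `config$seed`.
#' @return list with elements `spikes` (a [spike_train_set()]) and `stim`
#'   (a [stimulation_record()]).
#' @export
generate_evoked <- function(config, regime = c("basal", "cch"),
                            trial_seed = NULL) {
  stopifnot(inherits(config, "evoked_config"))
  regime <- match.arg(regime)
  if (is.null(trial_seed)) {
    trial_seed <- config$seed + if (regime == "basal") 1000L else 2000L
  }
  n_ch <- config$n_channels
  # channel structure: fixed across regimes
  set.seed(config$seed)
  responsive <- stats::runif(n_ch) < config$responsive_frac
  latency <- stats::runif(n_ch, config$latency_range[1], config$latency_range[2])
  p_early <- config$p_early *
    stats::runif(n_ch, config$p_spread[1], config$p_spread[2])
  p_late <- config$p_late *
    stats::runif(n_ch, config$p_spread[1], config$p_spread[2])
  scale <- if (regime == "cch") config$response_scale_cch else 1

  set.seed(trial_seed)
  lead_in <- 2
  onsets <- lead_in + config$isi * (seq_len(config$n_trials) - 1)
  dur <- lead_in + config$isi * config$n_trials
  trains <- rep(list(numeric(0)), n_ch)
  for (ch in seq_len(n_ch)) {
    tt <- numeric(0)
    if (config$background_rate > 0) {
      k <- stats::rpois(1, config$background_rate * dur)
      if (k) tt <- stats::runif(k, 0, dur)
    }
    if (responsive[ch]) {
      hit <- stats::runif(config$n_trials) < p_early[ch] * scale
      if (any(hit)) {
        lat <- latency[ch] +
          stats::rnorm(sum(hit), 0, config$latency_jitter_sd)
        lat <- pmax(lat, 0.0005)
        tt <- c(tt, onsets[hit] + lat)
      }
      late <- stats::runif(config$n_trials) < p_late[ch] * scale
      for (tr in which(late)) {
        k <- stats::rpois(1, config$late_n_spikes)
        if (k) {
          tt <- c(tt, onsets[tr] +
                    stats::runif(k, config$late_window[1], config$late_window[2]))
        }
      }
    }
    tt <- sort(tt[tt >= 0 & tt < dur])
    trains[[ch]] <- tt[!duplicated(tt)]
  }
  list(spikes = spike_train_set(trains, 0, dur),
       stim = stimulation_record(config$site, onsets,
                                 inter_stimulus_interval = config$isi))
}

#' Generate a raw wide-band trace with inserted spike waveforms
#'
#' Fixture generator for spike-detection testing: a symmetric biphasic
#' waveform (negative then positive lobe of equal amplitude) is inserted at
#' each ground-truth spike time on top of white Gaussian noise, sampled at
#' 10 kHz. The waveform's negative peak is aligned to the spike time.
#'
#' @param spikes a [spike_train_set()] of ground-truth times.
#' @param noise_sd Gaussian noise SD in microvolts.
#' @param amplitude lobe amplitude in microvolts (so SNR = amplitude /
#'   noise_sd).
#' @param lobe_ms single-lobe duration in milliseconds.
#' @return an [analog_signal_set()] of kind `"raw"` at 10 kHz.
#' @export
generate_raw_trace <- function(spikes, noise_sd = 2.5, amplitude = 20,
                               lobe_ms = 0.4) {
  stopifnot(inherits(spikes, "spike_train_set"))
  fs <- 10000
  dur <- spikes$t_stop - spikes$t_start
  n <- round(dur * fs)
  lobe <- max(2L, round(lobe_ms / 1000 * fs))
  half_sine <- sin(pi * seq_len(lobe) / (lobe + 1))
  wav <- c(-amplitude * half_sine, amplitude * half_sine)
  peak_off <- which.min(wav) - 1L  # sample offset of the negative peak
  n_ch <- length(spikes$trains)
  out <- matrix(if (noise_sd > 0) stats::rnorm(n_ch * n, 0, noise_sd) else 0,
                n_ch, n)
  for (ch in seq_len(n_ch)) {
    tr <- spikes$trains[[ch]] - spikes$t_start
    for (t0 in tr) {
      i0 <- round(t0 * fs) + 1L - peak_off
      idx <- seq(i0, i0 + length(wav) - 1L)
      ok <- idx >= 1 & idx <= n
      out[ch, idx[ok]] <- out[ch, idx[ok]] + wav[ok]
    }
  }
  analog_signal_set(out, fs, spikes$t_start, kind = "raw")
}
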