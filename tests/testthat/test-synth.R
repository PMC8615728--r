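test_that("generation is deterministic given a seed", {
  cfg <- regime_config("basal", duration = 60, seed = 42)
  expect_identical(generate_spontaneous(cfg), generate_spontaneous(cfg))
  ecfg <- evoked_config(n_trials = 10, seed = 42)
  expect_identical(generate_evoked(ecfg, "basal"),
                   generate_evoked(ecfg, "basal"))
})

test_that("silent configurations produce empty or flat output", {
  cfg <- regime_config("cch", burst_rate = 0, intra_burst_rate = 0,
                       duration = 30, seed = 1, target_mfr = 1e-9)
  sp <- generate_spontaneous(cfg)
  expect_equal(sum(lengths(sp$trains)), 0L)
  lfp <- generate_lfp_proxy(sp, noise_sd = 0)
  expect_true(all(lfp$samples == 0))
  expect_warning(generate_spontaneous(
    regime_config("basal", duration = 2, seed = 1)), "too short")
})

test_that("regime presets produce the intended spontaneous contrast", {
  sb <- generate_spontaneous(regime_config("basal", duration = 300, seed = 21))
  sc <- generate_spontaneous(regime_config("cch", duration = 300, seed = 22))
  # matched mean firing rate by construction (within sampling noise)
  dur <- 300
  mfr_b <- sum(lengths(sb$trains)) / dur / 60
  mfr_c <- sum(lengths(sc$trains)) / dur / 60
  expect_lt(abs(mfr_b - mfr_c) / mfr_b, 0.35)
  # burst-dominated basal vs desynchronized cch
  expect_gt(bi_b <- burstiness_index(sb), 0.5)
  expect_lt(bi_c <- burstiness_index(sc), 0.45)
  expect_gt(bi_b, bi_c)
  s_b <- sttc_matrix(sb)$mean
  s_c <- sttc_matrix(sc)$mean
  expect_gt(s_b, s_c)
})

test_that("LFP proxy concentrates basal power at low frequencies", {
  sb <- generate_spontaneous(regime_config("basal", duration = 120, seed = 23,
                                           n_electrodes = 8L))
  set.seed(24)
  lfp <- generate_lfp_proxy(sb)
  psd <- welch_psd(lfp)
  frac_delta <- mean(band_power(psd, c(1, 4))) / mean(band_power(psd, c(1, 30)))
  expect_gt(frac_delta, 0.5)
  # widening the kernel moves spectral mass to lower frequencies
  set.seed(25); narrow <- generate_lfp_proxy(sb, kernel_decay = 0.03,
                                             noise_sd = 0)
  set.seed(25); wide <- generate_lfp_proxy(sb, kernel_decay = 0.3,
                                           noise_sd = 0)
  centroid <- function(l) {
    p <- welch_psd(l); sum(p$freq * p$psd[1, ]) / sum(p$psd[1, ])
  }
  expect_lt(centroid(wide), centroid(narrow))
})

test_that("evoked generator realizes its stated response structure", {
  # deterministic early response: one PSTH bin at the set latency
  cfg <- evoked_config(n_channels = 4, responsive_frac = 1, p_early = 1,
                       p_spread = c(1, 1), latency_range = c(0.022, 0.022),
                       latency_jitter_sd = 0, p_late = 0,
                       background_rate = 0, n_trials = 20, seed = 31)
  ev <- generate_evoked(cfg, "basal")
  psth <- compute_psth(ev$spikes, ev$stim)
  expect_equal(unname(psth$area), rep(1, 4))      # one spike per trial
  occupied <- which(psth$rate[1, ] > 0)
  expect_equal(occupied, 6L)                      # latency 22 ms -> bin 6
  expect_equal(psth$rate[1, 6], 1 / 0.004)        # 250 spikes/s
  # background only: flat PSTH at the background rate
  cfg0 <- evoked_config(n_channels = 30, responsive_frac = 0,
                        background_rate = 4, n_trials = 60, seed = 32)
  ev0 <- generate_evoked(cfg0, "basal")
  p0 <- compute_psth(ev0$spikes, ev0$stim)
  post_blank <- 4:100  # skip bins overlapping the 10 ms artifact blanking
  expect_lt(abs(mean(p0$rate[, post_blank]) - 4) / 4, 0.15)
  # amplitude scaling halves the response: dPA near -50% without background
  cfg5 <- evoked_config(n_channels = 30, background_rate = 0,
                        response_scale_cch = 0.5, n_trials = 120, seed = 33)
  eb <- generate_evoked(cfg5, "basal")
  ec <- generate_evoked(cfg5, "cch")
  pb <- compute_psth(eb$spikes, eb$stim)
  pc <- compute_psth(ec$spikes, ec$stim)
  dpa_total <- delta_pa(sum(pb$area), sum(pc$area))
  expect_lt(abs(dpa_total - (-50)), 7)
})
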