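# fixture: spikes placed deterministically relative to each stimulus
evoked_fixture <- function(per_trial_offsets, n_trials = 10, n_ch = 1,
                           isi = 2) {
  onsets <- 2 + isi * (0:(n_trials - 1))
  dur <- 2 + isi * n_trials
  tr <- sort(unlist(lapply(onsets, function(on) on + per_trial_offsets)))
  sp <- spike_train_set(rep(list(tr), n_ch), 0, dur)
  list(spikes = sp, stim = stimulation_record(0, onsets, isi))
}

test_that("PSTH normalization follows the spikes per trial per bin rule", {
  # 24 spikes in one bin over 120 trials -> 24 / (120 * 0.004) = 50 spikes/s
  fx <- evoked_fixture(0.05, n_trials = 120)
  idx <- sample(seq_along(fx$spikes$trains[[1]]), 96)
  tr <- sort(fx$spikes$trains[[1]][-idx])  # keep 24 of the 120 spikes
  sp <- spike_train_set(list(tr), 0, fx$spikes$t_stop)
  psth <- compute_psth(sp, fx$stim)
  bin <- floor(0.05 / 0.004) + 1
  expect_equal(psth$rate[1, bin], 24 / (120 * 0.004))
  # one spike per trial in the same bin -> area of 1 spike/trial
  p1 <- compute_psth(fx$spikes, fx$stim)
  expect_equal(unname(p1$area), 1)
  expect_equal(p1$rate[1, bin], 50 * 120 / 24)
})

test_that("PSTH area is invariant to the binning of the window", {
  set.seed(14)
  fx <- evoked_fixture(sort(runif(5, 0.02, 0.39)), n_trials = 8)
  a1 <- compute_psth(fx$spikes, fx$stim, bin_size = 0.004)$area
  a2 <- compute_psth(fx$spikes, fx$stim, bin_size = 0.01)$area
  a3 <- compute_psth(fx$spikes, fx$stim, bin_size = 0.4)$area
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("active-channel filtering keeps the area-1 boundary inclusive", {
  fx <- evoked_fixture(0.05, n_trials = 10, n_ch = 2)
  # channel 1: 10 spikes (area 1.0); channel 2: 9 spikes (area 0.9)
  fx$spikes$trains[[2]] <- fx$spikes$trains[[2]][-1]
  psth <- compute_psth(fx$spikes, fx$stim)
  expect_equal(filter_active_channels(psth), 0L)
  silent <- evoked_fixture(numeric(0), n_trials = 5)
  expect_warning(keep <- filter_active_channels(
    compute_psth(silent$spikes, silent$stim)), "no channels")
  expect_length(keep, 0)
})

test_that("delta_pa identities and scale invariance hold", {
  expect_equal(delta_pa(2, 2), 0)
  expect_equal(delta_pa(2, 0), -100)
  expect_equal(delta_pa(2, 3), 50)
  expect_true(is.na(delta_pa(0, 1)))
  # scale-free: multiplying both conditions leaves dPA unchanged
  set.seed(15)
  pa <- runif(10, 0.5, 4); pb <- runif(10, 0.5, 4)
  expect_equal(delta_pa(pa, pb), delta_pa(7 * pa, 7 * pb))
})

test_that("stability threshold is 0 +/- 0 for identical halves and falls back to 20%", {
  fx <- evoked_fixture(c(0.05, 0.12), n_trials = 20, n_ch = 3)
  th <- stability_threshold(fx$spikes, fx$stim)
  expect_equal(th$center, 0)
  expect_equal(th$sd, 0)
  fb <- stability_threshold(NULL)
  expect_true(fb$fallback)
  expect_equal(c(fb$lower, fb$upper), c(-20, 20))
})

test_that("channel classification respects the threshold band", {
  cls <- classify_channels(c(-27, 5, 30, -10), channels = 0:3)
  expect_equal(as.character(cls$class),
               c("decreased", "unchanged", "increased", "unchanged"))
  s <- attr(cls, "summary")
  expect_equal(s$pct_decreased, 25)
  expect_equal(s$median_delta_pa, median(c(-27, 5, 30, -10)))
})

test_that("stationary evoked data is insensitive to stimulation order", {
  # two interleaved synthetic sessions from one stationary generator: the
  # first-half vs second-half areas agree within trial noise
  cfg <- evoked_config(n_channels = 20, n_trials = 60, seed = 16)
  ev <- generate_evoked(cfg, "basal")
  n <- ev$stim$n_trials
  s1 <- stimulation_record(0, ev$stim$onsets[1:(n / 2)], 5)
  s2 <- stimulation_record(0, ev$stim$onsets[(n / 2 + 1):n], 5)
  p1 <- compute_psth(ev$spikes, s1)
  p2 <- compute_psth(ev$spikes, s2)
  act <- filter_active_channels(compute_psth(ev$spikes, ev$stim))
  i <- match(act, p1$channels)
  deltas <- delta_pa(p1$area[i], p2$area[i])
  expect_lt(abs(mean(deltas)), 15)
})
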