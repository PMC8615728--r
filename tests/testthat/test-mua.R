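test_that("STTC matches direct formula evaluation and basic identities", {
  # single distant spikes: both proportions 0, tiled fractions 0.002
  expect_equal(sttc(1.0, 5.0, dt = 0.01, t_range = c(0, 10)), -0.002,
               tolerance = 1e-12)
  set.seed(4)
  a <- sort(runif(25, 0, 10))
  expect_equal(sttc(a, a, 0.01, c(0, 10)), 1)
  b <- sort(runif(18, 0, 10))
  # symmetry and joint time-shift invariance
  expect_equal(sttc(a, b, 0.02, c(0, 10)), sttc(b, a, 0.02, c(0, 10)))
  expect_equal(sttc(a, b, 0.02, c(0, 10)),
               sttc(a + 3, b + 3, 0.02, c(3, 13)), tolerance = 1e-12)
  expect_true(is.na(sttc(numeric(0), b, 0.01, c(0, 10))))
})

test_that("STTC equals the brute-force tiling oracle on small trains", {
  set.seed(5)
  for (r in 1:60) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    a <- sort(runif(na, 0, 2)); b <- sort(runif(nb, 0, 2))
    dt <- runif(1, 0.005, 0.3)
    expect_equal(sttc(a, b, dt, c(0, 2)), sttc_oracle(a, b, dt, c(0, 2)),
                 tolerance = 1e-12)
  }
})

test_that("mean pairwise STTC excludes empty trains instead of zero-filling", {
  set.seed(6)
  sp <- spike_train_set(list(poisson_train(5, 20), poisson_train(5, 20),
                             numeric(0)), 0, 20)
  res <- sttc_matrix(sp)
  expect_true(is.na(res$matrix[1, 3]))
  expect_equal(res$mean, res$matrix[1, 2])
})

test_that("burst detection follows the ISI-threshold definition", {
  # 10 spikes at 5 ms ISI then a 1 s gap: one burst of 10
  tr <- c(seq(0.1, by = 0.005, length.out = 10), 1.5)
  sp <- spike_train_set(list(tr), 0, 2)
  b <- detect_bursts(sp)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_spikes, 10L)
  # two bursts 150 ms apart are not merged
  tr2 <- c(seq(0.1, by = 0.005, length.out = 6),
           seq(0.1 + 5 * 0.005 + 0.15, by = 0.005, length.out = 6))
  b2 <- detect_bursts(spike_train_set(list(sort(tr2)), 0, 2))
  expect_equal(nrow(b2), 2L)
  # sparse Poisson firing yields (essentially) no bursts
  set.seed(7)
  sp3 <- poisson_set(rep(0.5, 10), 120)
  expect_lte(nrow(detect_bursts(sp3)), 1L)
})

test_that("firing statistics cover the IBR and CV(MFR) identities", {
  tr <- seq(0.1, by = 0.005, length.out = 20)  # all spikes in one burst
  sp <- spike_train_set(list(tr), 0, 1)
  expect_equal(firing_stats(sp)$ibr, 0)
  # no bursts detected -> IBR 100%
  sp2 <- spike_train_set(list(c(0.1, 0.5, 0.9)), 0, 1)
  expect_equal(firing_stats(sp2)$ibr, 100)
  # identical MFR on all electrodes -> CV(MFR) = 0
  sp3 <- spike_train_set(rep(list(c(0.1, 0.5, 0.9)), 4), 0, 1)
  expect_equal(firing_stats(sp3)$cv_mfr, 0)
})

test_that("burstiness index anchors at 0 for uniform and 1 for packed firing", {
  # one spike per 1 s bin: perfectly uniform
  sp <- spike_train_set(list(seq(0.5, 199.5, by = 1)), 0, 200)
  expect_equal(burstiness_index(sp), 0)
  # all spikes inside the fullest 15% of bins
  tt <- sort(runif(1000, 0, 25))
  sp2 <- spike_train_set(list(tt), 0, 200)
  expect_equal(burstiness_index(sp2), 1)
  expect_true(is.na(burstiness_index(spike_train_set(list(numeric(0)), 0, 200))))
})

test_that("SPIKE synchronization matches its definition at the anchors", {
  set.seed(8)
  tr <- poisson_train(3, 30)
  sp <- spike_train_set(list(tr, tr, tr), 0, 30)
  expect_equal(spike_synchronization(sp), 1)
  # regular antiphase grids: every distance equals the adaptive window, so
  # no spike is coincident
  a <- seq(0.5, 19.5, by = 1); b <- a + 0.5
  sp2 <- spike_train_set(list(a, b), 0, 21)
  expect_equal(spike_synchronization(sp2), 0)
  expect_true(is.na(spike_synchronization(
    spike_train_set(list(numeric(0), numeric(0)), 0, 1))))
})

test_that("SPIKE synchronization equals the naive reference implementation", {
  set.seed(9)
  for (r in 1:10) {
    sp <- poisson_set(runif(3, 1, 4), 20)
    expect_equal(spike_synchronization(sp),
                 spike_sync_reference(sp$trains), tolerance = 1e-12)
  }
})

test_that("spike detection recovers inserted waveforms", {
  set.seed(10)
  gt <- lapply(1:3, function(i) sort(runif(30, 0.1, 9.9)))
  gts <- spike_train_set(gt, 0, 10)
  # noiseless trace: exact recovery at insertion times
  raw0 <- generate_raw_trace(gts, noise_sd = 0, amplitude = 20)
  det0 <- detect_spikes(raw0, f_hp = NULL)
  for (i in 1:3) {
    expect_equal(length(det0$trains[[i]]), length(gt[[i]]))
    expect_lt(max(abs(det0$trains[[i]] - gt[[i]])), 2e-4)
  }
  # SNR 8 with the default detector: high recall and precision
  raw <- generate_raw_trace(gts, noise_sd = 2.5, amplitude = 20)
  det <- detect_spikes(raw)
  for (i in 1:3) {
    d <- det$trains[[i]]; g <- gt[[i]]
    recall <- mean(vapply(g, function(t) any(abs(d - t) < 1e-3), logical(1)))
    prec <- mean(vapply(d, function(t) any(abs(g - t) < 1e-3), logical(1)))
    expect_gte(recall, 0.95)
    expect_gte(prec, 0.95)
  }
  # pure noise at k = 7: almost no false positives
  noise <- analog_signal_set(matrix(rnorm(2e5, 0, 3), 1), 10000, kind = "raw")
  fp <- length(detect_spikes(noise)$trains[[1]]) / 20
  expect_lt(fp, 0.1)
  # no spikes: detector returns empty trains
  empty <- generate_raw_trace(spike_train_set(list(numeric(0)), 0, 5),
                              noise_sd = 0)
  expect_equal(lengths(detect_spikes(empty, f_hp = NULL)$trains),
               c(`0` = 0L))
})
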