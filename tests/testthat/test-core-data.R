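test_that("electrode layout is the 60-slot corner-less 8x8 grid", {
  lay <- electrode_layout()
  expect_equal(lay$n_electrodes, 60L)
  expect_equal(lay$positions$id, 0:59)
  expect_false(any((lay$positions$row %in% c(1, 8)) &
                     (lay$positions$col %in% c(1, 8))))
  expect_equal(anyDuplicated(lay$positions[, c("row", "col")]), 0L)
  expect_error(electrode_layout(59), "must be 60")
})

test_that("spike_train_set validates ordering and bounds", {
  expect_error(spike_train_set(list(c(0.2, 0.1)), 0, 1), "strictly increasing")
  expect_error(spike_train_set(list(c(0.5, 1.0)), 0, 1), "outside")
  expect_error(spike_train_set(list(0.5), 1, 1), "t_stop")
  s <- spike_train_set(list(c(0.1, 0.2), numeric(0)), 0, 1)
  expect_s3_class(s, "spike_train_set")
  expect_equal(names(s$trains), c("0", "1"))
})

test_that("binning counts spikes in half-open bins and conserves totals", {
  s <- spike_train_set(list(c(0.010, 0.030)), 0, 0.04)
  expect_equal(as.vector(bin_spike_counts(s, 0.02)), c(1L, 1L))
  s0 <- spike_train_set(list(numeric(0)), 0, 1)
  expect_true(all(bin_spike_counts(s0, 0.1) == 0L))
  # conservation for arbitrary bin sizes
  set.seed(1)
  sp <- poisson_set(rep(20, 5), 100)
  n_total <- sum(lengths(sp$trains))
  for (b in c(0.02, 0.31, 1, 7)) {
    expect_equal(sum(bin_spike_counts(sp, b)), n_total)
  }
  expect_error(bin_spike_counts(sp, 0.1, c(5, 5)), "empty interval")
  expect_error(bin_spike_counts(sp, 10, c(0, 5)), "bin larger")
})

test_that("trial alignment bins, blanks the artifact, and rejects overlap", {
  onsets <- c(2, 4, 6)
  stim <- stimulation_record(0, onsets, inter_stimulus_interval = 2)
  sp <- spike_train_set(list(c(2.012, 4.004)), 0, 10)
  tens <- align_trials(sp, stim, pre = 1, post = 0.5, bin_size = 0.005,
                       blank = 0.01)
  expect_equal(dim(tens$counts), c(3, 1, 300))
  post <- which(bin_times(tens) >= 0)
  # spike at onset + 12 ms lands in the third post-stimulus 5 ms bin
  expect_equal(tens$counts[1, 1, post[3]], 1L)
  expect_equal(sum(tens$counts[1, , ]), 1L)
  # spike at onset + 4 ms is blanked
  expect_equal(sum(tens$counts[2, , ]), 0L)
  expect_error(align_trials(sp, stim, pre = 1.8, post = 0.5,
                            bin_size = 0.005), "overlap")
  expect_error(align_trials(sp, stim, pre = 1, post = 0.5, bin_size = 0.0043),
               "divisible")
})

test_that("trial alignment is translation invariant", {
  set.seed(2)
  tt <- sort(runif(200, 0, 30))
  onsets <- seq(3, 27, by = 3)
  delta <- 11.3
  t1 <- align_trials(spike_train_set(list(tt), 0, 40),
                     stimulation_record(0, onsets, 3), pre = 1, post = 0.5)
  t2 <- align_trials(spike_train_set(list(tt + delta), 0, 60),
                     stimulation_record(0, onsets + delta, 3),
                     pre = 1, post = 0.5)
  expect_identical(t1$counts, t2$counts)
})

test_that("spike-train CSV serialization round-trips and rejects bad input", {
  set.seed(3)
  sp <- poisson_set(c(5, 0, 2), 12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spike_trains(sp, f)
  back <- read_spike_trains(f)
  expect_equal(length(back$trains), 3L)
  expect_equal(back$t_stop, sp$t_stop)
  for (i in 1:3) {
    expect_equal(back$trains[[i]], sp$trains[[i]], tolerance = 1e-6)
  }
  # unsorted times rejected with the offending electrode named
  writeLines(c("electrode_id,time_s", "0,0.5", "0,0.2"), f)
  expect_error(read_spike_trains(f), "electrode 0")
  # out-of-range id rejected
  writeLines(c("# t_start_s=0.000000 t_stop_s=1.000000 n_electrodes=2",
               "electrode_id,time_s", "5,0.1"), f)
  expect_error(read_spike_trains(f), "out of range")
})

test_that("stimulation CSV round-trips", {
  stim <- stimulation_record(7L, seq(2, 22, by = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_stimulation(stim, f)
  back <- read_stimulation(f)
  expect_equal(back$site, 7L)
  expect_equal(back$onsets, stim$onsets, tolerance = 1e-6)
})

test_that("session phases must be disjoint and ordered", {
  ph <- session_phases(basal = c(0, 1800), cch1 = c(2400, 4200),
                       cch2 = c(4800, 6000), discard = c(1800, 2400))
  expect_named(ph, c("basal", "discard", "cch1", "cch2"))
  expect_error(session_phases(basal = c(0, 1800), cch1 = c(1700, 3000),
                              cch2 = c(3000, 4000)), "disjoint")
})
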