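session_bursts <- function(...) synth_entrainment_session(...)

test_that("entrainment recovers the configured induction delay", {
  for (true_delay in c(20, 80, 160)) {
    ses <- session_bursts(induction_delay_s = true_delay, rng_seed = 3)
    ent <- compute_entrainment(ses$bursts, ses$stimlog)
    expect_true(ent$followed)
    expect_lte(abs(ent$induction_delay_s - true_delay), 5)
  }
})

test_that("entrainment handles the degenerate regimes", {
  # baseline already at the stimulation rate: zero induction delay
  ses <- session_bursts(baseline_rate_hz = 1, stim_freq_hz = 1,
                        induction_delay_s = 0, rng_seed = 5)
  ent <- compute_entrainment(ses$bursts, ses$stimlog)
  expect_true(ent$followed)
  expect_equal(ent$induction_delay_s, 0)
  # bursts never reach the band: not followed, delay NOT_REACHED (NA)
  ses2 <- session_bursts(baseline_rate_hz = 0.1, stim_freq_hz = 1,
                         induction_delay_s = 1e4, rng_seed = 6)
  ent2 <- compute_entrainment(ses2$bursts, ses2$stimlog)
  expect_false(ent2$followed)
  expect_true(is.na(ent2$induction_delay_s))
  # no bursts at all
  ent3 <- compute_entrainment(numeric(0), ses$stimlog)
  expect_false(ent3$followed)
  expect_equal(ent3$baseline_rate_hz, 0)
})

test_that("baseline rate averages the 5 minutes before the epoch", {
  set.seed(7)
  on <- sort(runif(60, 0, 300))  # 0.2 Hz over the pre-epoch span
  sl <- stimulus_log(seq(300, 599, by = 1), 0.2, 1, "EXCITE_470",
                     epochs = data.frame(start_s = c(0, 300, 600),
                                         end_s = c(300, 600, 900),
                                         state = c("PRE", "STIM", "POST")))
  ent <- compute_entrainment(on, sl)
  expect_equal(ent$baseline_rate_hz, 60 / 300)
})

test_that("decay time matches the generator's closed-form 75% crossing", {
  for (tau in c(40, 60)) {
    ses <- session_bursts(decay_tau_s = tau, rng_seed = 11)
    ent <- compute_entrainment(ses$bursts, ses$stimlog)
    dt <- decay_time(ent, ses$bursts)
    expect_false(dt$censored)
    expect_lte(abs(dt$decay_time_s - ses$truth$decay_crossing_s), 5)
  }
  # instant cessation: rate steps down immediately
  ses0 <- session_bursts(decay_tau_s = 1e-6, rng_seed = 12)
  ent0 <- compute_entrainment(ses0$bursts, ses0$stimlog)
  dt0 <- decay_time(ent0, ses0$bursts)
  expect_lte(dt0$decay_time_s, 20)
  # constant rate forever: censored at the recording end
  on <- seq(0.5, 899.5, by = 1)
  sl <- stimulus_log(seq(300, 599), 0.2, 1, "EXCITE_470",
                     epochs = data.frame(start_s = c(0, 300, 600),
                                         end_s = c(300, 600, 900),
                                         state = c("PRE", "STIM", "POST")))
  entc <- compute_entrainment(on, sl)
  dtc <- decay_time(entc, on)
  expect_true(dtc$censored)
  expect_equal(dtc$bound_s, 300)
})

test_that("entrainment metrics are invariant to uniform time translation", {
  ses <- session_bursts(induction_delay_s = 80, rng_seed = 13)
  ent0 <- compute_entrainment(ses$bursts, ses$stimlog)
  shift <- 40
  sl2 <- stimulus_log(ses$stimlog$pulse_onsets_s + shift,
                      ses$stimlog$pulse_width_s,
                      ses$stimlog$train_frequency_hz,
                      ses$stimlog$label,
                      transform(ses$stimlog$epochs,
                                start_s = start_s + shift,
                                end_s = end_s + shift))
  ent1 <- compute_entrainment(ses$bursts + shift, sl2,
                              duration_s = ses$truth$duration_s + shift)
  expect_equal(ent1$induction_delay_s, ent0$induction_delay_s,
               tolerance = 5 / 80)
  expect_equal(ent1$followed, ent0$followed)
})

test_that("evoked bursts sort by latency with misses last", {
  pulses <- seq(10, 19, by = 1)
  sl <- stimulus_log(pulses, 0.2, 1, "EXCITE_470")
  bursts <- pulses[c(1:4, 6:10)] + 0.15  # pulse 5 misses
  ev <- sort_evoked_bursts(sl, bursts)
  expect_equal(nrow(ev$table), 10)
  expect_equal(sum(is.na(ev$table$latency_s)), 1)
  expect_true(is.na(ev$table$latency_s[10]))
  hits <- ev$table$latency_s[!is.na(ev$table$latency_s)]
  expect_equal(hits, rep(0.15, 9), tolerance = 1e-9)
  # window wider than the inter-pulse interval is truncated and flagged
  ev2 <- sort_evoked_bursts(sl, bursts, window_s = 2)
  expect_true(ev2$truncated)
  expect_equal(ev2$window_s, 1)
})

test_that("latency distribution recovery stays within 3 SE of the generator", {
  set.seed(17)
  n <- 200
  pulses <- seq(5, by = 2, length.out = n)
  lat_true <- pmax(0.02, rnorm(n, 0.15, 0.02))
  sl <- stimulus_log(pulses, 0.2, 0.5, "EXCITE_470")
  ev <- sort_evoked_bursts(sl, pulses + lat_true)
  got <- ev$table$latency_s
  expect_equal(sum(is.na(got)), 0)
  se <- sd(lat_true) / sqrt(n)
  expect_lt(abs(mean(got) - mean(lat_true)), 3 * se + 1e-12)
})

test_that("response peak profiling separates single- and double-peak responses", {
  fs <- 1000
  n_pulse <- 20
  dur <- n_pulse * 2
  pulses <- seq(0, dur - 2, by = 2)
  em <- electrode_map(1)
  make_session <- function(two_peaks) {
    x <- rnorm(dur * fs, sd = 0.5)
    for (p in pulses) {
      i <- round(p * fs) + round(0.2 * fs)
      bump <- 30 * exp(-((1:200) - 100)^2 / (2 * 30^2))
      x[i:(i + 199)] <- x[i:(i + 199)] + bump
      if (two_peaks) {
        j <- round(p * fs) + round(0.8 * fs)
        x[j:(j + 199)] <- x[j:(j + 199)] + 0.7 * bump
      }
    }
    recording(matrix(x, 1), fs, em)
  }
  sl <- stimulus_log(pulses[-1], 0.2, 0.5, "EXCITE_470")
  set.seed(19)
  rec1 <- make_session(FALSE)
  ev1 <- sort_evoked_bursts(sl, pulses + 0.2, rec = rec1)
  pr1 <- response_peak_profile(ev1)
  expect_equal(pr1$secondary_fraction, 0)
  set.seed(19)
  rec2 <- make_session(TRUE)
  ev2 <- sort_evoked_bursts(sl, pulses + 0.2, rec = rec2)
  pr2 <- response_peak_profile(ev2)
  expect_gt(pr2$secondary_fraction, 0.9)
  # two detected density peaks near 0.2 s and 0.8 s post-pulse
  expect_gte(length(pr2$density_peak_times_s), 2)
  expect_lt(abs(pr2$density_peak_times_s[1] - 0.21), 0.1)
  expect_lt(abs(pr2$density_peak_times_s[2] - 0.81), 0.1)
  # amplitude scaling leaves peak times unchanged
  rec3 <- rec2; rec3$samples <- rec3$samples * 2
  ev3 <- sort_evoked_bursts(sl, pulses + 0.2, rec = rec3)
  pr3 <- response_peak_profile(ev3)
  expect_equal(pr3$peak_times_s, pr2$peak_times_s)
})
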