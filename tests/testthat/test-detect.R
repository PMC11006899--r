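make_rec <- function(x, fs) {
  recording(matrix(x, nrow = 1), fs, electrode_map(1))
}

test_that("band filter preserves the passband and rejects the stopbands", {
  fs <- 20000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  rec <- make_rec(sin(2 * pi * 1000 * t), fs)
  out <- filter_band(rec, 300, 3000)
  mid <- 10000:30000
  expect_lt(abs(tone_amplitude(out$samples[1, mid], 1000, fs) - 1), 0.01)
  # 10 Hz tone attenuated >= 40 dB by the spike band
  rec10 <- make_rec(sin(2 * pi * 10 * t), fs)
  out10 <- filter_band(rec10, 300, 3000)
  expect_lt(20 * log10(tone_amplitude(out10$samples[1, mid], 10, fs)), -40)
  # low-pass at 1000 Hz knocks white-noise power above 1200 Hz down >= 20 dB
  set.seed(21)
  wn <- rnorm(fs)
  lp <- meadyn:::filter_band_vec(wn, fs, NULL, 1000)
  pgram <- function(x) {
    sp <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    mean(sp[f > 1200 & f < fs / 2])
  }
  expect_lt(10 * log10(pgram(lp) / pgram(wn)), -20)
  expect_error(filter_band(rec, 300, 11000), "Nyquist")
})

test_that("noise sigma estimation is robust to spike contamination", {
  set.seed(31)
  fs <- 20000
  x <- rnorm(fs * 5, sd = 10)
  expect_lt(abs(estimate_noise_sigma(x) - 10) / 10, 0.05)
  # 1% of samples replaced by large transients
  xc <- x
  hit <- sample(length(x), 0.01 * length(x))
  xc[hit] <- sample(c(-200, 200), length(hit), replace = TRUE)
  expect_lt(abs(estimate_noise_sigma(xc) - 10) / 10, 0.10)
  expect_warning(s0 <- estimate_noise_sigma(rep(0, 1000)), "constant")
  expect_equal(as.numeric(s0), 0)
})

test_that("spike detection matches the brute-force threshold-scan oracle", {
  set.seed(41)
  fs <- 20000
  cfg <- analysis_config()
  for (rep in 1:20) {
    x <- rnorm(fs, sd = 5)
    # random inserted transients
    for (i in sample(1000:(fs - 1000), 10))
      x[i:(i + 9)] <- x[i:(i + 9)] + sample(c(-1, 1), 1) * 40 *
        sin(pi * (1:10) / 10)
    sig <- estimate_noise_sigma(x)
    thr <- 5 * sig
    got <- meadyn:::detect_threshold_events(x, fs, thr, 0.001)
    expect_equal(got$time_s, oracle_spikes(x, fs, thr))
  }
})

test_that("a single inserted biphasic transient yields one spike at its extremum", {
  set.seed(42)
  fs <- 20000
  x <- rnorm(fs, sd = 10)
  tmpl <- meadyn:::spike_template(fs) * 80   # 8 sigma peak
  i0 <- 10001
  x[i0:(i0 + length(tmpl) - 1)] <- x[i0:(i0 + length(tmpl) - 1)] + tmpl
  rec <- make_rec(x, fs)
  trains <- detect_spikes(rec, prefiltered = TRUE)
  st <- trains[[1]]$spike_times_s
  true_peak <- (i0 - 1 + which.max(abs(tmpl)) - 1) / fs
  expect_equal(length(st), 1)
  expect_lt(abs(st - true_peak), 0.0005)
  expect_equal(trains[[1]]$polarity, "NEG")
  # flat zero signal: no spikes anywhere
  z <- detect_spikes(make_rec(rep(0, fs), fs), prefiltered = TRUE)
  expect_length(z[[1]]$spike_times_s, 0)
})

test_that("detection threshold follows 5 sigma of the baseline noise", {
  set.seed(43)
  fs <- 20000
  x <- rnorm(2 * fs, sd = 7)
  rec <- make_rec(x, fs)
  tr <- detect_spikes(rec, prefiltered = TRUE)[[1]]
  expect_equal(tr$threshold_used_uv, 5 * tr$sigma_uv)
  expect_lt(abs(tr$sigma_uv - 7) / 7, 0.05)
})

test_that("burst detection matches the O(n^2) sliding-window oracle", {
  cfg <- analysis_config()
  # canonical example: 5 spikes spanning 80 ms
  b <- detect_bursts(c(0, 0.02, 0.04, 0.06, 0.08), cfg)
  expect_equal(nrow(b), 1)
  expect_equal(b$onset_s, 0)
  expect_equal(b$n_spikes, 5L)
  # 4 spikes never qualify
  expect_equal(nrow(detect_bursts(c(0, 0.01, 0.02, 0.03), cfg)), 0)
  # random Poisson trains against the oracle
  set.seed(51)
  for (rate in c(5, 20, 60, 120)) {
    t <- sort(runif(rate * 10, 0, 10))
    got <- detect_bursts(t, cfg)
    want <- oracle_bursts(t)
    expect_equal(got$onset_s, want$onset_s)
    expect_equal(got$offset_s, want$offset_s)
    expect_equal(got$n_spikes, want$n_spikes)
    if (nrow(got)) {
      expect_true(all(got$n_spikes >= 5))
      if (nrow(got) > 1)  # bursts never overlap
        expect_true(all(got$onset_s[-1] > got$offset_s[-nrow(got)]))
    }
  }
})

test_that("burst rate series conserves counts", {
  on <- seq(0.5, 59.5, by = 2)
  rs <- burst_rate_series(on, 10, 60)
  expect_equal(sum(rs$count), length(on))
  expect_equal(rs$rate_hz, rep(0.5, 6))
  expect_equal(burst_rate_series(numeric(0), 10, 60)$rate_hz, rep(0, 6))
  # Poisson process: mean rate within 3 SE of the generator rate
  set.seed(61)
  r <- 2
  on <- cumsum(rexp(1000, r))
  dur <- floor(max(on))
  rs <- burst_rate_series(on[on < dur], 5, dur)
  se <- sqrt(r / (5 * nrow(rs))) / sqrt(nrow(rs)) * nrow(rs)  # SE of mean rate
  expect_lt(abs(mean(rs$rate_hz) - r), 3 * sqrt(r * dur) / dur)
})

test_that("synchronized-burst pairing recovers constructed shifts", {
  left <- c(1, 5, 9, 13)
  # identical lists: all ties at zero delay
  p0 <- pair_sync_bursts(left, left)
  expect_equal(p0$delay_s, rep(0, 4))
  expect_equal(p0$leader, rep("TIE", 4))
  # constant +120 ms shift
  p1 <- pair_sync_bursts(left, left + 0.12)
  expect_equal(p1$delay_s, rep(0.12, 4))
  expect_equal(p1$leader, rep("LEFT", 4))
  # disjoint lists: nothing pairs
  expect_equal(nrow(pair_sync_bursts(left, left + 10)), 0)
  # swap symmetry: delays negate, leaders flip
  p2 <- pair_sync_bursts(left + 0.12, left)
  expect_equal(p2$delay_s, -p1$delay_s)
  expect_equal(p2$leader, rep("RIGHT", 4))
  # each burst used at most once
  p3 <- pair_sync_bursts(c(1), c(0.9, 1.1))
  expect_equal(nrow(p3), 1)
})

test_that("inter-event-interval CV has its analytic signatures", {
  expect_equal(iei_cv(seq(0, 10, by = 0.5)), 0)
  expect_warning(v <- iei_cv(c(1, 2)), "fewer than 3")
  expect_true(is.na(v))
  # alternating intervals a, 3a: closed form on the interval sequence
  on <- cumsum(c(0, rep(c(1, 3), 50)))
  iv <- diff(on)
  expect_equal(iei_cv(on), sd(iv) / mean(iv))
  # scale invariance
  expect_equal(iei_cv(on * 7), iei_cv(on))
  # Poisson onsets: CV near 1
  set.seed(71)
  on <- cumsum(rexp(1000, 1))
  expect_lt(abs(iei_cv(on) - 1), 3 / sqrt(1000))
})

test_that("propagation speed reflects constructed lags and direction", {
  fs <- 10000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  base <- as.numeric(stats::filter(rnorm(length(t)), rep(0.2, 5),
                                   circular = TRUE))
  lag_n <- 100  # 10 ms
  em <- electrode_map(1:2, x_um = c(0, 1000), y_um = 0,
                      compartment = c("LEFT", "RIGHT"))
  delayed <- c(rep(0, lag_n), base[1:(length(base) - lag_n)])
  rec <- recording(rbind(base, delayed), fs, em)
  ps <- propagation_speed(rec, c(1, 2))
  expect_true(ps$resolved)
  expect_equal(ps$lag_s, 0.01)
  expect_equal(ps$speed_um_per_ms, 100)
  # reversed direction: same magnitude, opposite sign
  rec2 <- recording(rbind(delayed, base), fs, em)
  ps2 <- propagation_speed(rec2, c(1, 2))
  expect_equal(ps2$speed_um_per_ms, -100)
  # identical channels: unresolved at this sampling rate
  rec3 <- recording(rbind(base, base), fs, em)
  expect_false(propagation_speed(rec3, c(1, 2))$resolved)
})
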