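test_that("band reconstruction isolates single tones", {
  fs <- 1000
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  mid <- 5000:35000
  d <- band_reconstruct(x, c(0.5, 4), fs, "delta")
  expect_lt(abs(tone_amplitude(d$samples[mid], 2, fs) - 1), 0.1)
  th <- band_reconstruct(x, c(4, 8), fs, "theta")
  expect_lt(max(abs(th$samples[mid])), 0.1)
  # superposition: delta output tracks the 2 Hz component alone
  x2 <- x + 0.8 * sin(2 * pi * 50 * t)
  d2 <- band_reconstruct(x2, c(0.5, 4), fs)
  expect_gt(cor(d2$samples[mid], x[mid]), 0.95)
  # zero in, zero out
  expect_equal(band_reconstruct(rep(0, 1000), c(0.5, 4), fs)$samples,
               rep(0, 1000))
  expect_error(band_reconstruct(x, c(30, 600), fs), "Nyquist")
})

test_that("band partition approximately reconstructs the low-passed signal", {
  set.seed(81)
  fs <- 200
  x <- as.numeric(stats::filter(rnorm(fs * 30), rep(1 / 6, 6),
                                circular = TRUE))
  x <- meadyn:::filter_band_vec(x, fs, 1, 40)
  parts <- list(c(1, 4), c(4, 8), c(8, 16), c(16, 40))
  recon <- Reduce(`+`, lapply(parts, function(b)
    band_reconstruct(x, b, fs)$samples))
  mid <- (2 * fs):(28 * fs)
  resid <- x[mid] - recon[mid]
  expect_lt(sum(resid^2) / sum(x[mid]^2), 0.1)
})

test_that("band power integral matches closed forms", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 5 * t)   # whole cycles over [0, 10]
  p <- band_power_integral(x, fs)
  expect_lt(abs(p - 10 / 2) / (10 / 2), 0.01)
  expect_equal(band_power_integral(rep(0, 1000), fs), 0)
  expect_equal(band_power_integral(2 * x, fs), 4 * p)
  expect_equal(band_power_integral(x, fs, 5, 5), 0)
})

test_that("wavelet coherence is high for shared bands, low for independent noise", {
  set.seed(91)
  fs <- 100
  n <- 60 * fs
  t <- seq_len(n) / fs
  x <- sin(2 * pi * 2 * t) + 0.2 * rnorm(n)
  co_self <- wavelet_coherence(x, x, fs, freqs_hz = c(1, 2, 4))
  inner <- co_self$coherence[2, (10 * fs):(50 * fs)]
  expect_gt(stats::median(inner, na.rm = TRUE), 0.99)
  # independent white noise: median well below self-coherence
  a <- rnorm(n); b <- rnorm(n)
  co_n <- wavelet_coherence(a, b, fs, freqs_hz = c(2, 4, 8, 16))
  expect_lt(stats::median(co_n$coherence, na.rm = TRUE), 0.5)
  # shared delta + independent gamma-band noise
  sh <- sin(2 * pi * 2 * t)
  g1 <- meadyn:::filter_band_vec(rnorm(n), fs, 20, 40)
  g2 <- meadyn:::filter_band_vec(rnorm(n), fs, 20, 40)
  co <- wavelet_coherence(sh + g1, sh + g2, fs, freqs_hz = c(2, 30))
  mid <- (10 * fs):(50 * fs)
  expect_gt(stats::median(co$coherence[1, mid], na.rm = TRUE), 0.8)
  expect_lt(stats::median(co$coherence[2, mid], na.rm = TRUE),
            stats::median(co$coherence[1, mid], na.rm = TRUE))
  expect_true(all(co$coherence >= 0 & co$coherence <= 1, na.rm = TRUE))
  expect_error(wavelet_coherence(a, b[-1], fs), "equal length")
})

test_that("normalized cross-correlation has unit self-correlation at zero lag", {
  set.seed(101)
  fs <- 1000
  x <- rnorm(2000)
  cc <- normalized_xcorr(x, x, fs, 0.05)
  expect_equal(cc$peak_lag_s, 0)
  expect_equal(cc$peak_value, 1)
  # shift by k samples moves the peak to lag k
  k <- 17
  y <- c(rep(0, k), x[1:(length(x) - k)])
  cc2 <- normalized_xcorr(x, y, fs, 0.05)
  expect_equal(cc2$peak_lag_s, k / fs)
  # sign inversion gives -1 at zero lag
  cc3 <- normalized_xcorr(x, -x, fs, 0.05)
  expect_equal(cc3$values[cc3$lags_s == 0], -1)
  expect_warning(normalized_xcorr(rep(0, 100), rep(0, 100), fs),
                 "zero-variance")
})

test_that("Hilbert analytic signal recovers tone phase and envelope", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- cos(2 * pi * 5 * t)
  a <- hilbert_analytic(x, taper_frac = 0)
  mid <- 1000:9000
  expect_lt(max(abs(Mod(a[mid]) - 1)), 0.01)
  inst_f <- diff(signal::unwrap(Arg(a[mid]))) * fs / (2 * pi)
  expect_lt(abs(stats::median(inst_f) - 5), 0.05)
})

test_that("modulation index identities hold analytically", {
  # uniform distribution: MI exactly 0
  expect_equal(mi_from_distribution(rep(1, 36)), 0)
  # single-bin concentration: MI exactly 1
  expect_equal(mi_from_distribution(c(1, rep(0, 35))), 1)
  # scaling amplitudes leaves MI unchanged
  set.seed(111)
  m <- runif(36)
  expect_equal(mi_from_distribution(m), mi_from_distribution(10 * m))
  expect_true(mi_from_distribution(m) >= 0 &&
                mi_from_distribution(m) <= 1)
})

test_that("PAC modulation index detects coupled envelopes and not constant ones", {
  fs <- 500
  t <- seq(0, 100 - 1 / fs, by = 1 / fs)
  slow <- cos(2 * pi * 1.5 * t)
  # constant envelope: no coupling
  x0 <- 0.5 * sin(2 * pi * 60 * t)
  p0 <- pac_modulation_index(band_signal(slow, c(0.5, 4), fs),
                             band_signal(x0, c(30, 150), fs))
  expect_lt(p0$modulation_index, 0.01)
  # fully phase-locked envelope
  x1 <- 0.5 * (1 + cos(2 * pi * 1.5 * t)) / 2 * sin(2 * pi * 60 * t)
  p1 <- pac_modulation_index(band_signal(slow, c(0.5, 4), fs),
                             band_signal(x1, c(30, 150), fs))
  expect_gt(p1$modulation_index, p0$modulation_index * 10)
  expect_true(p1$modulation_index >= 0 && p1$modulation_index <= 1)
  expect_equal(p1$kl_distance / log(36), p1$modulation_index)
  expect_equal(sum(p1$p), 1)
  # amplitude scaling of either input leaves MI unchanged
  p2 <- pac_modulation_index(band_signal(3 * slow, c(0.5, 4), fs),
                             band_signal(5 * x1, c(30, 150), fs))
  expect_equal(p2$modulation_index, p1$modulation_index, tolerance = 1e-10)
  expect_error(pac_modulation_index(band_signal(x1, c(30, 150), fs),
                                    band_signal(slow, c(0.5, 4), fs)),
               "phase band")
})

test_that("MI is monotone in the generator's coupling strength", {
  mis <- vapply(c(0, 0.5, 1), function(chi) {
    sp <- synth_pac(duration_s = 60, chi = chi, rng_seed = 7)
    d <- band_reconstruct(sp$x, c(0.5, 4), sp$fs_hz)
    g <- band_reconstruct(sp$x, c(30, 300), sp$fs_hz)
    pac_modulation_index(d, g)$modulation_index
  }, 0)
  expect_lt(mis[1], 0.01)
  expect_true(mis[1] < mis[2] && mis[2] < mis[3])
})

test_that("phase-phase coupling is 1 for identical/offset signals and small for noise", {
  fs <- 200
  t <- seq(0, 50 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  expect_equal(delta_phase_coupling(x, x), 1)
  # constant phase offset does not reduce locking
  y <- sin(2 * pi * 2 * t + 1.2)
  expect_gt(delta_phase_coupling(x, y), 0.99)
  # independent narrow-band noise decorrelates
  set.seed(121)
  a <- meadyn:::filter_band_vec(rnorm(200 * 200), 200, 0.5, 4)
  b <- meadyn:::filter_band_vec(rnorm(200 * 200), 200, 0.5, 4)
  expect_lt(delta_phase_coupling(a, b), 0.1)
  expect_warning(v <- delta_phase_coupling(rep(0, 100), x[1:100]), "zero")
  expect_true(is.na(v))
})
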