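#' Band-limited signal container
#'
#' A 1-D signal restricted to one named frequency band, as produced by
#' [band_reconstruct()].
#'
#' @param samples numeric vector.
#' @param band length-2 numeric band edges (Hz).
#' @param sampling_rate_hz sampling rate.
#' @param name band name (e.g. `"delta"`).
#' @param electrode_id source electrode.
#' @export
band_signal <- function(samples, band, sampling_rate_hz, name = "",
                        electrode_id = NA) {
  stopifnot(length(band) == 2, band[1] < band[2])
  structure(list(samples = as.numeric(samples), band = as.numeric(band),
                 sampling_rate_hz = sampling_rate_hz, name = name,
                 electrode_id = electrode_id),
            class = "band_signal")
}

as_samples <- function(x) if (inherits(x, "band_signal")) x$samples else
  as.numeric(x)

# ---- continuous wavelet transform (analytic Morlet, omega0 = 6) ----------
#
# Torrence & Compo formulation: psi_hat(s w) = pi^(-1/4) H(w)
# exp(-(s w - w0)^2 / 2); W_n(s) computed in the Fourier domain with
# normalization sqrt(2 pi s / dt) so that white noise has flat expected
# power across scales. Fourier factor lambda = 4 pi / (w0 + sqrt(2 + w0^2))
# maps scale to equivalent Fourier period; with w0 = 6, lambda ~ 1.033.

morlet_fourier_factor <- function(omega0 = 6)
  4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Continuous wavelet transform with an analytic Morlet wavelet
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param freqs_hz center frequencies of the scales (decreasing or
#'   increasing; stored as given).
#' @param omega0 Morlet nondimensional frequency (default 6, the standard
#'   choice for neural LFP).
#' @return list with complex coefficient matrix `W` (scales x time),
#'   `freqs_hz`, `scales_s`, and `coi_s` (cone-of-influence e-folding time
#'   per sample).
#' @export
morlet_cwt <- function(x, fs, freqs_hz, omega0 = 6) {
  n <- length(x)
  dt <- 1 / fs
  lambda <- morlet_fourier_factor(omega0)
  scales <- 1 / (freqs_hz * lambda)
  npad <- 2^ceiling(log2(n))
  xhat <- stats::fft(c(x - mean(x), rep(0, npad - n)))
  w_k <- 2 * pi * fs * c(0:(npad / 2), -(npad / 2 - 1):-1) / npad
  W <- matrix(0i, nrow = length(scales), ncol = n)
  pos <- w_k > 0
  norm4 <- pi^(-1 / 4)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- numeric(npad)
    psi[pos] <- norm4 * exp(-(s * w_k[pos] - omega0)^2 / 2)
    psi <- psi * sqrt(2 * pi * s / dt)
    Wj <- stats::fft(xhat * psi, inverse = TRUE) / npad
    W[j, ] <- Wj[seq_len(n)]
  }
  t_idx <- seq_len(n) - 1
  coi <- sqrt(2) * pmin(t_idx, n - 1 - t_idx) * dt  # available e-folding time
  list(W = W, freqs_hz = freqs_hz, scales_s = scales, coi_s = coi,
       omega0 = omega0)
}

# geometric frequency grid covering [low, high] at dj octave resolution
band_freq_grid <- function(low_hz, high_hz, dj = 1 / 12) {
  n <- max(2, ceiling(log2(high_hz / low_hz) / dj) + 1)
  exp(seq(log(low_hz), log(high_hz), length.out = n))
}

#' Reconstruct the component of a signal inside one frequency band
#'
#' Inverse continuous wavelet transform restricted to the scales whose
#' center frequencies lie in `band`: the delta/theta/gamma band isolation
#' step of the LFP analysis. Energy at frequencies outside the band is
#' strongly attenuated (>= 20 dB for well-separated bands).
#'
#' @param x numeric signal (or `Recording` channel extracted by the caller).
#' @param band length-2 band edges (Hz); high edge must be below Nyquist.
#' @param fs sampling rate (Hz).
#' @param name optional band name carried into the result.
#' @param dj scale resolution in octaves (default 1/12).
#' @param omega0 Morlet parameter.
#' @return A [band_signal()].
#' @export
band_reconstruct <- function(x, band, fs, name = "", dj = 1 / 12,
                             omega0 = 6) {
  x <- as_samples(x)
  stopifnot(band[1] > 0)
  if (band[2] >= fs / 2)
    stop("band high edge ", band[2], " Hz not below Nyquist (", fs / 2, ")")
  freqs <- band_freq_grid(band[1], band[2], dj)
  cw <- morlet_cwt(x, fs, freqs, omega0)
  # T&C inverse: x_n = dj sqrt(dt) / (Cdelta pi^(-1/4)) sum_j Re(W_j)/sqrt(s_j)
  cdelta <- 0.776
  dj_eff <- log2(freqs[2] / freqs[1])
  rec <- colSums(Re(cw$W) / sqrt(cw$scales_s)) *
    dj_eff * sqrt(1 / fs) / (cdelta * pi^(-1 / 4))
  band_signal(rec, band, fs, name)
}

#' Integrated signal power over a time window
#'
#' Trapezoidal integral of x(t)^2 over `[t0, t1]`; units microvolt^2 s when
#' `x` is in microvolts.
#'
#' @param x numeric vector or [band_signal()].
#' @param fs sampling rate (ignored when `x` is a `band_signal`).
#' @param t0,t1 window bounds in seconds (defaults: whole signal).
#' @return Nonnegative scalar.
#' @export
band_power_integral <- function(x, fs = NULL, t0 = 0, t1 = NULL) {
  if (inherits(x, "band_signal")) { fs <- x$sampling_rate_hz; x <- x$samples }
  stopifnot(!is.null(fs))
  n <- length(x)
  if (is.null(t1)) t1 <- n / fs
  i0 <- max(1, floor(t0 * fs) + 1)
  i1 <- min(n, floor(t1 * fs))
  if (i1 <= i0) return(0)
  seg <- x[i0:i1]
  pracma::trapz(seq_along(seg) / fs, seg^2)
}

#' Wavelet coherence of two signals
#'
#' Magnitude-squared coherence in the time-frequency plane:
#' `|S(Wx conj(Wy))|^2 / (S|Wx|^2 S|Wy|^2)` where `S` smooths over time
#' (boxcar spanning `smoothing` wavelet periods per scale) and over 3
#' adjacent scales. The time span must exceed the Morlet's own
#' autocorrelation length (several periods) to give the estimator real
#' degrees of freedom — with too little smoothing, coherence is
#' identically 1. Values are clipped to `[0, 1]`; cells outside the cone
#' of influence are set `NA`.
#'
#' @param x,y equal-length numeric signals.
#' @param fs sampling rate (Hz).
#' @param freqs_hz frequency grid (default 32 log-spaced points covering
#'   0.5 Hz to fs/4).
#' @param smoothing time-smoothing span in wavelet periods per scale
#'   (default 6).
#' @param omega0 Morlet parameter.
#' @return list (`coherence` matrix scales x time, `freqs_hz`, `times_s`,
#'   `coi_s`).
#' @export
wavelet_coherence <- function(x, y, fs, freqs_hz = NULL, smoothing = 6,
                              omega0 = 6) {
  x <- as_samples(x); y <- as_samples(y)
  if (length(x) != length(y)) stop("signals must have equal length")
  if (is.null(freqs_hz))
    freqs_hz <- band_freq_grid(0.5, fs / 4, dj = log2(fs / 2) / 32)
  cwx <- morlet_cwt(x, fs, freqs_hz, omega0)
  cwy <- morlet_cwt(y, fs, freqs_hz, omega0)
  lambda <- morlet_fourier_factor(omega0)
  sxy <- cwx$W * Conj(cwy$W)
  sxx <- abs(cwx$W)^2
  syy <- abs(cwy$W)^2
  smooth_t <- function(m) {
    for (j in seq_len(nrow(m))) {
      win <- max(3, round(smoothing * cwx$scales_s[j] * lambda * fs))
      win <- min(win, ncol(m))
      k <- rep(1 / win, win)
      row <- m[j, ]
      if (is.complex(row))
        m[j, ] <- complex(real = stats::filter(Re(row), k, sides = 2),
                          imaginary = stats::filter(Im(row), k, sides = 2))
      else m[j, ] <- stats::filter(row, k, sides = 2)
    }
    m
  }
  smooth_s <- function(m) {
    if (nrow(m) < 3) return(m)
    out <- m
    for (j in 2:(nrow(m) - 1)) out[j, ] <- (m[j - 1, ] + m[j, ] + m[j + 1, ]) / 3
    out
  }
  S <- function(m) smooth_s(smooth_t(m))
  num <- abs(S(sxy))^2
  den <- S(sxx) * S(syy)
  coh <- num / den
  coh[!is.finite(coh)] <- NA
  coh <- pmin(pmax(coh, 0), 1)
  coh <- matrix(coh, nrow = length(freqs_hz))
  # mask cone of influence: need coi_s >= scale e-folding time
  for (j in seq_along(freqs_hz))
    coh[j, cwx$coi_s < sqrt(2) * cwx$scales_s[j]] <- NA
  list(coherence = coh, freqs_hz = freqs_hz,
       times_s = (seq_along(x) - 1) / fs, coi_s = cwx$coi_s)
}

#' Normalized cross-correlation
#'
#' Cross-correlation scaled so that two identical signals give exactly 1 at
#' zero lag (coefficient normalization): `r(k) = sum x(t) y(t+k) /
#' sqrt(sum x^2 sum y^2)`. Positive peak lag means `y` lags `x`.
#'
#' @param x,y equal-length numeric signals.
#' @param fs sampling rate (Hz).
#' @param max_lag_s maximum |lag| evaluated.
#' @return list (`lags_s`, `values`, `peak_lag_s`, `peak_value`).
#' @export
normalized_xcorr <- function(x, y, fs, max_lag_s = NULL) {
  x <- as_samples(x); y <- as_samples(y)
  if (length(x) != length(y)) stop("signals must have equal length")
  n <- length(x)
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0) {
    warning("zero-variance input: cross-correlation undefined")
    return(list(lags_s = numeric(0), values = numeric(0),
                peak_lag_s = NA_real_, peak_value = NA_real_))
  }
  maxk <- if (is.null(max_lag_s)) n - 1 else min(n - 1, round(max_lag_s * fs))
  lags <- -maxk:maxk
  vals <- vapply(lags, function(k) {
    if (k >= 0) sum(x[seq_len(n - k)] * y[seq_len(n - k) + k])
    else sum(x[seq_len(n + k) - k] * y[seq_len(n + k)])
  }, 0)
  vals <- vals / denom
  ipk <- which.max(vals)
  list(lags_s = lags / fs, values = vals, peak_lag_s = lags[ipk] / fs,
       peak_value = vals[ipk])
}

#' Analytic signal via the Hilbert transform
#'
#' FFT construction of the analytic signal; the mean is removed and a
#' cosine taper applied to `taper_frac` of each edge before transforming.
#'
#' @param x numeric signal.
#' @param taper_frac fraction of each edge tapered (default 0.01).
#' @return Complex vector; `Mod` is the instantaneous amplitude envelope,
#'   `Arg` the instantaneous phase.
#' @export
hilbert_analytic <- function(x, taper_frac = 0.01) {
  x <- as_samples(x)
  n <- length(x)
  x <- x - mean(x)
  ntap <- floor(taper_frac * n)
  if (ntap > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(ntap) / ntap))
    x[seq_len(ntap)] <- x[seq_len(ntap)] * ramp
    x[n + 1 - seq_len(ntap)] <- x[n + 1 - seq_len(ntap)] * ramp
  }
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase-amplitude coupling modulation index
#'
#' Quantifies how strongly the amplitude envelope of a fast band (e.g.
#' gamma) is modulated by the phase of a slow band (e.g. delta): Hilbert
#' phase of the slow signal is binned over `[-pi, pi)` (default 36 bins of
#' 10 degrees), the mean fast-band amplitude per bin is normalized to a
#' distribution `p`, and the Kullback-Leibler distance of `p` from uniform,
#' divided by `log(n_bins)`, gives the modulation index: 0 for no coupling,
#' 1 when all amplitude concentrates in a single bin. Empty phase bins
#' receive the global mean amplitude (conservative, biases MI toward 0) and
#' the result is flagged. `pairing` records whether phase and amplitude
#' come from the same organoid (`INTRA`) or opposite ones (`INTER`).
#'
#' @param phase_signal slow-band [band_signal()] (or numeric vector).
#' @param amplitude_signal fast-band [band_signal()] (or numeric vector) of
#'   the same length and rate.
#' @param n_bins number of phase bins.
#' @param edge_frac fraction of each signal edge excluded from binning.
#' @param pairing `"INTRA"` or `"INTER"`.
#' @return An object of class `pac_result`: list with `modulation_index`,
#'   `kl_distance`, `bin_mean_amplitude`, `p` (normalized distribution),
#'   `bin_centers_rad`, `n_bins`, `empty_bins`, band descriptors and
#'   `pairing`.
#' @export
pac_modulation_index <- function(phase_signal, amplitude_signal, n_bins = 36,
                                 edge_frac = 0.01, pairing = "INTRA") {
  ph_band <- if (inherits(phase_signal, "band_signal")) phase_signal$band
  am_band <- if (inherits(amplitude_signal, "band_signal"))
    amplitude_signal$band
  xp <- as_samples(phase_signal)
  xa <- as_samples(amplitude_signal)
  if (length(xp) != length(xa)) stop("signals must have equal length")
  if (!is.null(ph_band) && !is.null(am_band) && ph_band[1] >= am_band[1])
    stop("phase band must be lower than amplitude band")
  phase <- Arg(hilbert_analytic(xp))
  amp <- Mod(hilbert_analytic(xa))
  n <- length(phase)
  drop <- floor(edge_frac * n)
  keep <- (drop + 1):(n - drop)
  phase <- phase[keep]; amp <- amp[keep]
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  bin <- findInterval(phase, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1; bin[bin > n_bins] <- n_bins
  m <- vapply(seq_len(n_bins),
              function(b) if (any(bin == b)) mean(amp[bin == b]) else NA_real_,
              0)
  empty <- which(is.na(m))
  if (length(empty)) m[empty] <- mean(amp)
  p <- m / sum(m)
  # KL(P || U) = log N - H(P)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  kl <- max(0, log(n_bins) - h)
  structure(list(modulation_index = kl / log(n_bins), kl_distance = kl,
                 bin_mean_amplitude = m, p = p,
                 bin_centers_rad = (edges[-1] + edges[-length(edges)]) / 2,
                 n_bins = n_bins, empty_bins = empty,
                 phase_band = ph_band, amplitude_band = am_band,
                 pairing = pairing),
            class = "pac_result")
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("PAC modulation index: %.4f (KL %.4f over %d bins, %s)\n",
              x$modulation_index, x$kl_distance, x$n_bins, x$pairing))
  if (length(x$empty_bins))
    cat("  note:", length(x$empty_bins), "empty phase bin(s) filled with",
        "global mean amplitude\n")
  invisible(x)
}

#' Modulation index of an explicit phase-bin distribution
#'
#' Computes `KL(P||U)/log(n)` directly from a vector of per-bin amplitudes
#' (analytic identities: uniform -> 0, single-bin concentration -> 1).
#'
#' @param m nonnegative per-bin mean amplitudes.
#' @return Modulation index in `[0, 1]`.
#' @export
mi_from_distribution <- function(m) {
  stopifnot(all(m >= 0), sum(m) > 0)
  p <- m / sum(m)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  max(0, log(length(m)) - h) / log(length(m))
}

#' Phase-phase coupling (phase-locking value) of two band signals
#'
#' `|mean(exp(i (phi_x - phi_y)))|` over Hilbert phases: 1 for identical or
#' constant-offset phase evolution, approaching 0 for independent signals.
#'
#' @param x,y equal-length band-limited signals (e.g. both delta band).
#' @return PLV in `[0, 1]`, or `NA` with a warning for zero signals.
#' @export
delta_phase_coupling <- function(x, y) {
  xs <- as_samples(x); ys <- as_samples(y)
  if (length(xs) != length(ys)) stop("signals must have equal length")
  if (all(xs == 0) || all(ys == 0)) {
    warning("zero signal: phase undefined")
    return(NA_real_)
  }
  px <- Arg(hilbert_analytic(xs))
  py <- Arg(hilbert_analytic(ys))
  min(1, Mod(mean(exp(1i * (px - py)))))
}
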