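#' Zero-phase band filtering of a recording
#'
#' Applies a 4th-order Butterworth filter forward and backward
#' (zero-phase), so that spike times, inter-compartment delays and
#' phase-based measures are not biased by filter group delay. Either edge
#' may be `NULL` to obtain a pure low-/high-pass.
#'
#' @param rec a `Recording`.
#' @param low_hz,high_hz band edges in Hz (`NULL` for open edge).
#' @param channels optional channel subset (indices).
#' @param order filter order (default 4).
#' @return A `Recording` with filtered samples, same shape and rate.
#' @export
filter_band <- function(rec, low_hz = NULL, high_hz = NULL, channels = NULL,
                        order = 4) {
  stopifnot(inherits(rec, "Recording"))
  if (is.null(channels)) channels <- seq_len(nrow(rec$samples))
  out <- rec$samples
  for (ch in channels)
    out[ch, ] <- filter_band_vec(rec$samples[ch, ], rec$sampling_rate_hz,
                                 low_hz, high_hz, order)
  rec$samples <- out
  rec
}

# vector core shared by filter_band and internal callers
filter_band_vec <- function(x, fs, low_hz = NULL, high_hz = NULL, order = 4) {
  nyq <- fs / 2
  if (is.null(low_hz) && is.null(high_hz))
    stop("at least one band edge required")
  for (e in c(low_hz, high_hz))
    if (e >= nyq) stop("band edge ", e, " Hz >= Nyquist (", nyq, " Hz)")
  if (!is.null(low_hz) && !is.null(high_hz)) {
    if (low_hz >= high_hz) stop("low edge must be below high edge")
    # cascade high-pass + low-pass: stable at extreme edge ratios
    # (300/10000 vs 3000/10000) where a direct bandpass design degrades
    bh <- signal::butter(order, low_hz / nyq, type = "high")
    bl <- signal::butter(order, high_hz / nyq, type = "low")
    x <- signal::filtfilt(bh, x)
    signal::filtfilt(bl, x)
  } else if (is.null(low_hz)) {
    signal::filtfilt(signal::butter(order, high_hz / nyq, type = "low"), x)
  } else {
    signal::filtfilt(signal::butter(order, low_hz / nyq, type = "high"), x)
  }
}

#' Robust baseline-noise SD of a spike-band signal
#'
#' Estimates the SD of the baseline noise ("quiescent" sigma). The default
#' strategy is the MAD-based robust estimator `median(|x - median(x)|) /
#' 0.6745`, which approximates the quiescent SD when spikes occupy a small
#' fraction of samples and needs no explicit quiescent-period marking; a
#' plain SD over user-marked quiescent epochs is available as an
#' alternative.
#'
#' @param x numeric vector, spike-band filtered signal.
#' @param strategy `"mad"` (default) or `"sd"`.
#' @param quiescent_epochs for `strategy = "sd"`, a `data.frame(start_s,
#'   end_s)` of quiescent spans.
#' @param fs sampling rate, required with `quiescent_epochs`.
#' @return Estimated sigma (same units as `x`); attribute `flag = "constant"`
#'   when the signal has no variation.
#' @export
estimate_noise_sigma <- function(x, strategy = c("mad", "sd"),
                                 quiescent_epochs = NULL, fs = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "sd" && !is.null(quiescent_epochs)) {
    stopifnot(!is.null(fs))
    idx <- unlist(lapply(seq_len(nrow(quiescent_epochs)), function(i) {
      seq(floor(quiescent_epochs$start_s[i] * fs) + 1,
          floor(quiescent_epochs$end_s[i] * fs))
    }))
    x <- x[idx]
    s <- stats::sd(x)
  } else {
    s <- stats::median(abs(x - stats::median(x))) / 0.6745
  }
  if (!is.finite(s) || s == 0) {
    warning("constant signal: sigma = 0")
    s <- 0
    attr(s, "flag") <- "constant"
  }
  s
}

#' Spike train container
#' @param electrode_id electrode identifier (or compartment label for pooled
#'   trains).
#' @param spike_times_s strictly increasing spike times (s).
#' @param polarity per-spike `"POS"`/`"NEG"` (extremum sign).
#' @param threshold_used_uv,sigma_uv detection threshold and noise SD.
#' @export
spike_train <- function(electrode_id, spike_times_s,
                        polarity = rep("NEG", length(spike_times_s)),
                        threshold_used_uv = NA_real_, sigma_uv = NA_real_) {
  if (length(spike_times_s) > 1 && any(diff(spike_times_s) <= 0))
    stop("spike times must be strictly increasing")
  structure(list(electrode_id = electrode_id,
                 spike_times_s = as.numeric(spike_times_s),
                 polarity = polarity,
                 threshold_used_uv = threshold_used_uv,
                 sigma_uv = sigma_uv),
            class = "spike_train")
}

#' Threshold spike detection
#'
#' Detects extracellular spikes channel by channel: the signal is band-pass
#' filtered to the spike band (unless `prefiltered`), the baseline noise SD
#' sigma is estimated, and every contiguous excursion beyond +/-
#' `spike_threshold_sigma` x sigma is reduced to a single event at its
#' extremum. Events closer than `refractory_s` on one electrode are merged
#' (largest extremum kept) to avoid double-counting multiphasic waveforms.
#'
#' @param rec a `Recording` (raw, or spike-band filtered with
#'   `prefiltered = TRUE`).
#' @param cfg an [analysis_config()].
#' @param prefiltered set `TRUE` when `rec` is already spike-band filtered.
#' @param refractory_s minimum separation between events on one electrode.
#' @return A list of [spike_train()], one per channel, in channel order.
#' @export
detect_spikes <- function(rec, cfg = analysis_config(), prefiltered = FALSE,
                          refractory_s = 0.001) {
  stopifnot(inherits(rec, "Recording"))
  fs <- rec$sampling_rate_hz
  lapply(seq_len(nrow(rec$samples)), function(ch) {
    x <- rec$samples[ch, ]
    if (!prefiltered)
      x <- filter_band_vec(x, fs, cfg$spike_band_hz[1],
                           min(cfg$spike_band_hz[2], 0.45 * fs))
    sig <- suppressWarnings(estimate_noise_sigma(x))
    thr <- cfg$spike_threshold_sigma * sig
    ev <- detect_threshold_events(x, fs, thr, refractory_s)
    spike_train(rec$electrode_map$electrode_id[ch], ev$time_s, ev$polarity,
                threshold_used_uv = thr, sigma_uv = as.numeric(sig))
  })
}

# contiguous supra-threshold excursions -> extremum times; then refractory
# merge keeping the larger extremum of each colliding pair
detect_threshold_events <- function(x, fs, thr, refractory_s) {
  empty <- list(time_s = numeric(0), polarity = character(0),
                amp = numeric(0))
  if (thr <= 0) return(empty)
  over <- abs(x) > thr
  if (!any(over)) return(empty)
  d <- diff(c(FALSE, over, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1
  idx <- amp <- numeric(length(starts))
  for (k in seq_along(starts)) {
    seg <- starts[k]:ends[k]
    j <- seg[which.max(abs(x[seg]))]
    idx[k] <- j
    amp[k] <- x[j]
  }
  # refractory merge
  keep <- rep(TRUE, length(idx))
  last <- 1
  for (k in seq_along(idx)[-1]) {
    if ((idx[k] - idx[last]) / fs < refractory_s) {
      if (abs(amp[k]) > abs(amp[last])) {
        keep[last] <- FALSE
        last <- k
      } else keep[k] <- FALSE
    } else last <- k
  }
  list(time_s = (idx[keep] - 1) / fs,
       polarity = ifelse(amp[keep] > 0, "POS", "NEG"),
       amp = amp[keep])
}

#' Burst detection on one spike train
#'
#' A burst is counted when at least `burst_min_spikes` spikes fall within a
#' `burst_window_s` window (defaults: 5 spikes in 100 ms). Overlapping or
#' chained qualifying windows are merged into one maximal event, so reported
#' bursts never overlap and each contains at least the minimum spike count;
#' merged bursts may span longer than the defining window.
#'
#' @param train a [spike_train()] (or numeric vector of spike times).
#' @param cfg an [analysis_config()].
#' @return `data.frame(electrode_id, onset_s, offset_s, n_spikes,
#'   peak_rate_hz)`, one row per burst.
#' @export
detect_bursts <- function(train, cfg = analysis_config()) {
  t <- if (inherits(train, "spike_train")) train$spike_times_s
       else as.numeric(train)
  id <- if (inherits(train, "spike_train")) train$electrode_id else NA
  k <- cfg$burst_min_spikes
  w <- cfg$burst_window_s
  n <- length(t)
  empty <- data.frame(electrode_id = id[0], onset_s = numeric(0),
                      offset_s = numeric(0), n_spikes = integer(0),
                      peak_rate_hz = numeric(0))
  if (n < k) return(empty)
  # spike i starts a qualifying window when spike i+k-1 falls within w
  qual <- which(t[seq_len(n - k + 1) + k - 1] - t[seq_len(n - k + 1)] <= w)
  if (!length(qual)) return(empty)
  # indices covered by qualifying windows: [i, i+k-1]; merge overlapping
  lo <- qual
  hi <- qual + k - 1
  m_lo <- lo[1]; m_hi <- hi[1]
  out <- list()
  flush <- function(a, b) {
    seg <- t[a:b]
    # peak rate: max spikes in any w-window inside the burst, per second
    cnt <- max(vapply(seg, function(s) sum(seg >= s & seg < s + w), 0L))
    data.frame(electrode_id = id, onset_s = seg[1], offset_s = seg[length(seg)],
               n_spikes = b - a + 1L, peak_rate_hz = cnt / w)
  }
  for (j in seq_along(lo)[-1]) {
    if (lo[j] <= m_hi) {           # windows share at least one spike
      m_hi <- max(m_hi, hi[j])
    } else {
      out[[length(out) + 1]] <- flush(m_lo, m_hi)
      m_lo <- lo[j]; m_hi <- hi[j]
    }
  }
  out[[length(out) + 1]] <- flush(m_lo, m_hi)
  do.call(rbind, out)
}

#' Population bursts of a compartment
#'
#' Pools detected spikes across all electrodes of one compartment and
#' applies the same burst rule to the pooled train.
#'
#' @param trains list of [spike_train()] in recording channel order.
#' @param rec the `Recording` the trains came from.
#' @param compartment `"LEFT"` or `"RIGHT"`.
#' @param cfg an [analysis_config()].
#' @return Burst table as in [detect_bursts()], `electrode_id` set to the
#'   compartment label.
#' @export
population_bursts <- function(trains, rec, compartment,
                              cfg = analysis_config()) {
  ch <- compartment_channels(rec, compartment)
  if (!length(ch)) stop("no electrodes in compartment ", compartment)
  pooled <- sort(unlist(lapply(trains[ch], function(tr) tr$spike_times_s)))
  pooled <- pooled[!duplicated(pooled)]
  b <- detect_bursts(pooled, cfg)
  if (nrow(b)) b$electrode_id <- compartment
  b
}

#' Burst rate time series
#'
#' Counts bursts per fixed bin and divides by the bin width; the series sums
#' back to the burst count times nothing lost (`sum(counts) == n bursts`).
#'
#' @param bursts burst table ([detect_bursts()]) or numeric onset vector.
#' @param bin_s bin width in seconds.
#' @param duration_s total duration covered by the series.
#' @return `data.frame(t_s, rate_hz, count)`; `t_s` is the bin start.
#' @export
burst_rate_series <- function(bursts, bin_s, duration_s) {
  stopifnot(bin_s > 0, duration_s > 0)
  on <- if (is.data.frame(bursts)) bursts$onset_s else as.numeric(bursts)
  edges <- seq(0, by = bin_s, length.out = ceiling(duration_s / bin_s) + 1)
  cnt <- if (length(on))
    tabulate(findInterval(on, edges, rightmost.closed = FALSE),
             nbins = length(edges) - 1)
  else rep(0L, length(edges) - 1)
  data.frame(t_s = edges[-length(edges)], rate_hz = cnt / bin_s, count = cnt)
}

#' Pair synchronized bursts between the two organoid compartments
#'
#' Greedy nearest-onset matching: candidate pairs within
#' `pairing_window_s` are taken in order of increasing onset difference,
#' each burst used at most once. `delay_s` is right onset minus left onset,
#' so positive delays mean the left organoid led; the leader is `TIE` when
#' `|delay| <= tie_epsilon_s`.
#'
#' @param left_bursts,right_bursts burst tables or onset vectors, sorted.
#' @param pairing_window_s maximum |onset difference| for a pair (default
#'   0.3 s, wide enough for the observed 100-200 ms inter-organoid delays).
#' @param tie_epsilon_s delays within this of zero count as ties.
#' @return `data.frame(left_onset_s, right_onset_s, delay_s, leader)`.
#' @export
pair_sync_bursts <- function(left_bursts, right_bursts,
                             pairing_window_s = 0.3, tie_epsilon_s = 0.01) {
  lon <- if (is.data.frame(left_bursts)) left_bursts$onset_s
         else as.numeric(left_bursts)
  ron <- if (is.data.frame(right_bursts)) right_bursts$onset_s
         else as.numeric(right_bursts)
  empty <- data.frame(left_onset_s = numeric(0), right_onset_s = numeric(0),
                      delay_s = numeric(0), leader = character(0))
  if (!length(lon) || !length(ron)) return(empty)
  cand <- expand.grid(i = seq_along(lon), j = seq_along(ron))
  cand$delay <- ron[cand$j] - lon[cand$i]
  cand <- cand[abs(cand$delay) <= pairing_window_s, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(abs(cand$delay)), , drop = FALSE]
  used_l <- logical(length(lon)); used_r <- logical(length(ron))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_l[i] || used_r[j]) next
    used_l[i] <- used_r[j] <- TRUE
    d <- cand$delay[r]
    rows[[length(rows) + 1]] <- data.frame(
      left_onset_s = lon[i], right_onset_s = ron[j], delay_s = d,
      leader = if (d > tie_epsilon_s) "LEFT"
               else if (d < -tie_epsilon_s) "RIGHT" else "TIE")
  }
  out <- do.call(rbind, rows)
  out[order(out$left_onset_s), , drop = FALSE]
}

#' Coefficient of variation of burst inter-event intervals
#'
#' SD over mean of inter-onset intervals; 0 for perfectly periodic
#' bursting, ~1 for Poisson bursting, larger for clustered/complex
#' patterns.
#'
#' @param bursts burst table or onset vector with at least 3 onsets.
#' @return CV (>= 0), or `NA` with a warning when fewer than 3 bursts.
#' @export
iei_cv <- function(bursts) {
  on <- if (is.data.frame(bursts)) bursts$onset_s else as.numeric(bursts)
  if (length(on) < 3) {
    warning("iei_cv undefined for fewer than 3 bursts")
    return(NA_real_)
  }
  iv <- diff(sort(on))
  stats::sd(iv) / mean(iv)
}

#' Signal propagation speed between two electrodes
#'
#' Cross-correlates the two channels' LFP traces over a window, takes the
#' lag of the (normalized) cross-correlation peak and divides the
#' inter-electrode distance by it. A zero-lag peak with nonzero distance
#' means propagation is unresolved at this sampling rate (lower bound
#' flagged).
#'
#' @param rec a `Recording` (LFP-filtered or raw).
#' @param channel_pair length-2 channel indices (from, to).
#' @param window_s optional `c(start_s, end_s)` window containing the event.
#' @param max_lag_s maximum lag searched.
#' @return list with `speed_um_per_ms` (signed: positive = from first to
#'   second channel), `lag_s`, `distance_um`, `resolved` (logical).
#' @export
propagation_speed <- function(rec, channel_pair, window_s = NULL,
                              max_lag_s = 0.05) {
  stopifnot(length(channel_pair) == 2)
  fs <- rec$sampling_rate_hz
  if (is.null(window_s)) window_s <- c(0, rec_duration(rec))
  i0 <- floor(window_s[1] * fs) + 1
  i1 <- floor(window_s[2] * fs)
  x <- rec$samples[channel_pair[1], i0:i1]
  y <- rec$samples[channel_pair[2], i0:i1]
  em <- rec$electrode_map
  dx <- em$x_um[channel_pair[2]] - em$x_um[channel_pair[1]]
  dy <- em$y_um[channel_pair[2]] - em$y_um[channel_pair[1]]
  dist_um <- sqrt(dx^2 + dy^2)
  cc <- normalized_xcorr(x, y, fs, max_lag_s)
  lag <- cc$lags_s[which.max(cc$values)]
  if (lag == 0) {
    return(list(speed_um_per_ms = Inf, lag_s = 0, distance_um = dist_um,
                resolved = FALSE))
  }
  # positive lag: y lags x -> propagation from channel 1 to channel 2
  list(speed_um_per_ms = dist_um / (lag * 1000), lag_s = lag,
       distance_um = dist_um, resolved = TRUE)
}
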