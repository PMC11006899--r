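#' Sliding-window burst rate
#'
#' Burst counts in windows of `window_s` placed every `step_s`, divided by
#' the window length. `align = "start"` reports each window at its start
#' time (used for induction analysis); `align = "center"` centers the
#' window on the reported time (used for decay analysis, where centering
#' makes the smoothed crossing of an exponential decay nearly unbiased).
#'
#' @param onsets burst onset times (s) or a burst table.
#' @param duration_s series span.
#' @param window_s window length (default 30 s).
#' @param step_s grid step (default 5 s).
#' @param align `"start"` or `"center"`.
#' @return `data.frame(t_s, rate_hz)`.
#' @export
sliding_burst_rate <- function(onsets, duration_s, window_s = 30,
                               step_s = 5, align = c("start", "center")) {
  align <- match.arg(align)
  on <- if (is.data.frame(onsets)) onsets$onset_s else as.numeric(onsets)
  tt <- seq(0, duration_s, by = step_s)
  lo <- if (align == "start") tt else tt - window_s / 2
  hi <- lo + window_s
  rate <- vapply(seq_along(tt), function(i)
    sum(on >= lo[i] & on < hi[i]) / window_s, 0)
  data.frame(t_s = tt, rate_hz = rate)
}

stim_epoch_of <- function(stimlog) {
  ep <- stimlog$epochs
  if (!is.null(ep) && any(ep$state == "STIM")) {
    row <- ep[ep$state == "STIM", ][1, ]
    return(c(row$start_s, row$end_s))
  }
  if (!length(stimlog$pulse_onsets_s)) stop("stimulus log has no epoch")
  c(stimlog$pulse_onsets_s[1],
    max(stimlog$pulse_onsets_s) + 1 / stimlog$train_frequency_hz)
}

#' Entrainment of burst rate to a stimulus train
#'
#' Tracks the burst rate in sliding windows (default 30 s every 5 s) and
#' declares the network "following" the stimulus once the rate stays within
#' a tolerance band (default +/-20%) of the stimulation frequency for at
#' least `n_consecutive` consecutive windows. The induction delay is the
#' time from stimulation onset to the start of the first qualifying run
#' (zero when the rate is already in band at onset); the baseline rate is
#' the mean over the `baseline_span_s` before the epoch.
#'
#' @param bursts burst onsets (vector or table).
#' @param stimlog a [stimulus_log()] with a `STIM` epoch (or pulses).
#' @param duration_s total session length; inferred from the epochs when
#'   absent.
#' @param window_s,step_s sliding-window parameters.
#' @param tolerance_frac half-width of the rate band around the stimulus
#'   frequency.
#' @param n_consecutive qualifying windows required.
#' @param baseline_span_s span before the epoch used for the baseline rate
#'   (default 300 s).
#' @return An object of class `entrainment_result`: `followed`,
#'   `induction_delay_s` (`NA` when not reached), `sustained_epoch`,
#'   `baseline_rate_hz`, `stim_frequency_hz`, `stim_epoch`, `rate_series`
#'   and the parameters.
#' @export
compute_entrainment <- function(bursts, stimlog, duration_s = NULL,
                                window_s = 30, step_s = 5,
                                tolerance_frac = 0.2, n_consecutive = 3,
                                baseline_span_s = 300) {
  on <- if (is.data.frame(bursts)) bursts$onset_s else as.numeric(bursts)
  epoch <- stim_epoch_of(stimlog)
  f <- stimlog$train_frequency_hz
  if (is.null(duration_s))
    duration_s <- if (!is.null(stimlog$epochs)) max(stimlog$epochs$end_s)
                  else max(c(on, epoch[2])) + window_s
  rs <- sliding_burst_rate(on, duration_s, window_s, step_s, "start")
  inband <- abs(rs$rate_hz - f) <= tolerance_frac * f
  # runs of consecutive in-band windows
  runs <- rle(inband)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  qual <- which(runs$values & runs$lengths >= n_consecutive)
  induction <- NA_real_
  sustained <- NULL
  followed <- FALSE
  for (q in qual) {
    t0 <- rs$t_s[starts[q]]
    t1 <- rs$t_s[ends[q]] + window_s
    if (t1 <= epoch[1] || t0 >= epoch[2]) next  # run outside the epoch
    induction <- max(0, t0 - epoch[1])
    sustained <- c(max(t0, epoch[1]), min(t1, epoch[2]))
    followed <- TRUE
    break
  }
  if (followed && induction > epoch[2] - epoch[1]) {
    followed <- FALSE; induction <- NA_real_; sustained <- NULL
  }
  b0 <- max(0, epoch[1] - baseline_span_s)
  base <- if (epoch[1] > b0) sum(on >= b0 & on < epoch[1]) / (epoch[1] - b0)
          else 0
  structure(list(followed = followed, induction_delay_s = induction,
                 sustained_epoch = sustained, baseline_rate_hz = base,
                 stim_frequency_hz = f, stim_epoch = epoch,
                 rate_series = rs, duration_s = duration_s,
                 window_s = window_s, step_s = step_s,
                 tolerance_frac = tolerance_frac,
                 n_consecutive = n_consecutive),
            class = "entrainment_result")
}

#' @export
print.entrainment_result <- function(x, ...) {
  cat(sprintf("Entrainment vs %g Hz stimulation [%g, %g] s\n",
              x$stim_frequency_hz, x$stim_epoch[1], x$stim_epoch[2]))
  if (x$followed)
    cat(sprintf("  followed: induction delay %.1f s (baseline %.3g Hz)\n",
                x$induction_delay_s, x$baseline_rate_hz))
  else cat("  not followed (induction NOT_REACHED)\n")
  invisible(x)
}

#' Post-stimulation burst-rate decay time
#'
#' Time after stimulation cessation until the smoothed burst rate first
#' drops below 75% of the maximum rate attained during the stimulation
#' epoch. The smoothing is a centered moving average of the same width as
#' the induction analysis (default 30 s, 5 s grid). When the rate never
#' drops below the criterion before the recording ends, the result is
#' censored at the recording-end bound.
#'
#' @param result an [compute_entrainment()] result.
#' @param bursts the same burst onsets.
#' @param criterion_frac decay criterion (default 0.75).
#' @return list with `decay_time_s` (`NA` when censored), `censored`,
#'   `bound_s` (recording-end bound when censored), `max_rate_hz`,
#'   `criterion_rate_hz`.
#' @export
decay_time <- function(result, bursts, criterion_frac = 0.75) {
  stopifnot(inherits(result, "entrainment_result"))
  if (!result$followed)
    stop("decay time requires a followed entrainment result")
  on <- if (is.data.frame(bursts)) bursts$onset_s else as.numeric(bursts)
  epoch <- result$stim_epoch
  rs <- sliding_burst_rate(on, result$duration_s, result$window_s,
                           result$step_s, "center")
  in_epoch <- rs$t_s >= epoch[1] + result$window_s / 2 &
    rs$t_s <= epoch[2] - result$window_s / 2
  if (!any(in_epoch)) in_epoch <- rs$t_s >= epoch[1] & rs$t_s <= epoch[2]
  max_rate <- max(rs$rate_hz[in_epoch])
  crit <- criterion_frac * max_rate
  # windows reaching past the recording end would dilute the rate
  post <- which(rs$t_s >= epoch[2] &
                  rs$t_s + result$window_s / 2 <= result$duration_s + 1e-9)
  below <- post[rs$rate_hz[post] < crit]
  if (!length(below))
    return(list(decay_time_s = NA_real_, censored = TRUE,
                bound_s = result$duration_s - epoch[2],
                max_rate_hz = max_rate, criterion_rate_hz = crit))
  list(decay_time_s = rs$t_s[below[1]] - epoch[2], censored = FALSE,
       bound_s = NA_real_, max_rate_hz = max_rate,
       criterion_rate_hz = crit)
}

#' Sort bursts evoked by stimulation pulses
#'
#' Assigns to every stimulus pulse the first burst whose onset falls within
#' `[pulse, pulse + window_s)`; the latency is the onset minus the pulse
#' time (`NA` marks a miss). Windows longer than the inter-pulse interval
#' are truncated to it and flagged. When a `Recording` is supplied, each
#' pulse also gets an aligned rectified-power trace (mean over channels of
#' the squared signal), the substrate for [response_peak_profile()].
#' Entries are sorted by latency, misses last.
#'
#' @param stimlog a [stimulus_log()].
#' @param bursts burst onsets (vector or table).
#' @param window_s post-pulse assignment window; default one inter-pulse
#'   interval.
#' @param rec optional `Recording` for aligned traces.
#' @return An object of class `evoked_bursts`: `data.frame(stim_onset_s,
#'   latency_s)` in `table`, list of power traces in `traces` (or `NULL`),
#'   `fs_hz`, `window_s`, `truncated` flag.
#' @export
sort_evoked_bursts <- function(stimlog, bursts, window_s = NULL,
                               rec = NULL) {
  on <- if (is.data.frame(bursts)) bursts$onset_s else as.numeric(bursts)
  pulses <- stimlog$pulse_onsets_s
  if (length(pulses) < 1) stop("stimulus log has no pulses")
  ipi <- if (length(pulses) > 1) min(diff(pulses))
         else 1 / stimlog$train_frequency_hz
  truncated <- FALSE
  if (is.null(window_s)) window_s <- ipi
  if (window_s > ipi + 1e-9) { window_s <- ipi; truncated <- TRUE }
  lat <- vapply(pulses, function(p) {
    hit <- on[on >= p & on < p + window_s]
    if (length(hit)) hit[1] - p else NA_real_
  }, 0)
  tab <- data.frame(stim_onset_s = pulses, latency_s = lat)
  ord <- order(is.na(tab$latency_s), tab$latency_s)
  tab <- tab[ord, , drop = FALSE]
  traces <- NULL
  fs <- NULL
  if (!is.null(rec)) {
    fs <- rec$sampling_rate_hz
    nwin <- floor(window_s * fs)
    traces <- lapply(tab$stim_onset_s, function(p) {
      i0 <- floor(p * fs) + 1
      i1 <- min(ncol(rec$samples), i0 + nwin - 1)
      if (i1 <= i0) return(numeric(0))
      colMeans(rec$samples[, i0:i1, drop = FALSE]^2)
    })
  }
  structure(list(table = tab, traces = traces, fs_hz = fs,
                 window_s = window_s, truncated = truncated),
            class = "evoked_bursts")
}

#' Multi-peak profile of evoked responses
#'
#' For each evoked trace, smooths the rectified-power profile, normalizes
#' it to its maximum and locates local maxima above a prominence threshold
#' (default 20% of the profile maximum), separated by at least
#' `min_separation_s`; peaks are classified primary/secondary/tertiary by
#' temporal order. Pooled peak times give a post-stimulus histogram and a
#' kernel density estimate (Silverman bandwidth unless given), whose own
#' local maxima summarize the response-peak clusters.
#'
#' @param evoked an [sort_evoked_bursts()] result with traces.
#' @param kde_bandwidth density bandwidth in seconds (`NULL` = Silverman).
#' @param prominence_frac peak threshold as a fraction of the profile max.
#' @param min_separation_s minimum peak separation.
#' @param smooth_s moving-average smoothing of the power profile.
#' @return list with `peak_times_s` (per trace), `has_secondary`,
#'   `secondary_fraction`, `pooled_peaks_s`, `histogram` (hist object),
#'   `density`, `density_peak_times_s`.
#' @export
response_peak_profile <- function(evoked, kde_bandwidth = NULL,
                                  prominence_frac = 0.2,
                                  min_separation_s = 0.1,
                                  smooth_s = 0.02) {
  stopifnot(inherits(evoked, "evoked_bursts"))
  if (is.null(evoked$traces))
    stop("evoked bursts carry no traces: pass a Recording to ",
         "sort_evoked_bursts()")
  if (length(evoked$traces) < 10)
    warning("fewer than 10 evoked traces: profile unstable")
  fs <- evoked$fs_hz
  ksm <- max(1, round(smooth_s * fs))
  minsep <- max(1, round(min_separation_s * fs))
  peak_times <- lapply(evoked$traces, function(tr) {
    if (!length(tr) || max(tr) == 0) return(numeric(0))
    sm <- as.numeric(stats::filter(tr, rep(1 / ksm, ksm), sides = 2))
    sm[is.na(sm)] <- 0
    sm <- sm / max(sm)
    pk <- pracma::findpeaks(sm, minpeakheight = prominence_frac,
                            minpeakdistance = minsep)
    if (is.null(pk)) return(numeric(0))
    sort(pk[, 2]) / fs
  })
  has2 <- vapply(peak_times, function(p) length(p) >= 2, TRUE)
  pooled <- unlist(peak_times)
  hist <- density <- dpk <- NULL
  if (length(pooled) >= 2) {
    hist <- graphics::hist(pooled, breaks = "FD", plot = FALSE)
    bw <- if (is.null(kde_bandwidth)) stats::bw.nrd0(pooled)
          else kde_bandwidth
    density <- stats::density(pooled, bw = bw)
    pk <- pracma::findpeaks(density$y,
                            minpeakheight = prominence_frac *
                              max(density$y))
    dpk <- if (!is.null(pk)) sort(density$x[pk[, 2]]) else numeric(0)
  }
  list(peak_times_s = peak_times, has_secondary = has2,
       secondary_fraction = mean(has2), pooled_peaks_s = pooled,
       histogram = hist, density = density, density_peak_times_s = dpk)
}
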