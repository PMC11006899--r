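#' Analysis configuration
#'
#' Bundles every tunable parameter of the spike/burst/LFP/avalanche/PAC
#' pipeline with the defaults used throughout: spikes are detected on the
#' 300-3000 Hz band at +/- 5 sigma of the baseline noise, a burst is five
#' spikes within a 100 ms window on one electrode, LFP is the < 1000 Hz
#' component, avalanches chain pooled spikes separated by at most 3 ms, and
#' phase-amplitude coupling uses 36 phase bins (10 degrees each) over the
#' named bands slow 0.2-0.5, delta 0.5-4, theta 4-8 and gamma 30-300 Hz.
#'
#' @param spike_band_hz numeric length-2, band-pass edges (Hz) for spike
#'   detection.
#' @param lfp_cutoff_hz low-pass cutoff (Hz) for LFP extraction.
#' @param spike_threshold_sigma detection threshold in units of the baseline
#'   noise SD.
#' @param burst_min_spikes minimum number of spikes defining a burst.
#' @param burst_window_s window length (s) within which `burst_min_spikes`
#'   must fall.
#' @param avalanche_bin_s maximum gap (s) chaining pooled spikes into one
#'   avalanche.
#' @param pac_n_bins number of phase bins for the modulation index.
#' @param bands named list of length-2 numeric band edges (Hz).
#' @param rng_seed optional integer seed recorded with the configuration.
#' @return An object of class `mea_config` (a validated list).
#' @export
analysis_config <- function(spike_band_hz = c(300, 3000),
                            lfp_cutoff_hz = 1000,
                            spike_threshold_sigma = 5,
                            burst_min_spikes = 5,
                            burst_window_s = 0.1,
                            avalanche_bin_s = 0.003,
                            pac_n_bins = 36,
                            bands = list(slow = c(0.2, 0.5),
                                         delta = c(0.5, 4),
                                         theta = c(4, 8),
                                         gamma = c(30, 300)),
                            rng_seed = NULL) {
  stopifnot(length(spike_band_hz) == 2, spike_band_hz[1] < spike_band_hz[2],
            lfp_cutoff_hz > 0, spike_threshold_sigma > 0,
            burst_min_spikes >= 2, burst_window_s > 0,
            avalanche_bin_s > 0, pac_n_bins >= 2)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || !(b[1] < b[2]))
      stop("band '", nm, "' must be c(low, high) with low < high")
  }
  structure(list(spike_band_hz = as.numeric(spike_band_hz),
                 lfp_cutoff_hz = lfp_cutoff_hz,
                 spike_threshold_sigma = spike_threshold_sigma,
                 burst_min_spikes = as.integer(burst_min_spikes),
                 burst_window_s = burst_window_s,
                 avalanche_bin_s = avalanche_bin_s,
                 pac_n_bins = as.integer(pac_n_bins),
                 bands = lapply(bands, as.numeric),
                 rng_seed = rng_seed),
            class = "mea_config")
}

#' @export
print.mea_config <- function(x, ...) {
  cat("MEA analysis configuration\n")
  cat(sprintf("  spike band      : %g-%g Hz, threshold %g sigma\n",
              x$spike_band_hz[1], x$spike_band_hz[2],
              x$spike_threshold_sigma))
  cat(sprintf("  burst rule      : >= %d spikes in %g ms\n",
              x$burst_min_spikes, 1000 * x$burst_window_s))
  cat(sprintf("  LFP cutoff      : < %g Hz\n", x$lfp_cutoff_hz))
  cat(sprintf("  avalanche bin   : %g ms\n", 1000 * x$avalanche_bin_s))
  cat(sprintf("  PAC bins        : %d\n", x$pac_n_bins))
  for (nm in names(x$bands))
    cat(sprintf("  band %-6s     : %g-%g Hz\n", nm,
                x$bands[[nm]][1], x$bands[[nm]][2]))
  invisible(x)
}
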