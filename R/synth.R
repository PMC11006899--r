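#' Synthetic-recording specification
#'
#' Parameters of the ground-truthed extracellular recording generator.
#' Defaults emulate the connected-organoid regime: 20 kHz sampling,
#' Gaussian background noise of known sigma, biphasic spike templates with
#' amplitude expressed in sigma units, sparse per-electrode Poisson
#' background firing, population bursts at 0.65 Hz shared by the two
#' compartments with a 120 +/- 20 ms right-after-left onset delay.
#'
#' @param duration_s recording length (s).
#' @param n_electrodes total electrode count (even; split LEFT/RIGHT).
#' @param fs_hz sampling rate.
#' @param noise_sigma_uv background noise SD (uV).
#' @param background_rate_hz per-electrode Poisson spike rate outside
#'   bursts.
#' @param burst_rate_hz population burst rate (Hz).
#' @param burst_spikes_lambda Poisson mean spikes per electrode per burst.
#' @param burst_span_s burst envelope length (s).
#' @param delay_mean_s,delay_sd_s inter-compartment burst onset delay
#'   distribution (right minus left).
#' @param template_amp_sigma spike template peak amplitude in noise-sigma
#'   units (a warning is raised below 6, where detection is expectedly
#'   lossy).
#' @param rng_seed mandatory integer seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(duration_s = 60, n_electrodes = 16, fs_hz = 20000,
                       noise_sigma_uv = 10, background_rate_hz = 1,
                       burst_rate_hz = 0.65, burst_spikes_lambda = 8,
                       burst_span_s = 0.15, delay_mean_s = 0.12,
                       delay_sd_s = 0.02, template_amp_sigma = 10,
                       rng_seed = 1) {
  stopifnot(duration_s > 0, n_electrodes %% 2 == 0, fs_hz > 0,
            noise_sigma_uv > 0, template_amp_sigma > 0,
            !is.null(rng_seed))
  if (template_amp_sigma < 6)
    warning("template amplitude below 6 sigma: detection near threshold ",
            "is expected to be lossy")
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate a synthetic extracellular recording with ground truth
#'
#' Gaussian noise plus biphasic spike templates inserted at known times:
#' independent Poisson background per electrode, and population bursts
#' occurring first in the LEFT compartment and, after a configured random
#' delay, in the RIGHT one. The returned ground truth (exact spike times
#' per electrode, burst onsets per compartment, per-burst delays) scores
#' any downstream detector without re-derivation; the generator never calls
#' the analysis code.
#'
#' @param spec a [synth_spec()].
#' @return list with `rec` (a `Recording`) and `truth` (list:
#'   `spike_times` per electrode, `left_burst_onsets_s`,
#'   `right_burst_onsets_s`, `delays_s`, `sigma_uv`).
#' @export
synth_recording <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$rng_seed)
  fs <- spec$fs_hz
  nsamp <- round(spec$duration_s * fs)
  em <- two_compartment_map(spec$n_electrodes)
  half <- spec$n_electrodes / 2
  # population burst skeleton: LEFT onsets Poisson, RIGHT delayed
  n_b <- stats::rpois(1, spec$burst_rate_hz * spec$duration_s)
  margin <- spec$burst_span_s + 3 * (spec$delay_mean_s + spec$delay_sd_s)
  left_on <- sort(stats::runif(n_b, 0, max(0.1, spec$duration_s - margin)))
  # enforce separation so bursts remain discrete events
  if (length(left_on) > 1)
    left_on <- left_on[c(TRUE, diff(left_on) > 2 * margin)]
  delays <- stats::rnorm(length(left_on), spec$delay_mean_s,
                         spec$delay_sd_s)
  right_on <- left_on + delays
  spike_times <- vector("list", spec$n_electrodes)
  for (e in seq_len(spec$n_electrodes)) {
    bg <- stats::rpois(1, spec$background_rate_hz * spec$duration_s)
    st <- stats::runif(bg, 0, spec$duration_s)
    onsets <- if (e <= half) left_on else right_on
    for (on in onsets) {
      k <- stats::rpois(1, spec$burst_spikes_lambda)
      if (k > 0)
        # front-loaded envelope: onset spike plus decaying spread keeps
        # the first spike near the nominal onset
        st <- c(st, on + c(0, sort(stats::rbeta(max(0, k - 1), 1.2, 2)) *
                             spec$burst_span_s))
    }
    st <- sort(st)
    if (length(st) > 1)
      st <- st[c(TRUE, diff(st) > 0.002)]  # 2 ms separation floor
    st <- st[st >= 0 & st < spec$duration_s - 0.002]
    spike_times[[e]] <- st
  }
  sig <- matrix(stats::rnorm(spec$n_electrodes * nsamp,
                             sd = spec$noise_sigma_uv),
                nrow = spec$n_electrodes)
  tmpl <- spike_template(fs) * spec$template_amp_sigma * spec$noise_sigma_uv
  ntm <- length(tmpl)
  for (e in seq_len(spec$n_electrodes)) {
    i0 <- floor(spike_times[[e]] * fs) + 1
    i0 <- i0[i0 + ntm - 1 <= nsamp]
    for (i in i0) sig[e, i:(i + ntm - 1)] <- sig[e, i:(i + ntm - 1)] + tmpl
  }
  rec <- recording(sig, fs, em,
                   annotations = list(source = "synth_recording",
                                      rng_seed = spec$rng_seed))
  list(rec = rec,
       truth = list(spike_times = spike_times,
                    left_burst_onsets_s = left_on,
                    right_burst_onsets_s = right_on,
                    delays_s = delays, sigma_uv = spec$noise_sigma_uv))
}

#' Generate a phase-amplitude-coupled test signal
#'
#' Standard coupled-envelope construction: a slow carrier plus a fast tone
#' whose envelope is `1 - chi + chi (1 + cos phase_slow) / 2`, plus white
#' noise. At `chi = 0` the fast amplitude is independent of the slow phase
#' (modulation index provably 0 in expectation); the modulation index is
#' monotone in `chi`, reaching maximal concentration as `chi -> 1`.
#'
#' @param duration_s signal length (s).
#' @param fs_hz sampling rate (default 1000, ample for a gamma-band tone).
#' @param phase_freq_hz slow carrier frequency (inside the phase band).
#' @param amp_freq_hz fast tone frequency (inside the amplitude band).
#' @param chi coupling strength in `[0, 1]`.
#' @param slow_amp,fast_amp carrier and tone amplitudes.
#' @param noise_sd broadband noise SD.
#' @param rng_seed integer seed.
#' @return list with `x` (signal), `fs_hz`, the parameters, and the true
#'   `phase_band`/`amplitude_band` implied by the tone frequencies.
#' @export
synth_pac <- function(duration_s = 100, fs_hz = 1000, phase_freq_hz = 1.5,
                      amp_freq_hz = 60, chi = 0.5, slow_amp = 1,
                      fast_amp = 0.5, noise_sd = 0.05, rng_seed = 1) {
  stopifnot(chi >= 0, chi <= 1, amp_freq_hz > phase_freq_hz)
  set.seed(rng_seed)
  t <- seq(0, duration_s - 1 / fs_hz, by = 1 / fs_hz)
  ph <- 2 * pi * phase_freq_hz * t
  env <- 1 - chi + chi * (1 + cos(ph)) / 2
  x <- slow_amp * cos(ph) + fast_amp * env * sin(2 * pi * amp_freq_hz * t) +
    stats::rnorm(length(t), sd = noise_sd)
  list(x = x, fs_hz = fs_hz, phase_freq_hz = phase_freq_hz,
       amp_freq_hz = amp_freq_hz, chi = chi, rng_seed = rng_seed)
}

#' Generate a stimulation-locked burst session with ground truth
#'
#' Burst point process for entrainment analysis: baseline Poisson bursts;
#' from `stim_start_s + induction_delay_s` to the end of stimulation,
#' bursts lock 1:1 to the pulses; after cessation the rate relaxes
#' exponentially (time constant `decay_tau_s`) from the stimulation rate
#' toward baseline, realized as a deterministic rate-following train (the
#' integrated-intensity construction), so the ground-truth 75% crossing is
#' exact. The closed-form crossing time `tau * log((peak - base) / (0.75
#' peak - base))` is returned with the truth.
#'
#' @param duration_s total session length (s).
#' @param baseline_rate_hz spontaneous burst rate.
#' @param stim_freq_hz pulse rate during stimulation.
#' @param stim_start_s,stim_duration_s stimulation epoch.
#' @param induction_delay_s true delay from stimulation onset to 1:1
#'   locking.
#' @param decay_tau_s post-cessation exponential decay constant.
#' @param pulse_width_s pulse width recorded in the log (default 0.2 s, the
#'   470 nm pacing pulse).
#' @param rng_seed integer seed.
#' @return list with `bursts` (onset vector), `stimlog` (a
#'   [stimulus_log()] with a `STIM` epoch), and `truth` (list:
#'   `induction_delay_s`, `decay_crossing_s` closed form, `peak_rate_hz`,
#'   `baseline_rate_hz`).
#' @export
synth_entrainment_session <- function(duration_s = 900,
                                      baseline_rate_hz = 0.2,
                                      stim_freq_hz = 1,
                                      stim_start_s = 300,
                                      stim_duration_s = 300,
                                      induction_delay_s = 80,
                                      decay_tau_s = 60,
                                      pulse_width_s = 0.2,
                                      rng_seed = 1) {
  stopifnot(stim_start_s + stim_duration_s < duration_s,
            induction_delay_s >= 0, decay_tau_s >= 0)
  set.seed(rng_seed)
  stim_end <- stim_start_s + stim_duration_s
  pulses <- seq(stim_start_s, stim_end - 1e-9, by = 1 / stim_freq_hz)
  lock_from <- stim_start_s + induction_delay_s
  # baseline Poisson bursts up to locking onset
  n0 <- stats::rpois(1, baseline_rate_hz * lock_from)
  pre <- sort(stats::runif(n0, 0, lock_from))
  locked <- pulses[pulses >= lock_from]
  # post-cessation: deterministic train following
  # r(t) = base + (peak - base) exp(-t / tau); no elevation when the
  # session never locked
  peak <- if (length(locked)) stim_freq_hz else baseline_rate_hz
  base <- baseline_rate_hz
  post_span <- duration_s - stim_end
  cum_int <- if (decay_tau_s > 0)
    function(t) base * t +
      (peak - base) * decay_tau_s * (1 - exp(-t / decay_tau_s))
  else function(t) base * t
  total <- cum_int(post_span)
  post <- numeric(0)
  if (total >= 1) {
    ks <- seq_len(floor(total))
    post <- stim_end + vapply(ks, function(k)
      stats::uniroot(function(t) cum_int(t) - k, c(0, post_span))$root, 0)
  }
  bursts <- sort(c(pre, locked, post))
  epochs <- data.frame(start_s = c(0, stim_start_s, stim_end),
                       end_s = c(stim_start_s, stim_end, duration_s),
                       state = c("PRE", "STIM", "POST"))
  sl <- stimulus_log(pulses, pulse_width_s, stim_freq_hz, "EXCITE_470",
                     epochs)
  crossing <- if (decay_tau_s > 0 && 0.75 * peak > base)
    decay_tau_s * log((peak - base) / (0.75 * peak - base))
  else 0
  list(bursts = bursts, stimlog = sl,
       truth = list(induction_delay_s = induction_delay_s,
                    decay_crossing_s = crossing, peak_rate_hz = peak,
                    baseline_rate_hz = base, duration_s = duration_s))
}
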