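#' Hodgkin-Huxley cell-class parameters
#'
#' Single-compartment parameter sets for the two cell classes of the in
#' silico organoid model: regular-spiking excitatory neurons (RS, with a
#' slow non-inactivating K+ adaptation current, so their inter-spike
#' intervals lengthen under constant drive) and fast-spiking inhibitory
#' neurons (FS, no adaptation, sustained high-rate firing). Values follow
#' the standard cortical single-compartment HH literature; all conductances
#' in mS/cm^2, capacitance in uF/cm^2, potentials in mV.
#'
#' @return A 2 x 10 matrix, rows RS and FS, columns `Cm, gL, EL, gNa, gK,
#'   gM, VT, tau_max, refr_ms, v_init`.
#' @export
hh_class_params <- function() {
  par <- rbind(
    RS = c(Cm = 1, gL = 0.0205, EL = -70.3, gNa = 56, gK = 6,
           gM = 0.075, VT = -56.2, tau_max = 608, refr_ms = 3,
           v_init = -70),
    FS = c(Cm = 1, gL = 0.038, EL = -70.4, gNa = 58, gK = 3.9,
           gM = 0, VT = -57.9, tau_max = 608, refr_ms = 3,
           v_init = -70))
  par
}

#' Build a one- or two-population HH network
#'
#' Wires RS/FS neurons into one of three topologies mirroring the organoid
#' culture configurations: `SINGLE` (one population), `FUSED` (two
#' populations joined at a contact zone by intra-grade synapses with short
#' delays) and `CONNECTED` (two populations joined by a sparse axon-bundle
#' pathway: long-delay synapses from a subset of bundle-projecting RS
#' neurons of each side onto the opposite population, with weight
#' `w_inter`; the regime that reproduces the connected-organoid activity
#' has `w_inter > w_intra`).
#'
#' @param topology `"SINGLE"`, `"FUSED"` or `"CONNECTED"`.
#' @param n_per_population neurons per population.
#' @param frac_excitatory RS fraction (default 0.8).
#' @param p_intra intra-population connection probability.
#' @param w_intra intra-population excitatory weight (mS/cm^2 conductance
#'   increment).
#' @param w_inh FS inhibitory weight.
#' @param p_inter inter-population (bundle or contact) connection
#'   probability per projecting-neuron/target pair.
#' @param w_inter bundle synaptic weight (CONNECTED only; must be given).
#' @param frac_bundle fraction of each side's RS neurons projecting through
#'   the bundle.
#' @param frac_inter_fs fraction of bundle synapses targeting FS neurons
#'   (feedforward inhibition of the opposite side).
#' @param inter_delay_s bundle axonal delay (default 0.05 s).
#' @param intra_delay_range_s local delay range.
#' @param rng_seed integer seed (synapse lists are reproducible).
#' @return An object of class `hh_network`.
#' @export
build_network <- function(topology = c("SINGLE", "FUSED", "CONNECTED"),
                          n_per_population = 200,
                          frac_excitatory = 0.8,
                          p_intra = 0.05, w_intra = 0.003, w_inh = 0.05,
                          p_inter = 0.05, w_inter = NULL,
                          frac_bundle = 0.3, frac_inter_fs = 0.5,
                          inter_delay_s = 0.05,
                          intra_delay_range_s = c(0.001, 0.003),
                          rng_seed = 1) {
  topology <- match.arg(topology)
  stopifnot(n_per_population >= 1, frac_excitatory > 0, frac_excitatory <= 1)
  if (topology == "CONNECTED" && is.null(w_inter))
    stop("CONNECTED topology requires w_inter")
  set.seed(rng_seed)
  npop <- if (topology == "SINGLE") 1L else 2L
  n <- npop * n_per_population
  population <- rep(seq_len(npop), each = n_per_population)
  n_rs <- round(frac_excitatory * n_per_population)
  cls <- unlist(lapply(seq_len(npop), function(p)
    c(rep(0L, n_rs), rep(1L, n_per_population - n_rs))))
  # positions: each population a 300 um radius disc; discs 1.5 mm apart
  r <- 300 * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  x <- r * cos(th) + (population - 1) * 1500
  y <- r * sin(th)

  rand_delay <- function(k) stats::runif(k, intra_delay_range_s[1],
                                         intra_delay_range_s[2])
  syn <- list()
  add_syn <- function(pre, post, w, delay_s, inh, inter) {
    syn[[length(syn) + 1]] <<- data.frame(pre = pre, post = post, w = w,
                                          delay_s = delay_s, inh = inh,
                                          inter = inter)
  }
  for (p in seq_len(npop)) {
    idx <- which(population == p)
    pairs <- which(matrix(stats::runif(length(idx)^2) < p_intra,
                          length(idx)) & !diag(length(idx)), arr.ind = TRUE)
    if (nrow(pairs)) {
      pre <- idx[pairs[, 1]]
      post <- idx[pairs[, 2]]
      inh <- cls[pre] == 1L
      add_syn(pre, post, ifelse(inh, w_inh, w_intra),
              rand_delay(length(pre)), as.integer(inh), 0L)
    }
  }
  if (topology == "FUSED") {
    # contact zone: neurons near the facing edges connect with intra-grade
    # weights and local delays
    edge1 <- which(population == 1 & x > 150)
    edge2 <- which(population == 2 & x < 1350)
    grid <- expand.grid(pre = c(edge1, edge2), post = c(edge2, edge1))
    grid <- grid[population[grid$pre] != population[grid$post], ]
    take <- stats::runif(nrow(grid)) < p_intra
    if (any(take)) {
      pre <- grid$pre[take]; post <- grid$post[take]
      inh <- cls[pre] == 1L
      add_syn(pre, post, ifelse(inh, w_inh, w_intra),
              rand_delay(length(pre)), as.integer(inh), 1L)
    }
  }
  if (topology == "CONNECTED" && p_inter > 0) {
    for (p in 1:2) {
      src_rs <- which(population == p & cls == 0L)
      bundle_src <- src_rs[seq_len(round(frac_bundle * length(src_rs)))]
      tgt_pop <- which(population == (3 - p))
      tgt_fs <- tgt_pop[cls[tgt_pop] == 1L]
      tgt_rs <- tgt_pop[cls[tgt_pop] == 0L]
      # FS targets drawn at a rate scaled so frac_inter_fs of bundle
      # synapses land on FS neurons (feedforward inhibition)
      p_fs <- p_inter * frac_inter_fs / (1 - frac_inter_fs) *
        length(tgt_rs) / max(1, length(tgt_fs))
      for (s in bundle_src) {
        k_fs <- tgt_fs[stats::runif(length(tgt_fs)) < min(1, p_fs)]
        k_rs <- tgt_rs[stats::runif(length(tgt_rs)) < p_inter]
        tgt <- c(k_rs, k_fs)
        if (length(tgt))
          add_syn(rep(s, length(tgt)), tgt, w_inter,
                  rep(inter_delay_s, length(tgt)), 0L, 1L)
      }
    }
  }
  syn <- if (length(syn)) do.call(rbind, syn)
         else data.frame(pre = integer(0), post = integer(0), w = numeric(0),
                         delay_s = numeric(0), inh = integer(0),
                         inter = integer(0))
  structure(list(topology = topology, n = n, population = population,
                 class = cls, x_um = x, y_um = y, synapses = syn,
                 params = hh_class_params(), rng_seed = rng_seed),
            class = "hh_network")
}

#' @export
print.hh_network <- function(x, ...) {
  cat(sprintf("HH network (%s): %d neurons (%d RS / %d FS), %d synapses\n",
              x$topology, x$n, sum(x$class == 0), sum(x$class == 1),
              nrow(x$synapses)))
  if (any(x$synapses$inter == 1))
    cat(sprintf("  inter-population synapses: %d (mean w %.4g)\n",
                sum(x$synapses$inter == 1),
                mean(x$synapses$w[x$synapses$inter == 1])))
  invisible(x)
}

#' Simulate an HH network
#'
#' Integrates the membrane equations of every neuron with conductance-based
#' exponential synapses (excitatory reversal 0 mV, tau 5 ms; inhibitory
#' -80 mV, tau 10 ms) at a fixed step. Background drive is an independent
#' Ornstein-Uhlenbeck current per neuron. The protocol may, per epoch,
#' silence all inter-population synapses (the ArchT bundle-silencing
#' analog) or inject periodic depolarizing pulses into the
#' bundle-projecting neurons (the ChR2 pacing analog). A fixed seed and
#' step size give a bit-stable spike raster.
#'
#' @param model an [build_network()] result.
#' @param duration_s simulated span (s).
#' @param protocol optional `data.frame(t0_s, t1_s, type, freq_hz,
#'   width_ms, amp_nA)` with `type` in `"silence_inter"`, `"pulse"`.
#' @param rng_seed integer seed.
#' @param dt_ms integration step (default 0.05 ms).
#' @param drive_mu_nA mean background drive per class `c(RS, FS)` in nA.
#' @param drive_sigma_nA OU noise SD in nA.
#' @param ou_tau_ms OU correlation time.
#' @param area_cm2 membrane area converting nA to uA/cm^2.
#' @param record_v neuron indices whose membrane potential is recorded.
#' @param record_stride_ms trace sampling interval.
#' @return An object of class `hh_sim_result`: `spikes`
#'   (`data.frame(neuron, time_s)`), `traces`/`trace_t_s`, the model, the
#'   protocol and the seed.
#' @export
simulate_network <- function(model, duration_s, protocol = NULL,
                             rng_seed = 1, dt_ms = 0.05,
                             drive_mu_nA = c(0.22, 0.18),
                             drive_sigma_nA = 0.09, ou_tau_ms = 5,
                             area_cm2 = 2e-4,
                             record_v = integer(0), record_stride_ms = 1) {
  stopifnot(inherits(model, "hh_network"), duration_s > 0)
  to_ua_cm2 <- 1e-3 / area_cm2   # nA -> uA/cm^2
  prot <- matrix(0, nrow = 0, ncol = 6)
  pulse_target <- rep(0L, model$n)
  if (!is.null(protocol) && nrow(protocol)) {
    type_code <- c(silence_inter = 1, pulse = 2)
    prot <- cbind(protocol$t0_s * 1000, protocol$t1_s * 1000,
                  type_code[protocol$type],
                  if (!is.null(protocol$freq_hz)) protocol$freq_hz else 1,
                  if (!is.null(protocol$width_ms)) protocol$width_ms else 0,
                  (if (!is.null(protocol$amp_nA)) protocol$amp_nA else 0) *
                    to_ua_cm2)
    if (any(is.na(prot[, 3]))) stop("unknown protocol type")
    # pulses target the bundle-projecting neurons (presynaptic side of
    # inter-population synapses); with none, all RS neurons
    src <- unique(model$synapses$pre[model$synapses$inter == 1])
    if (!length(src)) src <- which(model$class == 0L)
    pulse_target[src] <- 1L
  }
  ou_mu <- ifelse(model$class == 0L, drive_mu_nA[1], drive_mu_nA[2]) *
    to_ua_cm2
  set.seed(rng_seed)
  res <- .hh_simulate_cpp(
    n_neurons = model$n, cls = model$class, class_par = model$params,
    syn_pre = model$synapses$pre - 1L, syn_post = model$synapses$post - 1L,
    syn_w = model$synapses$w,
    syn_delay = as.integer(round(model$synapses$delay_s * 1000 / dt_ms)),
    syn_inh = model$synapses$inh, syn_inter = model$synapses$inter,
    duration_ms = duration_s * 1000, dt = dt_ms,
    ou_mu = ou_mu, ou_sigma = drive_sigma_nA * to_ua_cm2,
    ou_tau_ms = ou_tau_ms, ou_refresh = max(1L, round(0.5 / dt_ms)),
    protocol = prot, pulse_target = pulse_target,
    record_idx = as.integer(record_v - 1L),
    record_stride = max(1L, round(record_stride_ms / dt_ms)))
  if (res$diverged)
    stop("HH integration diverged (|V| > 200 mV) at step ",
         res$diverged_step, " (t = ",
         round(res$diverged_step * dt_ms, 2), " ms)")
  structure(list(spikes = data.frame(neuron = res$spike_neuron + 1L,
                                     time_s = res$spike_time_ms / 1000),
                 traces = res$traces, trace_t_s = res$trace_t_ms / 1000,
                 record_v = record_v, model = model, protocol = protocol,
                 duration_s = duration_s, dt_ms = dt_ms,
                 rng_seed = rng_seed),
            class = "hh_sim_result")
}

#' @export
print.hh_sim_result <- function(x, ...) {
  cat(sprintf("HH simulation: %s, %.1f s, %d spikes (%.2f Hz/neuron)\n",
              x$model$topology, x$duration_s, nrow(x$spikes),
              nrow(x$spikes) / x$model$n / x$duration_s))
  invisible(x)
}

#' Virtual multi-electrode array readout of a simulation
#'
#' Converts a simulated spike raster into a standard [recording()] so the
#' whole detection/oscillation/avalanche stack runs on model output. Each
#' electrode sums a biphasic extracellular spike template from every spike
#' of neurons within `mixing_radius_um`, attenuated as `1 / (1 +
#' (d/30um)^2)`, plus Gaussian noise of `noise_sigma_uv`. Electrodes with
#' no neuron in range yield pure noise and are flagged in the annotations.
#'
#' @param sim an [simulate_network()] result.
#' @param electrodes_per_side electrodes under each population (grid).
#' @param fs_hz output sampling rate (default 10000).
#' @param mixing_radius_um electrode listening radius.
#' @param noise_sigma_uv recording noise SD.
#' @param amp_uv template peak amplitude for a neuron at distance 0.
#' @param rng_seed seed for the noise.
#' @return A `Recording` with a LEFT/RIGHT electrode map.
#' @export
virtual_mea <- function(sim, electrodes_per_side = 8, fs_hz = 10000,
                        mixing_radius_um = 100, noise_sigma_uv = 3,
                        amp_uv = 60, rng_seed = 1) {
  stopifnot(inherits(sim, "hh_sim_result"))
  model <- sim$model
  npop <- max(model$population)
  per_side <- electrodes_per_side
  side <- ceiling(sqrt(per_side))
  pitch <- 600 / (side + 1)
  ex <- ey <- comp <- c()
  for (p in seq_len(npop)) {
    idx <- seq_len(per_side) - 1
    gx <- (idx %% side + 1) * pitch - 300 + (p - 1) * 1500
    gy <- (idx %/% side + 1) * pitch - 300
    ex <- c(ex, gx); ey <- c(ey, gy)
    comp <- c(comp, rep(if (p == 1) "LEFT" else "RIGHT", per_side))
  }
  em <- electrode_map(seq_along(ex), ex, ey, comp)
  n_el <- nrow(em)
  nsamp <- ceiling(sim$duration_s * fs_hz)
  set.seed(rng_seed)
  sig <- matrix(stats::rnorm(n_el * nsamp, sd = noise_sigma_uv),
                nrow = n_el)
  tmpl <- spike_template(fs_hz)
  ntm <- length(tmpl)
  flagged <- c()
  for (e in seq_len(n_el)) {
    d <- sqrt((model$x_um - ex[e])^2 + (model$y_um - ey[e])^2)
    near <- which(d <= mixing_radius_um)
    if (!length(near)) { flagged <- c(flagged, e); next }
    gain <- amp_uv / (1 + (d[near] / 30)^2)
    sp <- sim$spikes[sim$spikes$neuron %in% near, ]
    if (!nrow(sp)) next
    g <- gain[match(sp$neuron, near)]
    i0 <- floor(sp$time_s * fs_hz) + 1
    keep <- i0 + ntm - 1 <= nsamp
    i0 <- i0[keep]; g <- g[keep]
    for (k in seq_along(i0))
      sig[e, i0[k]:(i0[k] + ntm - 1)] <-
        sig[e, i0[k]:(i0[k] + ntm - 1)] + g[k] * tmpl
  }
  recording(sig, fs_hz, em,
            annotations = list(source = "virtual_mea",
                               pure_noise_electrodes = flagged))
}

# biphasic extracellular spike template, 1.2 ms: 0.4 ms negative lobe
# (unit depth) + 0.8 ms positive recovery at 30% amplitude
spike_template <- function(fs_hz) {
  n_neg <- max(2, round(0.0004 * fs_hz))
  n_pos <- max(2, round(0.0008 * fs_hz))
  c(-sin(pi * seq_len(n_neg) / (n_neg + 1)),
    0.3 * sin(pi * seq_len(n_pos) / (n_pos + 1)))
}

#' Per-population burst analysis of a simulation
#'
#' Runs the standard pipeline on the virtual-MEA readout: spike detection,
#' pooled population bursts per compartment and synchronized-burst pairing.
#'
#' @param sim an [simulate_network()] result.
#' @param cfg an [analysis_config()].
#' @param window_s optional `c(start, end)` restriction (s).
#' @param ... passed to [virtual_mea()].
#' @return list with `rec`, `trains`, `left`, `right` (population burst
#'   tables) and `pairs` (synchronized bursts).
#' @export
sim_population_analysis <- function(sim, cfg = analysis_config(),
                                    window_s = NULL, ...) {
  rec <- virtual_mea(sim, ...)
  if (!is.null(window_s)) rec <- segment_recording(rec, window_s[1],
                                                   window_s[2])
  trains <- detect_spikes(rec, cfg)
  left <- population_bursts(trains, rec, "LEFT", cfg)
  has_right <- length(compartment_channels(rec, "RIGHT")) > 0
  right <- if (has_right) population_bursts(trains, rec, "RIGHT", cfg)
           else left[0, , drop = FALSE]
  pairs <- pair_sync_bursts(right, right)[0, , drop = FALSE]
  if (has_right) pairs <- pair_sync_bursts(left, right)
  list(rec = rec, trains = trains, left = left, right = right,
       pairs = pairs)
}

#' Tuned organoid-model presets
#'
#' The parameter set under which the two-population model reproduces the
#' connected-organoid phenomenology: sparse noise-driven background firing
#' (~0.1-0.5 Hz per neuron), essentially no population bursts in an
#' isolated population, and recurrent inter-population volleys (synchronized
#' bursts with 50-200 ms alternating-leader delays) sustained by the axon
#' bundle pathway with `w_inter` (0.03) six-fold the intra-population
#' weight (0.005) — the regime in which higher inter- than intra-organoid
#' synaptic weight mimics the recorded activity. 65% of bundle synapses
#' target FS interneurons, so the coupled state tonically suppresses
#' background spiking; silencing the bundle (ArchT analog) abolishes
#' synchronized bursts and disinhibits single-spike firing.
#'
#' @param topology `"SINGLE"`, `"FUSED"` or `"CONNECTED"`.
#' @return list with `network` and `simulate` argument lists and the
#'   virtual-MEA settings under `mea`.
#' @export
hh_preset <- function(topology = c("SINGLE", "FUSED", "CONNECTED")) {
  topology <- match.arg(topology)
  list(network = list(topology = topology, n_per_population = 200,
                      frac_excitatory = 0.8, p_intra = 0.05,
                      w_intra = 0.005, w_inh = 0.06, p_inter = 0.05,
                      w_inter = if (topology == "CONNECTED") 0.03,
                      frac_bundle = 0.3, frac_inter_fs = 0.65,
                      inter_delay_s = 0.05),
       simulate = list(dt_ms = 0.05, drive_mu_nA = c(0.07, 0.06),
                       drive_sigma_nA = 0.04, ou_tau_ms = 5),
       mea = list(electrodes_per_side = 8, fs_hz = 10000,
                  mixing_radius_um = 60, noise_sigma_uv = 3,
                  amp_uv = 60))
}

#' Simulate a preset topology
#'
#' @param topology preset name, see [hh_preset()].
#' @param duration_s simulated span.
#' @param protocol optional protocol table (see [simulate_network()]).
#' @param rng_seed integer seed (drives wiring, noise and MEA noise).
#' @return An `hh_sim_result`.
#' @export
run_preset <- function(topology, duration_s, protocol = NULL,
                       rng_seed = 1) {
  ps <- hh_preset(topology)
  net <- do.call(build_network, c(ps$network, list(rng_seed = rng_seed)))
  do.call(simulate_network,
          c(list(model = net, duration_s = duration_s,
                 protocol = protocol, rng_seed = rng_seed + 1000),
            ps$simulate))
}

#' Bundle-silencing experiment on the connected preset
#'
#' Simulates the CONNECTED preset with the inter-population synapses
#' silenced during the middle third of the session (the in silico ArchT
#' illumination), runs the virtual-MEA burst pipeline and summarizes each
#' epoch: synchronized cross-population burst pairs and single
#' (non-burst) spikes per epoch.
#'
#' @param rng_seed integer seed.
#' @param epoch_s epoch length (s); the session is 3 epochs (pre / light-on
#'   / post).
#' @param cfg an [analysis_config()].
#' @return `data.frame(epoch, start_s, end_s, sync_pairs, left_bursts,
#'   right_bursts, single_spikes)`.
#' @export
silencing_experiment <- function(rng_seed = 1, epoch_s = 30,
                                 cfg = analysis_config()) {
  prot <- data.frame(t0_s = epoch_s, t1_s = 2 * epoch_s,
                     type = "silence_inter")
  sim <- run_preset("CONNECTED", 3 * epoch_s, protocol = prot,
                    rng_seed = rng_seed)
  ps <- hh_preset("CONNECTED")
  pa <- do.call(sim_population_analysis,
                c(list(sim = sim, cfg = cfg, rng_seed = rng_seed + 2000),
                  ps$mea))
  spans <- rbind(pa$left, pa$right)
  single_times <- sim$spikes$time_s
  if (nrow(spans)) {
    inb <- rep(FALSE, length(single_times))
    for (r in seq_len(nrow(spans)))
      inb <- inb | (single_times >= spans$onset_s[r] - 0.05 &
                      single_times <= spans$offset_s[r] + 0.05)
    single_times <- single_times[!inb]
  }
  edges <- epoch_s * (0:3)
  out <- lapply(1:3, function(e) {
    a <- edges[e]; b <- edges[e + 1]
    lw <- pa$left[pa$left$onset_s >= a & pa$left$onset_s < b, ]
    rw <- pa$right[pa$right$onset_s >= a & pa$right$onset_s < b, ]
    data.frame(epoch = c("pre", "silenced", "post")[e], start_s = a,
               end_s = b, sync_pairs = nrow(pair_sync_bursts(lw, rw)),
               left_bursts = nrow(lw), right_bursts = nrow(rw),
               single_spikes = sum(single_times >= a & single_times < b))
  })
  do.call(rbind, out)
}

#' Population burst rate of a preset topology
#'
#' Simulates a preset, runs the virtual-MEA pipeline and returns the
#' population burst rate averaged over compartments (bursts per
#' compartment per second), the quantity compared across SINGLE / FUSED /
#' CONNECTED cultures.
#'
#' @param topology preset name.
#' @param duration_s simulated span.
#' @param rng_seed integer seed.
#' @param cfg an [analysis_config()].
#' @return list with `burst_rate_hz`, `sync_rate_hz` (paired bursts per
#'   second; 0 for SINGLE) and the analysis object.
#' @export
preset_burst_rate <- function(topology, duration_s = 40, rng_seed = 1,
                              cfg = analysis_config()) {
  sim <- run_preset(topology, duration_s, rng_seed = rng_seed)
  ps <- hh_preset(topology)
  pa <- do.call(sim_population_analysis,
                c(list(sim = sim, cfg = cfg, rng_seed = rng_seed + 2000),
                  ps$mea))
  ncomp <- if (topology == "SINGLE") 1 else 2
  rate <- (nrow(pa$left) + nrow(pa$right)) / ncomp / duration_s
  list(burst_rate_hz = rate,
       sync_rate_hz = nrow(pa$pairs) / duration_s, analysis = pa)
}
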