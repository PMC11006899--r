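---
title: "Network dynamics of axon-bundle-connected cerebral organoids: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network dynamics of axon-bundle-connected cerebral organoids: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meadyn)
```

## Scope

`meadyn` analyzes multichannel extracellular recordings from paired
cerebral organoids grown on a multi-electrode array (MEA) chip whose two
compartments are connected by a reciprocal axon bundle. The package covers
the full analysis chain for such preparations — spike and burst detection,
inter-compartment synchrony, local-field-potential (LFP) band analytics,
phase-amplitude coupling, neuronal-avalanche criticality, optogenetic
entrainment metrics — plus a Hodgkin–Huxley (HH) two-population network
model whose virtual-MEA output feeds back into the same analysis chain,
and ground-truthed synthetic-data generators for every stage.

## Detection model

**Filtering.** Spikes are detected on a 300–3000 Hz band; LFP analyses use
the < 1000 Hz component. All filters are 4th-order Butterworth applied
forward–backward (zero phase): group-delay bias would contaminate
inter-compartment delay estimates and phase-based measures, which is why a
causal filter is not offered. The band-pass is realized as a high-pass /
low-pass cascade, which stays numerically well-behaved at edge ratios as
extreme as 300 Hz / 10 kHz-Nyquist.

**Noise floor.** The spike threshold is ±5σ, with σ the SD of the baseline
noise during quiescent periods. Because "quiescent" is not operationally
defined for arbitrary recordings, the default estimator is the
MAD-based robust SD, `median(|x − median(x)|)/0.6745`, which converges to
the quiescent SD as long as spikes occupy a few percent of samples (the
tests check < 10% bias with 1% of samples replaced by ±20σ transients). A
plain SD over user-marked quiescent epochs is available via
`estimate_noise_sigma(strategy = "sd")`.

**Spikes.** Each contiguous supra-threshold excursion becomes one event at
its extremum; events closer than a 1 ms refractory floor on one electrode
are merged, keeping the larger extremum, so multiphasic waveforms are not
double-counted. Detection is verified against a brute-force scan oracle on
every tested input.

**Bursts.** A burst is ≥ 5 spikes within a 100 ms window on one electrode.
Qualifying windows that share spikes merge into one maximal event, so
reported bursts never overlap and the rule has no free parameters; merged
events may span longer than 100 ms. Population bursts apply the same rule
to spikes pooled across one compartment's electrodes. Both levels are
reported because published burst-frequency comparisons do not always state
which level they use.

**Synchronized bursts.** Left/right population bursts are paired by greedy
nearest-onset matching within a 300 ms window (wide enough for the
empirically observed 100–200 ms inter-organoid delays, and for the < 50 ms
near-simultaneous cases), each burst used at most once; the delay sign
records which organoid led, with a 10 ms tie zone. The pairing is
symmetric: swapping the lists negates delays and flips leaders.

## Oscillation analytics

**Wavelet machinery.** Band isolation uses a continuous wavelet transform
with the analytic Morlet wavelet (ω₀ = 6), the standard choice for neural
LFP, computed in the Fourier domain, and band-limited inverse
reconstruction over log-spaced scales (1/12 octave). On single tones the
reconstruction recovers amplitude to within a few percent, and the
residual of a band-partition resummation carries < 10% of the energy.

**Coherence smoothing.** Wavelet coherence divides the smoothed
cross-spectrum by smoothed auto-spectra. The smoothing kernel is a boxcar
spanning **6 wavelet periods per scale** plus a 3-scale boxcar, and the
cone of influence is masked. The span matters: the Morlet's own
autocorrelation extends over several periods, so a one-period smoother
leaves the estimator with ~1 degree of freedom and coherence degenerates
to ≈ 1 even for independent noise. Six periods brings the
independent-noise median below 0.3 while leaving genuine shared rhythms
near 1; the span is exposed as the `smoothing` argument.

**Phase-amplitude coupling.** The modulation index follows the
KL-divergence construction: Hilbert phase of the slow band binned into 36
bins of 10° over [−π, π), mean fast-band amplitude per bin normalized to a
distribution, and MI = KL(P‖uniform)/log 36 ∈ [0, 1]. The mean is removed
and 1% cosine edge tapers applied before the Hilbert transform; the
tapered edges are excluded from binning. Empty phase bins (possible on
short windows) receive the global mean amplitude — this biases MI toward
0, i.e. toward *not* claiming coupling — and the result is flagged. The
MI window defaults to the whole recording; a windowed time course is a
matter of calling the function on segments.

**Phase–phase coupling** between the two organoids' delta bands is the
phase-locking value |mean exp(i(φₓ−φᵧ))|, insensitive to constant offsets.

## Avalanches and criticality

Avalanche extraction reads the grouping rule literally as gap-based
chaining: spikes pooled across electrodes belong to one avalanche while
consecutive gaps are ≤ Δt = 3 ms. The classic fixed-lattice binning
(avalanche = run of non-empty Δt bins) is provided as `mode = "lattice"`
for cross-checks; the two agree closely at these densities. Size is the
spike count of a cascade (the plausible reading of "length of the train of
signals"); Σ sizes = total spikes is asserted as a partition invariant.

The size distribution P(S) = k·S^(−α) is fitted two ways: weighted
least squares on the log-log histogram with logarithmic bins of ratio
10^0.1 (the "slope in log-log coordinates" that published exponents
describe), and discrete maximum likelihood with fixed x_min = 1, using a
generalized zeta function evaluated by truncated sum plus Euler–Maclaurin
tail. The MLE is the statistically sound estimator and the one used in
quantitative checks; its standard error comes from the observed
information and a Kolmogorov–Smirnov distance flags model mismatch
(exponential-family sizes give a KS distance several-fold larger than
true power-law samples).

The theoretical benchmark is the critical Galton–Watson branching process
(mean offspring 1), whose avalanche sizes follow S^(−3/2). The simulator
draws Poisson offspring generation-by-generation with a 10⁶ size cap
(capped fraction reported, ~6×10⁻⁴ at criticality); the MLE on 10⁵
critical cascades returns ≈ 1.49 — the exact MLE limit for the
Borel size distribution at x_min = 1 is 1.486, comfortably inside the
1.5 ± 0.1 acceptance band. Subcritical runs are checked against the
closed form E(S) = 1/(1−m).

## Entrainment metrics

"Following" a stimulus train is operationalized as the sliding-window
burst rate (30 s windows every 5 s) staying within ±20% of the stimulation
frequency for ≥ 3 consecutive windows; the induction delay is the time
from stimulation onset to the start of the first qualifying run (0 when
already in band). The baseline rate averages the 5 minutes before the
epoch. These constants are configuration, not magic: no published formula
exists for "induction of burst frequency", so the operationalization is
documented and tested against generators with known delays (20/80/160 s
recovered within one 5-s step).

The post-stimulation decay time is the first time after cessation at which
the smoothed rate falls below 75% of the epoch maximum. The smoothing is
the same 30-s window but **centered**: for an exponentially decaying rate
a trailing window is biased ~half a window early (its average at cessation
already reflects the decayed future), while the centered version crosses
within ~1 s of the closed-form crossing τ·log((peak−base)/(0.75·peak−base))
for the τ range of interest (≥ ~40 s). Windows that would reach past the
recording end are excluded; a rate that never crosses is reported censored
at the recording-end bound.

Evoked-burst profiling assigns each pulse the first burst onset within one
inter-pulse interval (longer windows are truncated and flagged), records
latencies with misses as NA sorted last, and, when the raw recording is
supplied, extracts per-pulse rectified-power traces whose local maxima
(≥ 20% prominence, ≥ 100 ms separation) are classified
primary/secondary/tertiary by order; the pooled peak times yield a
histogram and Silverman-bandwidth kernel density estimate.

## The in silico organoid model

Two populations of 200 single-compartment HH neurons (80% regular-spiking
with a slow non-inactivating K⁺ adaptation current, 20% fast-spiking; the
excitatory fraction sits inside the 60–80% range measured in these
organoids) are wired as `SINGLE`, `FUSED` (contact-zone coupling with
intra-grade weights) or `CONNECTED` (sparse long-delay bundle synapses,
both directions). Rate constants follow the standard cortical
single-compartment HH parameter sets; the RS/FS phenotypes (adapting ISIs
vs sustained fast firing) are asserted by simulation tests rather than
assumed. Synapses are conductance-based exponentials (excitatory 0 mV,
τ 5 ms; inhibitory −80 mV, τ 10 ms); integration is fixed-step (0.05 ms in
the presets, 0.025 ms available) with exponential-Euler gate updates from
lookup tables, so a fixed seed gives a bit-stable raster. Background
drive is an independent Ornstein–Uhlenbeck current per neuron.

The `CONNECTED` preset encodes the regime that reproduces the recorded
phenomenology, with the inter-population weight (0.03 mS/cm²) six-fold
the intra-population weight (0.005): isolated populations fire sparse
noise-driven background (~0.1–0.5 Hz/neuron) and essentially never
generate population bursts on their own; synchronized bursts arise from
reverberation through the 50 ms bundle pathway, with alternating leadership
and 50–200 ms delays. Tuning the drive so that *single* populations burst
at an appreciable rate was rejected deliberately: independent bursting
produces chance left–right coincidences, and the silencing experiment
(below) then cannot cleanly abolish synchronized bursts — the model regime
where bursts exist *only* through the bundle is also the one the weight
comparison in the source preparation argues for.

65% of bundle synapses target FS interneurons. This feedforward
inhibition makes the coupled state tonically suppress background firing
between bursts, so silencing all inter-population synapses (the ArchT
illumination analog) both abolishes synchronized bursts and *increases*
single (non-burst) spike counts — the disinhibition signature seen in
vitro. The spike-count comparison is made on single spikes, the quantity
the corresponding in vitro panel reports; total counts including burst
volleys could not be non-decreasing in any regime that bursts when
coupled.

The virtual MEA renders the raster back into a standard recording: 8
electrodes per compartment, each summing a biphasic template from spikes
of neurons within 60 µm (gain 1/(1+(d/30 µm)²), 60 µV at contact) plus
3 µV Gaussian noise, 10 kHz. Detection thresholds then see only the few
nearest neurons per electrode, which is what makes population bursts
discrete, detectable events rather than a saturated pooled stream.

## Synthetic-data generators

The generators are pure functions of (spec, seed) and never call the
analysis code they ground-truth. The recording generator inserts a
biphasic 1.2 ms template (0.4 ms negative lobe, 0.8 ms recovery) with
amplitude in units of σ, so detection difficulty is a single dial (a
warning flags < 6σ as expectedly lossy); population bursts occur at
0.65 Hz — the synchronized-burst frequency reported for mature connected
cultures — first in the left compartment and 120 ± 20 ms later in the
right, matching the observed delay scale. Per-electrode burst spikes are
Poisson(8) over a 150 ms front-loaded envelope, satisfying the 5-in-100 ms
rule with high probability. The default desk-scale geometry is 16
electrodes at 20 kHz and 60–120 s durations; rates, amplitudes and delays
— not size — are what the downstream estimators are sensitive to.

The PAC generator is the standard coupled-envelope construction
(envelope 1−χ+χ(1+cos φ_slow)/2), which makes MI provably zero in
expectation at χ = 0 and monotone in χ. The entrainment generator locks
bursts 1:1 to pulses after the configured induction delay and realizes the
post-cessation exponential decay as a deterministic rate-following train
(integrated-intensity construction) — a Poisson realization at ~1 Hz
would carry ±0.18 Hz of window noise, larger than the 75%-crossing
resolution being tested, whereas the deterministic train has exactly the
specified rate function and an exact closed-form crossing.

What passing on these generators does *not* show: robustness to electrode
drift, non-stationary noise floors, overlapping spike waveforms needing
sorting, or field potentials with realistic 1/f structure. The generators
validate estimator logic, not acquisition artifacts.

## Numerical choices and degenerate inputs

* Container I/O is a single-file RDS serialization of the validated
  recording object with CSV side-cars for electrode maps and stimulus
  logs; time is seconds from recording start with half-open intervals
  [start, end), sample i covering [i/fs, (i+1)/fs).
* Filters refuse band edges at or above Nyquist; converters refuse
  unknown units rather than guessing.
* Constant signals yield σ = 0 with a warning; zero-variance inputs to
  cross-correlation or phase coupling return NA with a warning.
* Power-law fits with < 3 distinct sizes are flagged degenerate (no
  estimate); < 50 avalanches flags low confidence. Log-log histogram bins
  with zero counts are dropped rather than imputed.
* `simulate_branching` refuses branching ratio ≥ 1 without a size cap.
* HH integration reports divergence (|V| > 200 mV) with the failing step
  rather than returning garbage rasters.
* Burst CV needs ≥ 3 bursts; fewer returns NA with a warning.

## Problem sizes

The bundled analyses and tests run at desk scale, chosen so the full
suite completes in minutes on one core while keeping every estimate's
sampling error far inside its test tolerance: 10⁵ cascades for exponent
recovery (SE ≈ 0.005–0.007), 100 s PAC signals at 1 kHz, 60–120 s
synthetic recordings at 16 × 20 kHz, 90 s HH sessions of 2 × 200 neurons,
and 900 s entrainment sessions (bursts are events, not samples). Nothing
in the methods depends on these sizes.

## Known limitations

* No spike sorting: thresholded multi-unit activity per electrode.
* The wavelet coherence significance is not assessed against surrogate
  data; the package reports the estimator, not p-values.
* The HH model is a phenomenological two-population caricature: point
  neurons, no synaptic plasticity, no conduction-velocity distribution
  along the bundle, and its parameters are presets rather than fits to
  the recorded tissue. It reproduces ordering and silencing phenomena,
  not quantitative burst statistics.
* The propagation-speed estimate resolves lags only down to one sample;
  zero-lag pairs are flagged unresolved rather than reported as infinite
  speed estimates.
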