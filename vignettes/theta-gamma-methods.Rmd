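---
title: "Models and methods: theta-driven PING in an entorhinal E-I network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: theta-driven PING in an entorhinal E-I network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind the
package: the network model, the analysis conventions, what the synthetic
generators do and do not emulate, and the places where the design was
genuinely open.

## The circuit model

The network holds 400 excitatory stellate cells (E) and 100 parvalbumin-
positive fast-spiking interneurons (I), all single-compartment
conductance-based models integrated at dt = 0.025 ms. Stellate cells are
never connected to each other; gamma arises purely from the E-I loop
(PING) assisted by mutual inhibition and gap junctions inside the I
population.

**Stellate template.** Transient Na (m³h) and delayed-rectifier K (n⁴)
spike currents with classic stellate kinetics, plus a persistent Na
current (instantaneous-activation approximation, τ = 0.15 ms) and a
two-component (fast/slow) hyperpolarization-activated H current, on a
5·10⁻⁵ cm² patch (C = 75 pF). The H and NaP conductances (30 and 15 nS)
and the leak reversal (−72.8 mV) were set jointly so the cell rests near
−62 mV, shows the sag/rebound phenotype, fires under the 15 nS theta
drive, and is strictly quiescent at rest. The prior stellate-database
models this template stands in for are defined in other works and not
restated numerically; the population statistics, not any exact parameter
set, are the contract here.

**PV template.** A Wang–Buzsáki-type fast-spiking model (instantaneous
Na activation, φ = 5 kinetics) on C = 85 pF with leak reversal near
−64.5 mV — close under its spike threshold, as real PV cells sit, so a
gamma-synchronous excitatory volley recruits it within 1–2 ms.

**Heterogeneity and the quiescence invariant.** Every maximal conductance
carries per-cell lognormal jitter (CV 0.20 by default; leak-reversal
jitter 1 mV for E, 2 mV for I). Lognormal tails can produce tonically
active parameter combinations, so the population constructors screen each
candidate set by simulating the isolated cells for 4 s and redraw
offenders with progressively shrunken jitter. Every sampled cell is
therefore quiescent at rest by construction and fires only under drive or
synaptic input.

**Synapses.** I→I GABA: biexponential, rise 0.3 ms, decay 2 ms, reversal
−75 mV. I→E GABA: 0.4/6 ms, reversal −65 mV, lognormal peak conductances
(configured mean 0.15 nS scaled ×5, σ_log 0.5). E→I AMPA:
single-exponential, decay 1 ms, reversal 0 mV, fixed 0.8 nS. All chemical
delays are uniform on 0.6–1 ms. Conductance waveforms are normalized so
the configured weight is the peak conductance, and synaptic events are
queued in a delay ring buffer at step resolution. Gap junctions couple
20% of unordered I pairs with g(V_j − V_i) currents (0.8 nS default),
antisymmetric by construction.

**Weight calibration.** The absolute I→I and I→E weight scales and the
gap conductance are not fixed by published values; they are configuration
constants calibrated once so that the default-drive network oscillates in
the gamma band (~70–90 Hz at desk scale) with the PING phenomenology:
PV bursts on a substantial fraction of gamma cycles, stellate cycle
skipping, and an EPSC→IPSC correlogram lag of ~3 ms. That lag decomposes
into ~1.8 ms of event lag (synaptic delay plus PV integration) plus
~1.2 ms of waveform-shape phase: the 6 ms IPSC decay carries more phase
lag at gamma frequency than the 1 ms EPSC decay, and the cross-correlation
of the band-filtered currents sees both terms.

**Drive and readouts.** The optogenetic-like drive is a half-wave-
rectified sinusoidal conductance g(t) = g_peak·max(0, sin 2πft)
(default 8 Hz, 15 nS peak, reversal 0 mV) applied to E cells only, after
5 s of unstimulated settling that lets the slow H states equilibrate.
Five readout cells per population are voltage-clamped — stellates at 0 mV
(the AMPA reversal, isolating IPSCs as positive-going currents) and PV
cells at −70 mV (near the GABA reversals, isolating EPSCs as
negative-going currents). Clamped cells never spike, so the clamp cannot
feed back into the network. Recorded current uses the outward-positive
voltage-clamp convention I = Σ g·(V_hold − E_syn).

**Scaled networks.** `default_network(scale = s)` multiplies population
sizes by s and divides the per-edge weight scales by s, preserving each
cell's expected aggregate synaptic conductance. The test suite runs the
250-cell (s = 0.5) configuration; the acceptance script simulates the
full 500-cell network.

## Spectral conventions

Filtering is 4th-order Butterworth applied forward and reverse (zero net
phase). The filters are designed in zero-pole-gain form and applied as
cascaded second-order sections with steady-state-initialized states plus
odd reflective padding sized to the slowest pole: transfer-function
coefficients of the narrow printed bands (50–200 Hz at 30–40 kHz;
0.1–3 Hz at 800 Hz) are numerically singular, while the biquad cascade is
exact to machine precision (validated against analytic magnitude
responses in the tests).

The scalogram uses the analytic Morlet wavelet (ω₀ = 6) on a log-spaced
grid with 32 voices per octave. Normalization is chosen so a sinusoid of
amplitude A yields peak power A² at its frequency, independent of
frequency; the 20 pA² quality-control threshold is interpreted on this
scale. Cycle averaging drops the first stimulation cycle (transient
network behaviour), rejects cycles whose raw signal exceeds 3000 pA
(currents) or 1000 µV (LFP), and averages up to 40 cycles. Bandwidth is
measured at half maximum on the cycle-averaged frequency profile
(linearly interpolated), and the QC signal-to-noise ratio divides the
peak by the mean power over the analyzed band — the denominator is
averaged over frequency of the cycle-averaged power, one of several
defensible readings, and is configurable.

Cross-correlograms are Pearson-normalized per analysis window (zero mean,
unit variance), averaged across windows (stimulation cycles 2–6 in the
standard protocol), then searched for the extremum of the requested
polarity. The reported lag is negative when the first signal precedes the
second; for periodic gamma correlograms the `first = TRUE` mode returns
the local extremum nearest zero lag — the "first peak" — rather than the
global one, which can sit a full gamma period away.

## Fluorescence spike extraction

The cascade follows the printed constants exactly: 0.1–3 Hz zero-phase
bandstop to obtain F_fast; dF/F against the mean; inversion (the
indicator is negative-going); noise σ estimated as the standard deviation
of the negatively rectified, linearly detrended first 100 ms after
stimulation offset; peak detection on the 50 Hz-highpassed trace with
MinPeakDistance 2 samples, MaxPeakWidth 6 samples (width at half height),
MinPeakProminence 0.0075 (an absolute dF/F value — the one scale-dependent
constant, kept absolute and exposed in configuration), MinPeakHeight
2σ_noise; then detected peaks are excised (± one half-width, linear
interpolation — the removal method is unstated, so the simplest one is
used), σ_SR recomputed on the residual trace, and peaks below 3.5σ_SR
discarded. Neurons with SNR_peak < 3.75 are excluded, as are "constantly
firing" neurons, operationalized (the paper does not quantify it) as
spiking in more than 95% of 50 ms bins.

Two structural consequences of this cascade are worth knowing. First, on
pure Gaussian noise the final 3.5σ_SR threshold still passes a fraction
of noise local maxima (a few tenths per second at 800 Hz, independent of
the noise scale), so a detector false-discovery rate of a few percent
against a realistic spike rate is intrinsic, not a bug. Second, the
SNR_peak of noise-only detections concentrates just above 3.75 (= 3.5
plus the mean exceedance of the tail), so the 3.75 neuron cutoff excludes
empty neurons with high but not certain probability. The tests assert the
quantities this cascade actually controls — ≥90% sensitivity and ≤10%
FDR at snr_peak = 8, monotonicity in SNR, translation equivariance and
amplitude-scale invariance — rather than idealized zero-false-positive
behaviour.

## Phase statistics

Instantaneous phase is the angle of the FFT analytic signal of the
zero-phase band-filtered trace (60–120 Hz for gamma). The phase
convention is cosine-like: 0 at the filtered-signal peak, ±π at the
trough, so "firing near the trough" reads as |phase| ≈ π. Downsampling
interpolates the unwrapped phase linearly and rewraps; filtered traces
are downsampled with cubic splines. Spike phases are looked up at the
nearest sample (at 30+ kHz the error is negligible; at 800 Hz the frame
quantization is a real limitation shared with the recordings this
emulates). Bursts (inter-spike interval < 6.67 ms) contribute only their
first spike. Vector strength R is the mean resultant length; PPC is
computed by the O(N) identity (N·R² − 1)/(N − 1), which the tests verify
against the brute-force pairwise sum to 10⁻¹² on every draw; pooled
statistics concatenate phases across cells before computing R and PPC.

## Clustering

Distances are d = 1 − r on Pearson correlations over the stimulation
window; linkage is average; the dendrogram is cut with the depth-2
inconsistency criterion at 1.1 (a link is consistent when its height's
z-score against the link heights within two levels below, itself
included, is ≤ 1.1; sd = 0 gives coefficient 0). A subtlety: a link whose
two child links have near-equal heights approaches the three-point
maximum coefficient 2/√3 ≈ 1.155 > 1.1, so *exactly* exchangeable
clusters — all within-cluster correlations identical — are over-cut by
construction. Real populations are not exchangeable, and the synthetic
generator therefore jitters the per-neuron mixing weight slightly
(σ = 0.03 on √r); with that realism the planted partition is recovered
essentially perfectly. Leaf ordering minimizes the summed distance
between adjacent leaves by the exact dynamic program for populations up
to 60 neurons (the study regime is ~41), falling back to the
agglomeration order beyond.

## Synthetic data: scope and limits

The generators emulate the structure the pipeline is sensitive to —
theta-gated gamma amplitude (half-wave-rectified envelope), planted
EPSC/IPSC lags, negative-going spike transients with controlled
peak-SNR on drifting baselines, latent-factor correlation structure with
spatially compact clusters, von Mises phase concentration — with
i.i.d. Gaussian noise throughout (the noise model implied by estimating
noise as a standard deviation). They do not emulate photon shot noise
statistics, movement artifacts, photobleaching beyond the bandstop's
reach, electrode drift, or cross-contamination between ROIs. Passing the
recovery tests therefore demonstrates that the pipeline implements its
definitions correctly and is well-conditioned at realistic SNR, not that
it is robust to every artifact class of real recordings.

Default protocol constants mirror the acquisition conditions: stimulation
at 4/8/12/16 Hz with 16/23/17/16 cycles, 500 ms unstimulated padding,
800 Hz imaging frame rate, 30 kHz electrophysiology rate, positions on a
1160 × 325 px field at 1 µm/px. The fluorescence firing-rate default
(20 Hz during stimulation) approximates a theta-driven stellate; spike
kernels are biexponential with ~2-frame half-width at 800 Hz, satisfying
the detector's 6-sample width ceiling (indicator kinetics are not
quantified in the source, so the kernel time constants are exposed as
configuration).

## Known limitations

- The E→I lag reported by the cross-correlogram is ~2.9–3.0 ms under the
  default calibration. Both 2.1 ms and 3 ms appear as printed values for
  this quantity in the source material; the model sits on the latter.
  Reducing the waveform-shape component further would require altering
  the printed synaptic time constants.
- Gamma peak frequency varies more across drive frequencies at full scale
  (~20% max deviation) than at the 250-cell desk scale (~9–11%), because
  the long 4 Hz depolarized phase sustains faster gamma; the stability
  property is asserted at desk scale.
- Scalogram QC (SNR ≥ 5) is tuned for sustained oscillations; strongly
  theta-gated synthetic currents with half-cycle silence can sit below
  the bar even when clean. This mirrors the conservative intent of the
  rule (excluding weak recordings) rather than a detection failure.
- The PV and stellate templates are stand-ins with matched phenotypes,
  not refits of the cited calibrated populations; conclusions that depend
  on fine intrinsic-property distributions should not be drawn from them.
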