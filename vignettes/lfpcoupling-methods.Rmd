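---
title: "Detecting HFOs and interictal discharges and quantifying their coupling"
author: "lfpcoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting HFOs and interictal discharges and quantifying their coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpcoupling)
```

## The problem

In rodent models of Alzheimer's disease, hippocampal networks become
hyperexcitable: interictal epileptiform discharges (IEDs — sharp transients
between seizures) grow more frequent, and high-frequency oscillations
(HFOs, 80–500 Hz bursts) change in rate and composition. Beyond the rates
themselves, the *temporal coupling* between the two — IEDs appearing to
trigger HFOs — is a candidate electrophysiological biomarker of memory
impairment. This package implements the full analysis chain on continuous
local field potentials (LFP): staged automatic detection of both event
classes, an entropy-based coupling statistic on the peri-event time
histogram (PETH) with bootstrap significance, and state-stratified rate and
behavior-regression summaries. Because no public dataset accompanies the
original in-vivo experiments, the package also ships a first-class
synthetic-LFP generator with known ground truth, so that every stage is
testable end to end.

## Synthetic sessions

`simulation_config()` / `generate_coupled_session()` produce one session:

* **Background**: spectrally shaped Gaussian noise with power
  $\propto 1/f^{\alpha}$ (FFT-filter method), default $\alpha = 1$ and
  SD 50 (arbitrary µV-scale units). This is the simplest stationary
  surrogate with a realistic spectral slope; it has no oscillatory
  rhythms, non-stationarity, or artifacts.
* **HFO atoms**: Hann-windowed sinusoids ("Gabor atoms"), default 6 cycles.
  Ripple-band carriers are drawn uniformly on 85–195 Hz, fast-ripple
  carriers on 205–495 Hz (a 5 Hz margin keeps no truth atom ambiguous at
  the 200 Hz class boundary or the filter edges). Amplitude is
  parameterized as a multiple (default 6×) of the SD of the 80–520
  Hz-filtered background, which makes detector SNR directly interpretable.
* **IED atoms**: a sharp biphasic difference-of-Gaussians spike (fixed 3 ms
  width — the broadband "vertical stripe" the HFO detector must reject),
  plus a Tukey-windowed ~70 Hz fast-activity component whose duration is
  the atom's `width_ms`, plus an optional half-sine slow wave. The fast
  component is what the IED detector's 60–80 Hz band actually measures; a
  lone difference-of-Gaussians spike of width $w$ carries essentially no
  60–80 Hz energy once $w \gtrsim 50$ ms, so it alone cannot produce
  detected durations that track the atom width. Amplitude is calibrated per
  atom so that its peak on the normalized squared signal (NSS, below) hits
  a target in baseline-SD units (default 30). Background interference
  spreads realized peaks by roughly ±8 SD around that target, so a few
  percent of atoms genuinely fall under the printed 20 SD acceptance
  threshold — detector recall against all injected truth is therefore
  ~0.95, not 1.0, by construction.
* **Coupling**: IED times are homogeneous Poisson (default 2/min) within
  the event states (default NREM only); each IED independently triggers
  one HFO with probability `coupling_prob` at a lag
  $\mathcal{N}(50\,\mathrm{ms}, 20\,\mathrm{ms}^2)$ (the lag scale is a
  simulation knob, not an empirical claim); uncoupled HFOs form an
  independent Poisson stream (default 2/min). A triggered HFO whose lag
  would leave the recording is redrawn once, then dropped.
* **States**: default schedule repeats 25 min NREM / 5 min REM. Sleep
  staging itself is out of scope; state labels are always consumed as
  input.
* **Behavior**: per-animal task completion times
  $y_i = a + b\,h_i + \varepsilon_i$ with Gaussian noise.

Everything is reproducible from `seed`. What passing tests on this
generator do **not** show: robustness to real-world artifacts (chewing,
movement, electrical noise), non-stationary background, overlapping event
clusters, or volume-conducted events — the generator is deliberately
stationary and sparse.

## HFO detection

Four stages per channel, within the selected sleep states:

1. **Band-pass + envelope.** Zero-phase frequency-domain band-pass with
   square-root raised-cosine edges; the amplitude gain is exactly
   $1/\sqrt{2}$ (half power) at the configured 80 and 520 Hz edges
   (transition width 20 Hz). The envelope is the analytic-signal magnitude,
   lightly smoothed (Gaussian, 2 ms). Candidates are maximal runs above
   `center + 3 × scale`, where center/scale are the per-state median and
   1.4826×MAD of the envelope; run extents are widened to the surrounding
   excursion above 1 robust SD, runs closer than 10 ms are merged, and each
   must last at least max(6 ms, 3 cycles at its dominant frequency,
   estimated from zero crossings). Three cycles rather than four: a
   6-cycle Hann atom spends only ~60–70 % of its nominal duration above
   any practical boundary threshold, so demanding 4 of 6 nominal cycles
   would systematically discard textbook bursts.
2. **Sharp-transient rejection.** A Morlet map (7 cycles, 40 log-spaced
   frequencies 60–600 Hz), normalized per frequency by its median over
   baseline probes. Sharp transients spread power vertically; a candidate
   is rejected when mean normalized power below 80 Hz at the in-band peak
   time reaches the in-band peak power (ratio threshold 1.0).
3. **Morphology ("bulb") filter.** Keep a candidate iff the in-band
   normalized peak reaches the power floor (default 30×, placed in the
   gap of the bimodal separation seen on calibration simulations, where
   baseline excursions cluster well below it and genuine 6×-SNR bursts
   well above),
   and the supra-half-maximum blob around the peak is compact (relative
   frequency extent ≤ 1) and isolated from the low-frequency edge by a
   ≥ 6 dB trough (a blob touching the lowest analysis frequency is never
   isolated).
4. **Background cleanup.** Events whose envelope peak falls below the
   99.9th percentile of the state's envelope distribution are removed.

Accepted events are classified by the frequency of maximal normalized
time–frequency power: ripple below 200 Hz, fast ripple at or above it (the
boundary frequency is assigned upward — the published ranges overlap at
exactly 200 Hz, so a deterministic tie-break is required). All thresholds
are baseline-relative, which makes the detector invariant to global signal
scaling.

## IED detection

The normalized squared signal (NSS) chain: anti-aliased resampling to
1250 Hz, zero-phase 60–80 Hz band-pass (resampling first is numerically
better conditioned and equivalent for a band far below the output
Nyquist), squaring, Gaussian smoothing with σ = 5 ms (a 10 ms boxcar
leaves >20 % ripple at twice the carrier frequency and fragments events),
and centering/scaling into baseline-SD units. The baseline is robust
(median/MAD, then mean/SD after excluding suprathreshold samples once), so
events do not inflate their own threshold.

Candidates are maximal runs above **5 SD**; runs peaking under **20 SD**
are rejected (`low_peak`); onset-crossing durations outside **30–250 ms**
are rejected (`duration`). The final "Shannon entropy correction"
eliminates shape transitions: each event's NSS profile, scored over a
window twice the event duration, is summed into 10 time bins and its
entropy compared against 0.9 ln 10. A genuine discharge is concentrated
relative to its surround (low entropy); a step or plateau that persists
across the window approaches the ln 10 maximum and is rejected. Scoring
strictly within the event cannot separate the two cases — between its own
5 SD crossings even an ideal triangular discharge has entropy
2.18 > 0.9 ln 10 — which is why the surround is included. The operation is
isolated in `entropy_shape_filter()` so alternative readings can be
swapped in. Manual curation is not implemented; the automated criteria
stand in for it, and rejected candidates can be exported for external
review via `keep_rejected = TRUE`.

## Coupling

`build_peth()` anchors time zero at each IED and collects HFO lags in a
half-open ±500 ms window, 10 ms bins (N = 100; the window is published,
the bin width is a package choice that resolves ripple-scale lags and is
logged with every result). With bin probabilities $p_i$:

$$S = -\sum_{i=1}^{N} p_i \ln p_i, \qquad S_{max} = \ln N, \qquad
h = \frac{S_{max} - S}{S_{max}}.$$

Natural logarithms throughout; empty bins contribute 0; an empty window
yields $h = 0$ flagged "undefined" rather than an error. $h$ is 0 for a
uniform histogram and 1 for perfect lag locking.

**Significance.** Surrogates circularly shift all event times by a uniform
offset (wrapping), preserving each stream's structure while destroying
cross-dependence; `p = (1 + k)/(n_{boot} + 1)`. Two practical points:

* State-restricted streams must first be mapped onto concatenated
  within-state time (`collapse_to_state_time()`); otherwise surrogate
  events wander into unanalyzed gaps that contain no anchors and the null
  is biased.
* Surrogate ranking uses the count-weighted entropy deficit
  $G = 2 n (S_{max} - S)$ (the G statistic for histogram non-uniformity)
  rather than $h$ itself: $h$ is scale-free in the in-window count, and a
  surrogate window holding one stray event scores $h = 1$, which would
  make the test powerless exactly when coupling is strong and surrogate
  windows are near-empty. $G$ is strictly increasing in $h$ at fixed
  count, degenerates to 0 (not 1) for empty windows, and is exchangeable
  under the null, so type-I calibration is preserved (verified by Monte
  Carlo in the test suite). The reported `h`, `S`, `S_max` follow the
  formulas above unchanged.

**Comparing h across conditions.** The plug-in entropy of a binned PETH is
count-biased (sparse histograms look concentrated; dense ones populate
distribution tails), so `coupling_strength_rarefied()` evaluates the exact
expected $h$ of a fixed-depth subsample (multivariate hypergeometric —
rarefaction, as used for ecological diversity indices) for fair
comparisons between pooled PETHs of different sizes. Note that $h$
saturates in `coupling_prob` once most anchors carry a triggered event:
between 50 % and 100 % coupling the histogram shape barely changes and
only the uncoupled-background dilution (a few percent) separates the
levels.

## Rates and behavior

`occurrence_rates()` counts events whose peak lies in the requested sleep
state (half-open intervals, membership brute-force checkable) over the
analyzed state time; the default unit is events/min as in the figure
axes, with a `per_sec` flag covering the alternative stated in the methods
text. `summarize_groups()` gives per-stratum group means, SEMs and Welch
t statistics (group sizes are unequal in the motivating experiments);
omnibus repeated-measures ANOVA and multiplicity control are intentionally
left to external tools. `regress_behavior()` is ordinary least squares
with Pearson r, $R^2 = r^2$, and the two-sided t-test on n − 2 degrees of
freedom.

## Numerical choices and degenerate inputs

* All filtering is frequency-domain and exactly zero-phase; band edges are
  half-power points by construction (the test suite sweeps tones in 5 Hz
  steps to verify 80/520 Hz empirically).
* Resampling is Fourier truncation (ideal anti-aliasing); lengths follow
  `round(duration × rate)`.
* Sample indexing is 0-based with half-open occupancy
  $[k/f_s, (k+1)/f_s)$; all public times are seconds.
* Degenerate inputs error early and explicitly: empty recordings, all-zero
  signals (zero baseline scale), empty anchor streams, fewer than 3
  animals for regression, constant predictors.
* Fixture I/O is 32-bit float; one write–read cycle is near-lossless
  (relative error < 1e-6) and the file itself is the canonical bit-exact
  representation. EDF export is 16-bit quantized interchange only.

## Problem sizes used in the test suite

Detector performance is scored on three 30-minute single-channel sessions
(recall and precision pooled across seeds); bootstrap calibration uses 100
replicates × 200 surrogates; monotonicity pools 20 sessions per coupling
level. These sizes put every Monte-Carlo check comfortably inside a few
minutes on one core while keeping binomial confidence bands tight enough
to be meaningful.

## Known limitations

* The generator is stationary 1/f noise plus isolated atoms; detector
  precision on real recordings with artifacts will be lower, and the
  background-cleanup percentile (99.9) may need retuning.
* The sharp-transient and bulb criteria are quantitative stand-ins for
  published intent ("remove sharp transients", "non-bulb shape"); their
  thresholds (ρ = 1.0, floor 30×, 6 dB isolation) are package defaults,
  all exposed in `default_config()`.
* Coupling is within-channel/within-region; cross-regional coupling and
  phase–amplitude metrics are out of scope.
* Per-session $h$ at low event rates is dominated by finite-count bias;
  compare conditions via pooled PETHs at a common rarefied depth, or test
  significance with the bootstrap, rather than comparing raw per-session
  $h$ values.
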