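# lfpcoupling

Detection of high-frequency oscillations (HFOs) and interictal
epileptiform discharges (IEDs) in continuous local field potentials
(LFP), and quantification of their temporal coupling — an analysis
pipeline for rodent electrophysiology in models of Alzheimer's-type
hippocampal hyperexcitability.

## Who this is for

Electrophysiologists working with chronic multi-site LFP recordings
(e.g. hippocampus, mPFC, striatum, thalamus at 3000 Hz) who need:

* automatic, staged **HFO detection** (80–520 Hz band; envelope
  threshold → time–frequency sharp-transient rejection → "bulb"-shape
  morphology → background cleanup) with ripple / fast-ripple
  classification at 200 Hz;
* automatic **IED detection** on the normalized squared signal (60–80 Hz
  band, 1250 Hz resampling, 5 SD onset / 20 SD peak thresholds,
  30–250 ms duration window, entropy shape filter);
* **IED→HFO coupling**: the peri-event time histogram (PETH) of HFO lags
  around IED anchors in a ±500 ms window, scored by the Shannon-entropy
  coupling strength with circular-shift bootstrap significance;
* **state-stratified occurrence rates** (NREM/REM, events/min) and
  behavior regressions (completion time vs electrophysiological
  measure);
* a **synthetic-LFP generator** with known ground truth (1/f background,
  Gabor HFO atoms, spike-and-wave IED atoms, tunable coupling) so the
  whole chain is testable without any recording.

## The statistic at its core

For a PETH with `N` bins and bin probabilities `p_i`:

    S     = -Σ p_i ln(p_i)          (Shannon entropy, nats)
    S_max = ln(N)
    h     = (S_max - S) / S_max     (coupling strength, 0..1)

`h = 0` for temporally unstructured HFO lags, `h = 1` for perfect lag
locking. Significance comes from circularly time-shifted surrogates of
the HFO stream (the standard point-process null), ranked by the
count-weighted entropy deficit `G = 2 n (S_max - S)` so that near-empty
surrogate windows do not masquerade as strong coupling;
`p = (1 + k)/(n_boot + 1)`.

## Worked example

Simulate a 10-minute hippocampal session in which 80 % of IEDs trigger
an HFO ~50 ms later, then run both detectors and the coupling analysis:

```r
library(lfpcoupling)

cfg <- simulation_config(duration_s = 600, coupling_prob = 0.8, seed = 42,
                         state_schedule = data.frame(label = "NREM",
                                                     start_s = 0,
                                                     end_s = 600))
sess <- generate_coupled_session(cfg)

hfo <- detect_hfos(sess$recording)          # NREM by default
ied <- detect_ieds(sess$recording)

a <- collapse_to_state_time(ied$peak_time_s, sess$recording$states, "NREM")
e <- collapse_to_state_time(hfo$peak_time_s, sess$recording$states, "NREM")
bootstrap_significance(a$times, e$times, a$span_s, n_boot = 200, seed = 1)

cols <- intersect(names(hfo), names(ied))
occurrence_rates(rbind(hfo[, cols], ied[, cols]), sess$recording$states,
                 by = c("region", "kind"), state_labels = "NREM")
```

This prints:

```
<coupling_result> h = 0.6439 (S = 1.6397, S_max = 4.6052), p_boot = 0.004975 (200 surrogates)

       region kind state analyzed_minutes n_events rate
1 hippocampus  hfo  NREM               10       35  3.5
2 hippocampus  ied  NREM               10       17  1.7
```

Read: 35 HFOs and 17 IEDs were detected in 10 NREM minutes (3.5 and
1.7 events/min). The PETH of HFO lags around IED anchors is far more
concentrated than uniform (entropy 1.64 nats vs the ln(100) = 4.61
maximum), giving coupling strength h = 0.64; none of the 200
circular-shift surrogates matched it, so p ≈ 0.005 — the detected
coupling is real, as it should be for a session simulated with 80 %
IED→HFO triggering.

The `analysis/` directory holds the numbered drivers of the full study
workflow — `01_simulate_cohort.R` (a FAD+/FAD− cohort with
group-dependent IED rates and coupling), `02_detect_events.R`,
`03_coupling_analysis.R`, `04_rates_and_behavior.R` — each a thin
narrative over the package functions, writing its tables under
`results/`.

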