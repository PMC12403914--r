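Package: lfpcoupling
Title: Detection of High-Frequency Oscillations and Interictal Discharges
    in Local Field Potentials and Entropy-Based Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for rodent intracranial local field
    potentials (LFP): simulation of synthetic multi-channel recordings with
    1/f background, ripple/fast-ripple oscillation bursts and epileptiform
    spike transients with known ground truth; staged automatic detection of
    high-frequency oscillations (80-520 Hz) and interictal epileptiform
    discharges (normalized squared signal with 5/20 SD thresholds);
    quantification of IED-HFO temporal coupling via the Shannon entropy of
    the peri-event time histogram with circular-shift bootstrap
    significance; and sleep-state-stratified occurrence rates with
    behavior regression summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
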