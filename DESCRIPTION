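Package: neonapnea
Title: Respiratory Phenotyping of Neonatal Mouse Plethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects respiratory cycles in whole-body plethysmography
    recordings of newborn mice, estimates the cut-off respiratory cycle
    (CORC) duration that separates repetitive breathing from isolated
    apneic cycles, quantifies the apneic time fraction, classifies apneas
    as breath-holding or central-like from the pressure waveform, detects
    airway "clicks" in synchronized ultrasound audio with two-point clock
    drift correction, and aggregates per-pup metrics with normality-gated
    group comparisons.  A synthetic-recording generator with full ground
    truth emulates neonatal breathing so that every stage of the pipeline
    can be validated without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
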