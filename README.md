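# neonapnea

Respiratory phenotyping of newborn mice from whole-body plethysmography.

Neonatal mice of some genotypes die within hours of birth from apneic
breathing.  Quantifying that phenotype from a chamber-pressure trace requires
answering four questions per recording: where are the respiratory cycles,
which cycles are apneas, of which type (breath-holding with air retained in
the lung, versus central-like with the lung deflated), and — in joint
ultrasound-audio recordings — which apneas end with the "click" of a closed
airway reopening.  `neonapnea` implements that chain for physiologists
working on neonatal breathing and airway obstruction, together with a
calibrated synthetic-recording generator so every stage can be validated
against ground truth.

## The statistics at the core

* **CORC (cut-off respiratory cycle)** — the duration threshold separating
  the repetitive-breathing population from isolated apneic cycles.  Two
  estimators: the Poincaré-plot route (`corc_poincare()`), which identifies
  cycles similar to both neighbours, fits a single Gaussian to their
  durations and sets `CORC = mean + 4·SD`; and the threshold-scan route
  (`corc_logthd()`), which uses the linearity of the apneic time fraction
  in `log(ThD)` and extrapolates down to the departure point.
* **ATF (apneic time fraction)** — `sum of apneic-cycle durations /
  recorded time`, partitioned exactly into breath-holding and central-like
  components by `classify_apneas()` (plateau level relative to the
  end-expiratory baseline, plus click association).
* **Ventilation variables** — per-cycle `F_R = 60/(Ti+Te)` breaths/min,
  `V_T` (µL, after 2.5 µL syringe calibration), `V_E = F_R·V_T/1000`.
* **Click detection and clock sync** — sub-millisecond broad-band transients
  found by an energy + spectral-flatness detector; audio and pressure clocks
  (rated ±50 ppm) aligned by a two-point fit on a shared trigger pulse and
  chamber knock, to sub-2 ms over ten minutes.

## Worked example

Simulate a mutant-genotype pup, run the pipeline, and read off the apnea
statistics:

```r
library(neonapnea)

profile <- build_profile("mutant_n4A_P0_12h")
rec <- simulate_recording(profile, duration_s = 300, seed = 1, audio = FALSE)
analysis <- analyze_recording(rec)
analysis
#> CORC estimate: 0.520 s (method: poincare)
#> Apnea summary: ATF 33.7%, 44 apneas (CORC 0.520 s)
#>   breath-hold 26.6%, central-like 7.1%
#> F_R 141.0 breaths/min, V_T 7.52 uL, V_E 1.060 (per g: 0.757)

rec$truth$atf      # programmed ground truth for the same recording
#>        total  breath_hold central_like
#>    0.3369887    0.2663757    0.0706130
```

The CORC lands between the regular cluster (~0.4 s cycles) and the
programmed apneas (1.2 s and longer), and the measured ATF (33.7% total,
26.6% breath-holding) matches the programmed ground truth of this particular
seed; across a 17-pup cohort the mean converges to the profile's calibrated
expectation of 29.3%.  Cohorts and group statistics:

```r
cohort <- simulate_cohort(profile, n_pups = 17, duration_s = 300, seed = 1)
metrics <- per_pup_metrics(cohort$recordings)
round(100 * mean(metrics$atf), 1)
#> [1] 30.7

control <- per_pup_metrics(
  simulate_cohort(build_profile("control_P0_12h"), 17, 300, seed = 2)$recordings)
compare_groups(metrics$atf, control$atf)
#> unpaired t test: statistic 18.69, p = 2.769e-18 (n = 17/17)
```

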