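---
title: "Quantifying neonatal apneas from whole-body plethysmography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neonatal apneas from whole-body plethysmography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neonapnea)
```

## The measurement problem

Newborn mice breathe in short, fairly regular cycles (a few hundred
milliseconds) punctuated, in some genotypes, by isolated long cycles —
apneas.  In whole-body plethysmography the only observable is the chamber
pressure, sampled here at 1 kHz with inspiration plotted upward.  Two apnea
phenotypes must be told apart from that single trace:

* **breath-holding apneas** — expiratory flow stops just after an
  inspiration, so the trace plateaus *above* the end-expiratory baseline
  (air is retained in the lung).  The hold may carry resuming inspiratory
  efforts of growing amplitude and typically ends with a small upward
  pressure shift immediately followed by an abrupt deflation.  In joint
  audio recordings that shift coincides with a sub-millisecond broad-band
  "click", the acoustic signature of a closed airway reopening; and
* **central-like apneas** — a normal breath followed by a long pause with
  the lung deflated, i.e. a flat segment at baseline.

The package implements the full chain from raw pressure (and optional
ultrasound audio) to cohort-level statistics, plus a generator that
synthesizes recordings with known ground truth so that every stage can be
validated quantitatively.

## Respiratory-cycle segmentation

`segment_breaths()` detects inspiration onsets on the low-pass-filtered
(20 Hz) trace after subtracting a running baseline.  Within a cycle, `Ti`
runs from the onset to the inspiratory peak and `Te` from the peak to the
next onset, so `duration = Ti + Te` exactly and apneic pauses are absorbed
into the enclosing cycle's `Te` — the convention under which cycle durations
populate Poincaré plots.  Ventilation variables follow the standard
formulas: per-cycle frequency `F_R = 60/(Ti + Te)` breaths/min (the only
dimensionally valid reading of the conventional shorthand `1/Ti + Te`),
tidal volume `V_T` as the mean inspiratory amplitude in µL after syringe
calibration (`calibrate_volume()`, default 2.5 µL), and
`V_E = F_R · V_T / 1000`.  Whether `V_E` is normalized by body weight varies
between laboratories, so both forms are returned.

Two numerical choices matter:

* **Baseline.** A running *median* over a window comparable to an apnea
  duration is dragged up by breath-hold plateaus (holds last up to ~3.5 s),
  after which the resuming efforts riding the plateau cross the detector
  thresholds and split the hold into spurious short cycles.  The baseline is
  therefore a running **10th percentile over 5 s**: as long as a window
  retains a modest fraction of near-baseline samples, the estimate stays at
  the end-expiratory level and the whole hold remains one cycle.
* **Hysteresis.** An onset fires when the baseline-subtracted trace crosses
  15% of the running tidal amplitude, and only if it has re-armed below 5%
  since the previous onset; the onset time is the arming-level crossing.
  The two-level scheme makes detection immune to noise of SD up to ~5% of
  `V_T` and to plateau-riding efforts (the trace never re-arms during a
  hold).  A 0.1 s refractory period suppresses sub-physiological intervals.

Sync marks (trigger pulse, chamber knock) are blanked by interpolation
before filtering so they cannot masquerade as breaths.  Cycles whose
amplitude exceeds 5× the running median are flagged as movement artifacts
and excluded from ventilation summaries, mirroring the restriction of the
analysis to quiet breathing.

## The CORC statistic

An apneic cycle is an *isolated* cycle longer than the **cut-off respiratory
cycle** (CORC) duration.  Both published routes to the CORC are implemented:

* `corc_poincare()` — cycles whose duration is within tolerance of *both*
  neighbours form the repetitive set; a single Gaussian summarises it and
  `CORC = mean + k·SD` with `k = 4` by default.  The neighbour tolerance is
  3 robust SDs of the first differences of duration, so "about the same
  duration" adapts to each record.  `k = 4` places the boundary far enough
  out that, at a few hundred cycles per record, essentially no regular cycle
  exceeds it, while remaining well below the shortest programmed apneas.
* `corc_logthd()` — the apneic time fraction `ATF(ThD)` (summed duration of
  cycles longer than a threshold `ThD`, divided by recording time) falls
  linearly with `log(ThD)` inside the apneic duration range.  The line is
  fitted on the clearly apneic range (`ThD ≥ 3×` median duration) and the
  CORC is the largest grid point whose observed ATF departs from the fit by
  more than 3 residual SDs, on a 40-point descending log grid.  The "3
  residual SDs" rule is this package's concrete reading of "departs
  significantly"; the published analysis does not specify a test.

When the two populations are well separated, *any* threshold inside the gap
selects the identical apnea set, which is why the two estimators agree on
the apneic population even when their numerical thresholds differ — and why
the acceptance tests compare the *apnea sets* (symmetric difference < 5%)
rather than the raw thresholds.  Consecutive apneic cycles violate the
isolation assumption; they are counted individually but flagged.

## Apnea typing

For each apneic cycle `classify_apneas()` measures the **plateau level**:
the median trace level during the pause (from 1.5 regular-cycle durations
after the onset to 0.15 s before the cycle end), relative to the local
baseline, in units of `V_T`.  The rule is: breath hold if the plateau is
≥ 0.3 `V_T`, or if a click falls within ±100 ms of the pause-terminating
deflation and the plateau is ≥ 0.1 `V_T`; central-like if the plateau is
below 0.1 `V_T`; anything between 0.1 and 0.3 without a click is flagged
`ambiguous` and resolved to central-like — the same conservative tie-break
the manual two-reviewer validation used.  The thresholds are exposed as
arguments; the published figures show plateaus well above baseline but give
no number, so 0.3/0.1 are declared package defaults.  The per-type apneic
time fractions partition the total exactly by construction.

## Clicks, clock drift and alignment statistics

`detect_clicks()` high-passes the audio at 5 kHz (zero-phase FFT filtering,
overlap-save on long traces), forms a 0.2 ms running-RMS envelope, and
thresholds it at `median + 8·MAD`.  Candidates longer than 2 ms (knocks,
vocal syllables) are rejected, detections within 10 ms are merged, and
tonal events are rejected by spectral flatness: the maximum Wiener entropy
over five 0.6 ms frames around the event peak must exceed 0.4.  Evaluating
flatness within the event's own extent keeps a genuine broad-band transient
from being diluted by the surrounding noise floor, while ultrasonic
vocalization surrogates (near-pure tones) stay far below the threshold in
every frame.

Consumer-grade acquisition clocks are rated at ±50 ppm, which accumulates to
tens of milliseconds over a session — far more than the sub-2 ms precision
needed to associate clicks with pressure events.  `fit_sync()` solves the
two-point linear map from the trigger pulse (start) and chamber knock (end)
detected in both channels; both marks are located as the peak of a matched
moving average of the squared signal, so the detected time is the mark's
centre in either channel and mark-shape differences cancel.
`peri_event_histogram()` (20 ms bins; 1 s windows, 2 s for breath holds)
and `click_context_fractions()` quantify time-locking and the distribution
of clicks across breathing contexts; the central bin is half-open
`[-bin/2, +bin/2)` with ties to the earlier bin, a convention chosen purely
for reproducibility.

## The synthetic-data generator

`simulate_recording()` renders, at 1 kHz, regular cycles (quarter-sine
inspiration over `Ti`, exponential return over `Te`), breath holds
(inspiration, fall to a plateau at 0.8 `V_T`, optional resuming efforts
growing linearly from 0.2 to 1.0 `V_T`, a 0.15 `V_T` upward shift 130 ms
before cycle end, then rapid deflation; a click is emitted at the shift with
the profile's probability), central-like apneas (a normal breath followed by
a baseline pause) and vocal cycles (faster active expiration with a
compression dip; 15–20 kHz tone surrogates and compression-locked clicks in
the audio channel).  Audio is rendered at 50 kHz by default — enough to
carry the 0.5 ms broad-band clicks and tonal surrogates that define the
detection problem at desk-scale file sizes; the analysis accepts any rate
≥ 20 kHz.  Both channels carry a 10 ms trigger near the start and a knock
impulse at 96% of the duration; the audio clock runs at
`1 + drift_ppm·1e-6` times the pressure clock.

Cycle kinds are drawn per cycle, but apneas are kept *isolated* (the cycle
after an apnea is forced regular), matching their definition.  A naive
Bernoulli draw under that constraint would under-produce apneas, so the
draw probabilities after a non-apneic cycle are rescaled to
`p/(1 − p_bh − p_cl)`; the stationary kind fractions then equal the plain
mixture probabilities, and the closed form in `expected_summary()`,

`ATF_t = p_t E[D_t] / ((1 − p_bh − p_cl) μ_reg + p_bh E[D_bh] + p_cl E[D_cl])`,

is exact for the generator.  Regular durations are truncated-normal
(μ = 0.4 s, σ = 0.03 s, floor 0.1 s — a 150 breaths/min neonatal rhythm);
apneic durations are uniform (breath holds 1.5–3.5 s, central-like
1.2–2.8 s), simple laws chosen because the source data report none.  Vocal
bouts (5 cycles) relabel would-be-regular cycles, so they leave the apnea
calibration untouched.

The registry in `build_profile()` inverts the closed form so each cohort's
*expected* ATFs equal the published means (mutant 29.3% total / 22.6%
breath-hold; control 12.3% / 8.3%; null 1.7% breath-hold with the
central-like channel set to the control value, which the source does not
report; wild-type joint-audio 9.7% breath-hold).  The wild-type profile
additionally calibrates the vocal bout rate and stray click probabilities so
the expected click-context proportions are 81.5 : 15.0 : 2.2 : 1.1
(vocal : breath-hold : eupnea : central), anchored on a 69.5% breath-hold
click probability.  `apply_treatment()` derives its scale factors from the
same closed form: PTZ shortens the regular cycle by 15% and solves the
breath-hold probability for a halved total ATF (a reduction comfortably
beyond the reported 40%); CNO solves both channels for a five-fold total
ATF; saline is the identity.  A `dreadd_baseline` profile (5% total ATF) is
registered as the chemogenetic pre-injection state, so the five-fold CNO
effect lands on the reported ~25% plateau.

**What the generator does *not* emulate** — movement artifacts, chamber
temperature/humidity drifts, heartbeat ballistics, realistic vocal syllable
structure, gradual post-natal deterioration — bounds what passing tests
show: they validate the estimators against the programmed phenomenology,
not the full messiness of animal recordings.  Thresholds that are free
parameters here (plateau cut-offs, detector bands) would need re-checking
against manually scored real data.

## Problem sizes and reproducibility

Validation uses 300 s records (the standard acquisition length) with
cohorts of 10–17 pups matching the published group sizes, and a single
600 s dual-clock recording for the synchronization check; at these sizes the
full suite runs in minutes on one core.  Cohort seeds derive per pup as
`seed + pup index`, so every figure in the README and every acceptance
number is reproducible bit for bit.  Under Monte-Carlo variation a cohort
mean is compared to its target within 3 standard errors of the simulated
sample — the resolution the sample sizes themselves allow.

## Known limitations

* The CORC estimators assume a dominant repetitive population; records that
  are mostly apneic (no Gaussian cluster) raise an error rather than
  guessing.
* `corc_logthd()` inherits the arbitrariness of its departure rule; its
  value within the inter-population gap is stable, but on overlapping
  populations the 3-SD choice moves the boundary.
* Typing of apneas with plateaus near the thresholds depends on the
  declared cut-offs; the `ambiguous` flag marks exactly those cases.
* Click detection parameters were validated only against the simulator's
  click model (broad-band 0.5 ms bursts at high SNR).
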