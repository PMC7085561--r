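---
title: "Methods: gravity-trace repetition counting and agreement analysis for the Senior Fitness Test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gravity-trace repetition counting and agreement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msft)
```

## The measurement problem

The Senior Fitness Test (SFT) is a six-item field battery for older adults:
three repetition-counted items (30-second chair stand, 30-second arm curl,
2-minute step in place), two manually measured flexibility distances
(chair sit-and-reach, back scratch, signed centimetres) and one stopwatch item
(8-foot up-and-go). A smartphone strapped to the thigh or forearm can count
the repetition items automatically from its *gravity sensor*: a software-fused
virtual sensor whose output is the gravity vector in device coordinates, with
magnitude close to standard gravity (9.81 m/s²) at all times. As the limb
rotates, gravity redistributes between the device axes; for the mountings used
here the rotation is confined to the y–z plane, so the y component alone
carries the movement signal:

| item          | baseline posture (y)          | active posture (y)          |
|---------------|-------------------------------|-----------------------------|
| chair stand   | sitting, phone flat (≈ 0)     | standing, vertical (≈ −9.8) |
| arm curl      | arm extended (≈ −9.8)         | curled past vertical (≈ +8.5, above the +7.5 datum) |
| 2-min step    | standing (≈ −9.8)             | thigh horizontal (≈ 0)      |

One repetition is one baseline → active → baseline cycle, credited when the
signal *returns* to baseline.

## Signal model and simulator

`simulate_trace()` generates traces by rotating a pitch angle φ between a
baseline and an active value with raised-cosine ramps, then mapping
y = −g sin φ, z = g cos φ, x = 0. Because the rotation is rigid, the noiseless
trace satisfies |g| = 9.81 m/s² at every sample to machine precision — a
structural invariant the test suite asserts at 1e−9. Gaussian noise of
standard deviation `noise_sd` is added per axis *after* norm construction, so
noisy norms fluctuate around 9.81 as real fused-sensor output does. A baseline
mounting tilt (±20°) rotates the baseline posture only.

Parameters and defaults:

* `rep_period_s` — full-cycle period. Defaults are 1.4 s (chair stand),
  0.95 s (arm curl) and 0.9 s (step), chosen so that the largest repetition
  count in the 60–69-year normative band (mean + 2 SD) completes inside the
  item's time limit: participants pace themselves to finish within the test,
  and a slower cadence would make high normative counts physically
  inconsistent with the 30 s / 120 s windows.
* `transition_frac = 0.3` — fraction of the period spent ramping; observed
  leg-strength traces show smooth, roughly sinusoidal transitions rather than
  square edges.
* `sample_rate_hz = 50` — a typical Android sensor "game" rate; algorithms use
  actual timestamps, the rate is metadata.
* `noise_sd = 0.2` m/s² — moderate fused-sensor noise; the detectors are
  validated up to 0.5 m/s².
* lead-in/lead-out plateaus of 1.5 s mimic the operator pressing start before
  the first repetition.

`simulate_battery()` draws the per-item repetition count uniformly from the
60–69 band mean ± 2 SD (chair stand 9–19, arm curl 12–28, step 82–118),
giving fixtures that span the realistic range. All simulation is seeded and
leaves the caller's RNG state untouched.

What the simulator deliberately does **not** model: imperfect or asymmetric
movement (partial stands, compensatory trunk lean), sensor-fusion transients,
drift, or autocorrelated noise — real gravity-sensor noise is not white.
Passing the round-trip tests therefore demonstrates that the detector is
correct *for the waveform class it was designed around*, not that it is robust
to pathological movement; that caveat applies equally to any bench validation
of this kind of instrument.

## Detector

`count_repetitions()` implements a two-state hysteresis machine on the
moving-average-smoothed y channel (window 5 samples, centred, edges shrink
symmetrically — which also makes smoothing exactly mean-preserving for
constant-extended signals):

* BASELINE → ACTIVE when the active predicate holds continuously ≥ 0.15 s;
* ACTIVE → BASELINE, crediting a repetition at the transition sample's
  timestamp, when the baseline predicate holds continuously ≥ 0.15 s.

Default bands (m/s²): chair stand — active y < −8.0, baseline |y| < 2.0;
arm curl — active y > +7.5, baseline y < −5.0; step — active y > −2.0,
baseline y < −8.0. Two deliberate choices:

* The chair-stand/step active threshold is −8.0 rather than the −9.8 datum:
  −9.8 is the extreme of the waveform, and a noisy signal need not attain its
  exact extremum; −8.0 (the phone within ~35° of vertical) detects every real
  excursion while the ≥ 6 m/s² gap to the baseline band keeps noise from
  crossing both thresholds. The arm-curl +7.5 threshold is kept as the datum
  itself since the simulated active plateau (+8.5) already clears it.
* The 0.15 s dwell debounce: the fastest plausible sit-to-stand or knee-raise
  phase lasts far longer than 150 ms, while single-sample noise spikes do not.

Degenerate inputs are well-defined rather than errors: a flat trace counts 0;
a trace that ends mid-active-phase leaves the last repetition uncounted and
sets `incomplete_final_phase`; a trace that *starts* active begins in the
ACTIVE state and the interrupted repetition completes on its first return to
baseline; samples after the item's time limit are discarded before detection,
so they can never affect the count.

The state machine is evaluated run-wise (qualified runs of each predicate via
run-length encoding) rather than sample-wise; this is algebraically identical
to the per-sample automaton and fast enough to process hundreds of two-minute
traces per second. Simple threshold logic was preferred over trained
classifiers deliberately: it is interpretable, configurable per patient, and
runs in real time on low-cost hardware.

## Normative scoring

Results are compared against the Rikli–Jones reference means and SDs per
10-year age band (60–69, 70–79, 80–89), shipped as a plain CSV so alternative
tables can be substituted. "Within the normal interval" is operationalised as
|z| ≤ 1 with z = (value − mean)/SD; the band half-width is a parameter. The
packaged table is sex-pooled (a single value per cell); sex-specific tables
are an extension point, not a default. Ages outside 60–89 clamp to the nearest
band and the classification is flagged `clamped_age`, because validation
cohorts routinely include volunteers in their fifties and refusing to score
them would be less honest than disclosing the extrapolation. For the
up-and-go item lower is better; the z sign is reported as computed together
with a direction note.

## Agreement statistics

For n subjects measured by k methods, `icc()` computes from the ANOVA mean
squares (MS~B~ between subjects, MS~W~ within, MS~E~ two-way residual):

* one-way random: single (MS~B~−MS~W~)/(MS~B~+(k−1)MS~W~), average
  (MS~B~−MS~W~)/MS~B~;
* two-way consistency: the same forms with MS~E~; the average-measures variant
  is identical to Cronbach's α (asserted to 1e−12 in the tests).

Confidence intervals use the exact F pivots for the chosen form. All variances
use n−1 denominators. Degenerate inputs (zero between-subject variance, zero
total variance) raise explicit undefined-statistic errors; a zero residual
with positive subject variance yields ICC 1 with a degenerate interval.

The default form is **two-way consistency, average measures**. On the packaged
seven-volunteer fixture the published agreement column (0.93–0.99) coincides
numerically with Cronbach's α — i.e. with the consistency/average form — and
its chair-stand confidence interval matches that form's F-pivot interval,
whereas the one-way random single-measures estimate on the same data is 0.56.
Both families are implemented and the report states which was used, so either
convention can be reproduced explicitly. Reported precision is two decimals,
the convention of the field's agreement tables.

`bland_altman()` summarises per-subject differences against pair means with
limits of agreement at mean ± 1.96 SD of the differences; on simulated
Gaussian pairs the empirical coverage of the limits is 0.95 ± 0.01 at
n = 5 000, which the acceptance suite checks. Interpretation labels follow the
conventional cut-offs (ICC: ≤ 0.4 poor, ≤ 0.75 fair-to-good, above that
excellent; α: ≤ 0.5 unacceptable, ≤ 0.9 poor-to-good, above that excellent),
with boundary values assigned to the lower band — the published prose
("below … between … over") is ambiguous exactly at the boundaries, so the
conservative reading was fixed and documented.

## SUS scoring

`sus_score()` is the standard Brooke scheme: ten 5-point items of alternating
polarity, odd items contributing (response − 1), even items (5 − response),
scaled by 2.5 onto 0–100. Note every valid single-rater score is a multiple
of 2.5. Aggregation labels a mean below 50 unacceptable, 50–70 (inclusive)
marginal, above 70 good. The module is validated by construction — extremal
patterns, the mirror symmetry s ↔ 100 − s under answer complementation, and
boundary labels — since raw multi-rater questionnaire data are rarely
published.

## Records and interfaces

Sessions, persons and sensor buffers live in a single-file JSON document store
(versioned via `schema_version`), keeping the tool fully offline and its
fixtures human-readable; sessions reference persons and buffers reference
sessions, with referential integrity enforced on upsert. Age is derived from
birth date at the session date rather than stored, so it can never go stale.
Partially completed sessions are first-class: summaries list missing items
instead of failing. The command-line interface is a thin dispatcher over the
same exported functions and emits machine-readable JSON (CSV on request).

## Problem sizes and verification

The test suite validates the detector round trip on 50 seeded simulations per
item per noise level (0, 0.2, 0.5 m/s²), requiring exact ground-truth
recovery in all 450 runs; ICC implementations against a brute-force
sums-of-squares oracle on 100 random 5×2…8×3 matrices at 1e−9; the α/ICC
identity on 100 random two-rater matrices at 1e−12; and Bland–Altman coverage
on 5 000 simulated pairs. These sizes give stable statistics while keeping the
whole suite under a minute on a single core.

## Known limitations

* The detectors assume the two-plateau waveform; movements that stall inside
  the hysteresis gap (e.g. a half-stand) are — by design — not counted, and
  biomechanically impaired movement patterns are untested territory.
* White Gaussian noise is a stand-in; the spectral character of real fused
  gravity output is device-specific and not modelled.
* The normative table is sex-pooled; clinical use with sex-specific reference
  values requires dropping in the corresponding table.
* Agreement statistics require complete pairs (listwise completeness); there
  is no missing-data machinery, matching the small-n validation designs the
  module targets.
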