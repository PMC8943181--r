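---
title: "Models and methods behind orsmoke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind orsmoke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orsmoke)
```

## The measurement problem

Electrocautery devices release a plume of volatile organic compounds (VOCs)
— aldehydes, nitriles, aromatics, dienes — into operating-room (OR) air.
Real-time proton-transfer-reaction time-of-flight mass spectrometry
(PTR-TOF-MS) can quantify hundreds of these species at 1 Hz in ppb-by-volume,
which makes it possible to ask practical occupational-health questions: how
much of which compound does the surgical team inhale, which species exceed
OSHA/NIOSH permissible exposure limits, and whether a smoke evacuation
system (SES), the surgical approach (open vs minimally invasive), or
distance from the cautery tip changes exposure.

orsmoke implements the analysis layer of such a study: it starts from
per-operation concentration time series (the output of vendor peak
quantification — raw spectral processing is out of scope) and produces
per-operation summaries, hazard-panel and exposure-limit reports,
inhaled-dose and breath-uptake estimates, and randomized-design statistics.
Because raw instrument data from such studies are typically not deposited, a
synthetic OR-air simulator with known ground truth is part of the package
and is what the test suite exercises end to end.

## The compound registry

The packaged panel (`load_registry()`) transcribes a 32-row table of harmful
VOCs observed at surgeon level without SES: identity (name, CAS numbers),
hazard classes, OSHA and NIOSH limits where assessed, and the recorded
average and maximum concentration per compound. Three transcription
decisions matter downstream:

* **Isobaric rows stay merged.** PTR-MS cannot separate isobars, so rows
  such as "Acetone/Propanal" or "1,3-butadiene/1-Butyne" are one record with
  all CAS numbers attached and the molecular weight of the first-listed
  compound. Molecular formulas are supplied from compound identity (the
  source table lists none) and are needed only for mass conversion.
* **Suspect limit cells are transcribed verbatim and flagged.** The methanol
  limit cell prints 4200 and the ethanol cell 100,0000; regulatory limits
  for both compounds are conventionally quoted in ppm, so the ppb reading is
  doubtful. These rows carry `limit_suspect = TRUE`; the exceedance screen
  evaluates them like any other limit but reports them in a separate
  footnote section rather than guessing the intended unit.
* **The column totals are internally consistent.** The average column sums
  to 272.71 ppb, matching the recorded 272.69 total within last-digit
  rounding of 32 two-decimal entries; the maximum column sums to 8991.01,
  matching the recorded integer total 8991. Reports print the column sums.

`protonated_mass()` supports exact-mass identification: PTR ionization
yields MH+, so the monoisotopic neutral mass plus 1.00728 u is the ion
observed. For the small molecules in the panel, monoisotopic and average
molecular mass differ by well under 0.5 u, which the tests assert for every
record.

`applicable_limit()` returns the *more stringent* (minimum) of the OSHA and
NIOSH limits — the conservative screening choice — and `NA` ("unassessed")
when neither exists; unassessed compounds are listed but never flagged.
Exceedance is a strict inequality: a maximum exactly at the limit does not
flag.

## Signal processing

An `ion_series()` carries a 1 Hz time axis, one ppb column per compound, and
half-open `[start, end)` segment windows following the instrument protocol:
pre-operation blank, standard-gas calibration, operation, closing blank.

* **Blank subtraction** removes the per-channel mean of the pre-operation
  blank from every sample. Negative values are *retained*: clipping at zero
  would bias means and totals upward.
* **Calibration** is single-point: one factor per channel per operation,
  `standard / mean(calibration segment)`, multiplying the whole record so
  that the calibration segment reads the known standard. Sensitivity drift
  within an operation is not modelled, mirroring the bracketing
  blank/calibration protocol. In the pipeline, calibration is applied to the
  raw record before blank subtraction, so the recovered factor is exactly
  the inverse instrument sensitivity; both operations are linear, so the
  order affects only that exactness.
* **Summaries** are computed over the operation segment only — the
  statistics describe surgery-time exposure, not blanks. The time of each
  channel's maximum is normalised by segment length
  (`argmax_time_fraction` in [0, 1]); ties break toward the earliest
  sample, a deterministic rule consistent with the interest in
  early-operation maxima. The "total VOC" and "harmful total" traces are
  pointwise sums over channels, so blank subtraction and totalling commute.

## Exposure model

Concentration-to-mass conversion is ideal gas: `ug/m3 = ppb × MW / Vm`,
with the molar volume derived as `Vm = R·T/P`. Defaults are 25 °C and
101.325 kPa, giving 24.47 L/mol — within 0.1% of the industrial-hygiene
convention figure of 24.45 L/mol. The inhaled dose over an operation is

    dose_ug = ppb × 1e-9 × (MV × t / Vm) × MW × 1e6

with minute ventilation MV = 5 L/min and duration t = 120 min by default,
the conventional assumptions for OR personnel. At these defaults a 136 ppb
mean acetaldehyde concentration gives 147 µg per operation; because the
source study's corresponding figure (146 µg) implies a molar volume of
about 24.6 L/mol and no temperature/pressure convention is stated, the
package fixes the thermodynamic convention above and treats agreement
within ±2% as exact. Dose is linear in concentration, ventilation and
duration, and invariant under (T, P) pairs with equal molar volume.

Breath uptake is the mean inhaled-minus-exhaled concentration difference
over the operation; the uptake *fraction* divides by the inhaled mean and
is clipped to [0, 1] with a flag (instrument noise can push the raw ratio
outside). When the inhaled mean is not positive the fraction is undefined
but the absolute difference is still reported. Reported uptakes in this
setting span essentially the full range — ~1% for phenol up to ~90% for
butadiene — which is why both the ppb difference and the fraction are
returned rather than a single normalised number (published per-breath
percentages in this area are ambiguous about their denominator).

Cigarette equivalence divides an inhaled mass by per-cigarette emitted
masses (acetaldehyde 2000 µg, 1,3-butadiene 130 µg per unfiltered
cigarette); compounds without a reference return `NA` rather than zero.

## The synthetic OR-air generator

The simulator is the package's substitute for unreleased raw data, and its
defaults are the study conditions the rest of the package is tested under:

* **Cautery events** form a homogeneous Poisson process during the operation
  segment (default 2 activations/min). Each event releases, per compound, a
  log-normal concentration amplitude (default sd = 2 × mean). The log-normal
  family is the simplest that reproduces the heavy-tailed maxima seen in OR
  air, where the maximum harmful total exceeds the average by a factor of
  ~30.
* **Clearance is first-order**: each plume decays as `exp(-k t)` with
  `k = 0.02 s^-1` by default, a desk-scale stand-in for the local dilution
  produced by a laminar-flow OR ventilation system (0.3–0.6 m/s downdraft).
  No spatial airflow is modelled.
* **Design factors act multiplicatively on emission amplitudes**: SES use
  attenuates by 0.5 (the same halving conventionally assumed when power
  analyses correct concentrations for doubled distance), room-air
  measurement dilutes by 0.5, and open surgery scales by 1.3 (the observed
  open-vs-minimally-invasive maximum ratio is about 1.3). Multiplicative
  coding keeps the statistics module's linear recovery well-posed.
* **Background and instrument effects**: anesthetic carrier gases
  (sevoflurane, desflurane) appear as constant background rather than
  cautery emissions; Gaussian noise is added; and the entire record is
  scaled by a true sensitivity (`calib_true_factor`), which is exactly what
  single-point calibration must undo. Blank windows contain background
  only; the calibration window contains the standard.
* **`sim_config_from_registry()`** chooses per-event amplitudes so that the
  model's stationary operation mean, `rate × E[A] / k` above background,
  approximates each compound's panel average — i.e. simulated operations
  look like the recorded ones at surgeon level.

Everything is reproducible bit-for-bit from (design, config, seed), and the
ground truth (event times, amplitudes, analytic expected means) is returned
alongside each simulated record.

What the simulator does *not* emulate: particulates and aerosols, viral or
cellular payloads, spatial gradients, within-operation sensitivity drift,
correlated multi-compound plumes (amplitudes are drawn independently per
compound), and non-Poisson surgeon behaviour such as long cutting bursts.
Passing parameter-recovery tests on this generator therefore demonstrates
that the analysis chain is correct and well calibrated, not that any given
real OR matches these effect sizes.

## Statistics

* **Two-group comparisons** use Welch's two-sided t-test. Published p-values
  in this setting come without a named test, and the reported group spreads
  are visibly unequal, so the unequal-variance form is the safe default. The
  degenerate identical-constant-groups case returns p = 1.
* **Effect decomposition** regresses a per-operation response on one 0/1
  indicator per factor (SES used, open approach, surgeon level) plus an
  intercept, by ordinary least squares. Coding one indicator per *level*
  (e.g. both "with SES" and "without SES") alongside an intercept is rank
  deficient and has no unique solution; the one-indicator-per-factor coding
  is the minimal full-rank equivalent, and with a single varying factor its
  coefficient equals the difference of group means exactly. The multiple
  correlation R and residual sd are reported; collinear codings raise an
  error naming the offending columns rather than silently dropping terms.
  No multiple-testing correction is applied to per-compound comparisons
  (matching the raw-p-value reporting convention); reports state the number
  of tests run.
* **Time-of-maximum distribution**: per operation the K = 100 channels with
  the largest maxima are selected ("highest concentrations" is read as
  ranking by per-operation maximum, consistent with the emphasis on
  maxima), their normalised times-of-maximum pooled, and the pool tested
  against the uniform distribution on [0, 1] — the only distribution-free
  null for "no systematic timing" — with a one-sample Kolmogorov–Smirnov
  test (asymptotic form; the 1 s grid induces ties that the exact test
  cannot handle).
* **Sample size** uses normal-approximation power evaluated against the t
  critical value, `power(n) = pnorm(d * sqrt(n/2) - qt(1 - alpha/2, 2n - 2))`,
  returning the smallest integer n ≥ 2 per group reaching the target. At
  the design point d = 1.22, alpha = 0.05, power = 0.90 this gives 15 per
  group. The approximation sits within Monte-Carlo error of brute-force
  simulated power (the exact noncentral-t power at n = 15 is 0.897; the
  rule's documented approximation is what fixes the returned n, and the
  test suite verifies the simulated power curve crosses the target at this
  scale).

## Numerical choices and test problem sizes

Simulation-based checks run at desk scale, chosen once as faithful
miniatures of the study conditions rather than full-length operations:

* Parameter-recovery replicates use 100 operations of 120 s at 2
  events/min with moderate amplitude spread (sd = mean) — enough events per
  operation that the response is well away from the zero-event edge case,
  and enough operations that a halving SES effect is recovered with the
  correct sign in ≥ 95% of replicates.
* Power checks at the study's n = 15 per arm use 240 s operations with low
  amplitude spread (sd = 0.2 × mean), where the simulated standardized
  effect comfortably exceeds the design's minimum detectable d = 1.22.
* Null-calibration replicates use ~30 events per operation (10/min for
  180 s); with sparser events the per-operation mean is dominated by a
  zero-event point mass and no t-test would be near nominal — a property of
  the degenerate miniature, not of the method.
* Monte-Carlo tolerances are stated in the tests as multiples of the
  empirical standard error (typically 3), or as the absolute bands the
  corresponding design property implies (e.g. type-I rate 0.05 ± 0.02 over
  500 replicates).

Degenerate inputs are errors, not warnings: empty registries, missing
segments, non-positive calibration means, odd randomization blocks,
out-of-range uptake fractions and rank-deficient design matrices all fail
with messages naming the offending operation, channel or column.

## Known limitations

* The exceedance screen compares instantaneous maxima against limits that
  are mostly 8-hour time-weighted averages or short-term exposure limits;
  it is a conservative screen, not a compliance determination.
* Dose estimation assumes a constant mean concentration and fixed minute
  ventilation; real breathing varies with workload.
* The effect decomposition is linear on a multiplicative truth; its
  coefficients are first-order approximations of the multiplicative
  factors, which is why the tests check sign and ordering rather than
  coefficient values on simulated data.
* Group statistics from any particular study cannot be reproduced without
  its raw per-operation dataset; the package's claims are therefore
  calibration and recovery properties on synthetic data, plus the
  deterministic worked examples above.

## A worked pipeline run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(out_dir = "orsmoke-demo", n_ops = 12,
                       duration = 600, seed = 1)
res <- run_pipeline(cfg)
res$decomposition
print(res$exceedance)
```

The run writes `summaries.csv`, `dose_table.csv`, `exceedance.csv`,
`comparisons.csv`, `effect_decomposition.csv`, `max_time_histogram.csv`, a
panel-style `report.txt`, a `run.log` with per-stage counts and seeds, and a
`MANIFEST`; rerunning with the same configuration and seed is
byte-identical.
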