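---
title: "Intraoperative AKI risk modelling from urine oximetry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intraoperative AKI risk modelling from urine oximetry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Acute kidney injury (AKI) after cardiac surgery is common and is diagnosed
late, because the KDIGO criteria rest on serum-creatinine rises or reduced
urine output that only manifest hours to days after the insult.
Renal-medullary hypoxia is a common pathway to injury, and the partial
pressure of oxygen in urine (PuO~2~), measured noninvasively at the
urinary-catheter outlet at 1 Hz, tracks medullary oxygenation well enough to
be a candidate intraoperative risk signal.

`puro2risk` implements an analysis pipeline around that idea: clean the 1 Hz
PuO~2~/urine-flow record, segment it by surgical period, derive
hypoxia-exposure features, select preoperative and PuO~2~ features, train a
bagged support-vector-machine classifier under leave-one-out
cross-validation (LOOCV), and compare a preoperative-only model against a
preoperative + PuO~2~ model with paired statistics (DeLong on AUROCs, exact
McNemar on sensitivity and specificity). Because no public dataset of such
recordings exists, the package ships a synthetic-cohort generator with the
statistical structure the analysis assumes, so every stage runs and is
testable end to end.

## The synthetic cohort

`generate_cohort()` draws, per subject:

* **Demographics**, conditional on the AKI label, from group means/SDs and
  event proportions of a high-risk cardiac-surgery cohort (46 AKI / 27
  no-AKI): age 65 ± 11 vs 62 ± 15 y, BMI 29.38 ± 5.89 vs 26.57 ± 5.32,
  baseline creatinine 1.12 ± 0.26 vs 0.97 ± 0.25 mg/dL,
  insulin-dependent-diabetes probability 14/46 vs 1/27, LVEF &lt; 35 %
  probability 7/46 vs 2/27, and a five-level procedure mix. Weight is
  derived from BMI and a sex-specific height draw (women 162 ± 7 cm, men
  176 ± 7 cm), because the 0.5 mL/kg/h flow-discard rule needs kilograms
  while cohort tables report only BMI.
* **A surgical timeline**: surgery starts at second 0; 1–3 bypass runs
  (probabilities 0.7/0.2/0.1) whose total on-pump time is drawn near the
  group mean (160.42 ± 55.28 vs 167.74 ± 70.25 min), preceded by a 75 ± 15
  min pre-bypass phase and followed by a 90 ± 20 min post-bypass phase.
* **Waveforms** at 1 Hz. PuO~2~ is a discretized Ornstein–Uhlenbeck
  (mean-reverting AR(1)) process — chosen because it produces realistic
  autocorrelated traces with controllable period means — with targets
  μ~pre~ = 50, μ~CPB~ = 42, μ~post~ = 38 mmHg, within-subject SD 8 mmHg,
  mean-reversion rate 0.005 s⁻¹, and linear 5-min ramps at period
  transitions. For AKI subjects the post-bypass target is lowered by
  δ = 10 mmHg by default. These anchors are set once from the clinical
  literature on this monitor (a post-bypass mean below 25 mmHg and
  cumulative time below thresholds near 35 mmHg are the reported
  risk-associated ranges); no per-period population summaries exist to
  calibrate against, so δ is an explicit free parameter of the generator,
  not an estimate.
* **Artifacts**, recorded as hidden ground-truth masks so the QC stage can
  be scored for recall: sporadic flow-sensor error codes (rate 0.002 per
  sample), retrograde-flow blips (rate 5 × 10⁻⁵ s⁻¹, ~5 s, negative flow),
  zero-flow stagnation episodes (rate 10⁻⁴ s⁻¹, mean 120 s), and, with
  probability 0.05 per period, an absent chunk covering 50–95 % of the
  period (device disconnection). Urine flow is log-normal around a
  1.2 mL/kg/h target with slow (10-min time-constant) variation, so the
  trailing flow rate occasionally dips below the 0.5 mL/kg/h discard
  threshold, as in real recordings.

What the generator deliberately does **not** emulate: the raw optical
fluorescence signal and its temperature correction (it emits calibrated
PuO~2~ directly), serum-creatinine trajectories or KDIGO staging (the AKI
label is an input), and any dependence of demographics on the waveform
beyond the group label. Passing tests on synthetic data therefore
demonstrate that the pipeline recovers structure *of the kind assumed*, not
that the clinical effect sizes are reproduced; with the default δ = 10 mmHg
the post-bypass separation is considerably cleaner than clinical reality,
so absolute AUROCs on synthetic cohorts run higher than published clinical
values and only the direction of the model comparison is meaningful.

## Signal QC

Four discard rules compose by union into a per-sample mask
(`compute_qc_mask()`), each with a recorded reason code:

* **error_code** — nonzero flow-sensor error code.
* **retrograde** — negative flow, plus a guard window (default 30 s, on
  both sides) because backflow contaminates adjacent oximetry; the guard
  width is a declared default, not a literature value.
* **stagnant** — a maximal run of |flow| &lt; 0.01 mL/min lasting strictly
  longer than 60 s; urine standing in the tubing equilibrates with ambient
  oxygen.
* **low_flow** — trailing 10-min mean flow, converted to mL/kg/h, strictly
  below 0.5 (clinical urine output is a rate over time; instantaneous 1 Hz
  flow is far too noisy to threshold directly). A relative tolerance of
  10⁻⁹ keeps rates exactly at the threshold from being discarded through
  accumulation rounding.

Periods are half-open intervals in seconds from surgery start: pre-bypass
`[start, first run start)`, bypass `[first run start, last run end)`
including inter-run gaps, post-bypass `[last run end, surgery end)`. A
period is dropped when its missing fraction — QC-discarded plus absent
samples over the period length — strictly exceeds 0.70 ("more than 70 %").
Subjects are excluded for a ventricular-assist device or for any missing
candidate feature.

## Features

Ten preoperative columns (age, sex as female = 1, BMI, baseline creatinine,
insulin-dependent diabetes, LVEF &lt; 35 %, and procedure type one-hot
encoded against an `isolated_cabg` reference) plus, per kept period, four
distribution summaries (mean, 25th percentile, median, 75th percentile;
quantiles interpolate linearly) and, per period × threshold, cumulative
time below and area below the threshold, in minutes and mmHg·min. The
default grid {15, 25, 35} mmHg covers the thresholds reported as
risk-relevant for this signal; with it the table holds exactly 40 candidate
features. Exposure sums use strict inequality (a sample at the threshold
contributes nothing) and are not normalized by period duration by default —
the working hypothesis is cumulative, not fractional, exposure — with a
`normalize_exposure` flag for the variant.

## Selection and the classifier

Preoperative features enter by forward stepwise logistic selection: at each
step every remaining candidate is scored by the Wald p-value of its
coefficient in the expanded multivariable model, and the smallest-p
candidate enters while p &lt; 0.05. Wald was chosen over the
likelihood-ratio score for determinism and convention; there is no backward
elimination, and a retained feature whose p-value later rises only triggers
a warning. Procedure-type dummies enter individually. The PuO~2~ signal
contributes exactly one feature — the maximizer of the univariate AUROC
(Mann–Whitney with half-credit ties, natural direction, lexicographic
tie-break) — to avoid stacking correlated features derived from one signal.

The classifier is bagging over SVMs (`e1071::svm`): each of 100 base
learners fits a bootstrap resample (size N, with replacement; single-class
resamples are redrawn), on features z-scored with training-set parameters.
The RBF kernel uses scale 1/(p·var) and C = 1; no tuning is performed
anywhere. The predicted probability is the vote share of the base
learners' hard predictions, a declared design choice (Platt-style averaged
calibration was rejected as an extra fitted layer on ~70 subjects). Under
LOOCV each fold re-standardizes and retrains on its N − 1 subjects with a
fold-derived seed, so fold order is irrelevant and the held-out subject's
label and row cannot leak into its own prediction — a property the test
suite verifies by mutation.

By default, selection runs once on the full dataset before LOOCV,
replicating the published pipeline's stated order; this leaks selection
information into the folds and makes the cross-validated AUROC optimistic.
`nested_selection = TRUE` re-runs both selection procedures inside every
fold for an honest estimate.

## Comparison statistics

All comparison statistics are implemented in the package:

* **ROC/AUROC** — the curve sweeps unique score thresholds; the area is
  computed both by trapezoid and by Mann–Whitney pair counting and the two
  are asserted equal on every call.
* **DeLong** — placement values per case and control, component
  covariances S₁₀/m + S₀₁/n, z = ΔAUROC /√(var_a + var_b − 2 cov),
  two-sided normal p. Confidence intervals are symmetric normal, clipped
  to [0, 1]. Identical score vectors short-circuit to z = 0, p = 1; other
  zero-variance cases are flagged degenerate. The implementation is
  cross-checked against `pROC::roc.test` and a stratified bootstrap in the
  tests.
* **Confusion summaries** — predicted positive iff probability strictly
  exceeds 0.5 (0.5 itself predicts no-AKI).
* **McNemar** — exact two-sided binomial, `min(1, 2·P(Bin(b+c, ½) ≤
  min(b, c)))`, on the discordant correctness pairs within the true-case
  stratum (sensitivity) and true-control stratum (specificity); the exact
  form suits strata of 46 and 27.
* **Cohort table** — pooled-variance Student t for continuous rows and
  Yates-corrected chi-square for 2×2 categorical rows. These exact
  variants were adopted because recomputing published cohort-table
  p-values from their printed summaries reproduces the printed values only
  under pooling and only with the continuity correction; both
  summary-statistic helpers (`pooled_t_summary()`, `chisq_2x2()`) are
  exported.

## Numerical and design notes

* One global seed derives every stream seed (cohort, per-subject,
  per-estimator, per-fold) through a fixed integer map, so identical
  configurations give byte-identical artifacts.
* Logistic fits use `stats::glm` IRLS with epsilon 10⁻¹⁰ and 100
  iterations; separation is detected from the fitted-probability warning
  or diverging coefficients and flagged rather than silently accepted.
* AUROC ties get half credit everywhere; the best-feature search does not
  reorient features (an AUROC below 0.5 loses), since the reported
  clinical winner is a natural-direction feature.
* Constant feature columns get unit scale during standardization instead
  of dividing by zero.
* Quantiles are R type 7; `[10, 20, 30, 40]` gives q25 = 17.5.

## Problem sizes in the tests

The suite exercises the full pipeline at the default study conditions
(n = 73, prevalence 46/73, δ = 10 mmHg) over 20 seeds for the directional
model comparison, a 30-subject cohort for the per-subject leakage mutation
test, 1100 subjects for demographic calibration (≥ 500 per group, moments
within 3 standard errors), and 2000 bootstrap resamples for the DeLong
variance cross-check. These sizes were chosen to give the property checks
comfortable statistical power while keeping a full run of the suite
desk-scale.

## Known limitations

* The generator's AKI effect is a clean mean shift in post-bypass PuO~2~;
  real signals differ between patients in baseline, dynamics, and artifact
  structure in ways no three-parameter period model captures.
* Absolute performance numbers on synthetic cohorts are not clinical
  estimates; only paired, directional comparisons within a run are
  interpretable.
* The default (non-nested) selection replicates a published pipeline
  order, optimism included — use nested selection for honest error
  estimates.
* The exact retrograde/stagnation detection used by the physical device is
  proprietary to its firmware; the rules here are declared, configurable
  approximations.
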