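---
title: "Refined KDIGO phenotyping of AKI and AKD in general wards: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refined KDIGO phenotyping of AKI and AKD in general wards: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardaki)
```

## The phenotyping problem

The KDIGO creatinine criteria call acute kidney injury (AKI) when serum
creatinine (SCr) rises by at least 0.3 mg/dL within 48 hours, or reaches at
least 1.5 times a baseline within 7 days. Applied naively to general-ward
EHR data these criteria misfire in two characteristic ways:

* **Low baselines.** In patients with healthy kidneys and low SCr
  (baseline under ~0.6 mg/dL), ordinary fluctuation easily crosses the
  1.5-fold bar while the absolute change stays clinically trivial.
* **Transient dips.** A single spuriously low measurement — assay error,
  dilution, a fluid bolus — becomes the 7-day minimum, and the return to
  the patient's real level is then "a rise from baseline".

`wardaki` implements both the standard criteria and a refined operational
definition designed for ward data, so that the two can be compared on
identical series.

### The refined definition

At every measurement the **baseline** is the lowest SCr of the *previous*
7 days, after an exclusion pass: a candidate value is excluded when it sits
at least 0.3 mg/dL below **both** the median of the other window values and
the most recent other window value. Exclusion cascades: if the minimum is
excluded the next-lowest candidate is tested, recursively. An AKI call then
requires

1. an absolute rise of at least 0.3 mg/dL over that baseline, **and**
2. either a baseline measured within the prior 48 hours, or a value
   reaching at least 1.5 times the baseline.

The conjunction in (1) is what removes the low-baseline pathology: a
0.5 → 0.76 mg/dL excursion crosses 1.5-fold but rises only 0.26. The
exclusion rule removes the transient-dip pathology: in the canonical
0.9 → 0.6 → 0.9 mg/dL sequence the 0.6 is excluded (it is exactly
0.3 below both the median and the recent value of its window), the
baseline stays 0.9, and no AKI is called — while the standard criteria
fire on the 48-hour rise 0.9 − 0.6 = 0.3.

Because the refined baseline can never be lower than the raw 7-day minimum
and the refined rule adds a conjunct, **every refined call is also a
standard call**; the property is checked on 10^4 random trajectories in the
test suite rather than merely asserted.

One consequence of reading "lower than the median *and* recent values" as
a conjunction is worth recording: the largest value of a window can never
be 0.3 below the median of the others, so at least one candidate always
survives and the median fallback for an all-excluded window — kept as a
defensive branch, returning the window median with reason
`"all_excluded"` — is provably unreachable. A disjunctive reading would
not have this property; we chose the conjunction because the phrasing
"median and recent" naturally reads as both, and because only the
conjunction reproduces the dip example's declassification without also
discarding legitimately low stable baselines.

### Windows, boundaries and ties

* All thresholds are inclusive (`>= 0.3`, `>= 1.5x`), matching how such
  criteria are written; comparisons use an absolute tolerance of 1e-9
  mg/dL so grid-valued data behave identically across platforms.
* Windows are open at both ends: values strictly after `t - 7 d` and
  strictly before `t`. A measurement is never its own baseline, and a
  value exactly 7 days (or 48 h) old falls outside the corresponding
  window.
* Baseline candidates are scanned in ascending value, ties broken by
  earliest timestamp.
* One AKI event per admission: the first firing measurement is the onset;
  later re-elevations are not new events.
* Calendar days use the local-midnight convention, day 1 being the
  admission date. Timestamps are treated as naive wall-clock times and
  handled in UTC internally, so host timezone settings cannot shift day
  boundaries.
* Recovery (for AKD) is strict: the first post-onset value *below* 1.5
  times the onset baseline, the baseline being frozen at its onset-time
  value — a moving baseline would make recovery ill-defined.

### AKD and label construction

After an AKI onset the 7 following calendar days are scanned. The first
SCr below 1.5 x baseline marks recovery; if none qualifies **and** the
window contains at least one measurement in days 5–7 (so that a late
recovery could have been observed), the patient is AKD; otherwise the
status is *indeterminate* — a value, not an error — and the patient is
excluded from the AKD prediction task. The day 5–7 requirement is our
operationalisation of "insufficient SCr measurements": it is the weakest
rule under which an AKD call is evidence-based rather than an artefact of
the patient simply not being measured.

For the early-warning task, days 1–3 before onset are labeled 1, the onset
day and everything after it are excluded, and all other days are 0. Days
with no SCr measurement in their next 7 calendar days (including the index
day) are excluded, because an onset there could not have been observed.
When directives overlap, exclusion wins and each excluded day carries
exactly one reason, with on/after-onset taking precedence over missing
lookahead. Patients are dropped entirely as *ambiguous* when the refined
detector had to skip candidate evaluations for lack of any baseline (a
>7-day gap between SCr measurements) and no unambiguous onset was found
later.

## Eligibility

Filters run sequentially, each patient attributed to the first rule that
fires: age below 19; fewer than 3 SCr measurements in the stay; eGFR at or
below 60 mL/min/1.73 m² on the first calendar day with an SCr measurement
(first value chronologically that day); and a refined AKI onset on
admission day 1, since prediction needs at least one prior day of data.
Patients whose eGFR cannot be computed (missing age or sex) go to an
explicit `unevaluable` bucket. The report's counts reconcile by
construction and filtering is idempotent. Each admission is treated as an
independent observation unit; readmissions are not linked.

eGFR uses the race-free CKD-EPI 2021 creatinine equation
(142 x min(SCr/k, 1)^a x max(SCr/k, 1)^-1.200 x 0.9938^age x 1.012 if
female; k = 0.7/0.9 and a = -0.241/-0.302 for female/male). The test suite
compares it with an independent log-space evaluation over a
(SCr, age, sex) grid at 0.1 mL/min/1.73 m² tolerance.

## Feature engineering

Records are summarised at 24-hour intervals: vitals as per-day mean,
maximum, minimum and count; labs as the most recent value at or before the
end of the day; exposure flags (nephrotoxic drug classes, surgery under
general anaesthesia, contrast CT, vascular imaging, ICU transfer) ORed
over the trailing 7 days including the index day. Derived features are
eGFR, the BUN/Cr ratio, BMI, and delta features (current value minus the
median of the patient's previous *observed* values — carried-forward
values never enter the history). The feature set is schema-driven
(`feature_config()`) because any particular hospital's selected list is
data-dependent; the shipped default covers the common ward panel.
Physiologic plausibility clipping is configurable per feature, since no
universal numeric bounds exist.

Missing values are handled in two stages, with every cell's provenance
tracked (`observed` / `carried` / `imputed` / `missing_level`):

1. last observation carried forward within the admission;
2. features with residual missingness below 20% (assessed after stage 1,
   on the training rows only) are completed by chained-equation
   imputation — round-robin linear regressions over the other features,
   10 iterations, seeded, fitted on training rows only; features at or
   above 20% are converted to training-quantile tertiles plus an explicit
   `"missing"` level.

Robust scaling ((x − median)/IQR, training statistics only; zero-IQR
features flagged constant and passed through) completes the pipeline. No
evaluation-split statistic can influence any transform; the test suite
perturbs evaluation rows and asserts the training-side outputs are
bit-identical.

## Prediction harness

Cross-validation folds are assigned per patient, never per row, so a
patient's days cannot straddle training and validation; evaluation on
patients seen in training is refused outright. Whether the original
study grouped folds by patient is not documented; we enforce grouping
because the alternative leaks within-patient correlation, and we accept
that this makes our cross-validation conservatively harder. Model
families sit behind one adapter — logistic regression (default, always
available), random forest (`ranger`) and gradient boosting (`xgboost`) —
because the model comparison is a harness feature, not bespoke
methodology. The metric panel (accuracy, precision, recall, specificity,
F1 at cutoff 0.5, AUROC, AUPRC) is verified against a brute-force
confusion-matrix and pairwise-concordance oracle. Calibration uses five
equal-count bins; the slope is the least-squares slope of observed event
rate on mean predicted probability across bins — binned least squares
rather than logistic recalibration, matching the five-group evaluation
style and keeping the statistic transparent; a zero-variance bin
structure is flagged degenerate rather than reported. The framework
simulation replays admissions year by year: an event counts as predicted
early when at least one of its 1–3 pre-onset days is flagged at the
cutoff.

## The synthetic cohort generator

Real ward EHR data cannot be shipped, so every stage is exercised on
simulated cohorts with planted ground truth. Defaults emulate a general
ward: log-normal stays with median ~10 days, ~8% AKI with onset median
~day 7 (2 + Poisson(5)), ~15% of AKI progressing to AKD, recovery times
centred on day 5, plus a ~6% transient-fluctuation class, split 2:1
between a low-baseline pattern (baseline 0.40–0.50 mg/dL with a spike
clearing 1.5x but rising under 0.3) and a dip-then-return pattern
(baseline 1.1, one-day dip of 0.45). Class probabilities are tied to
covariates through a logistic link (age, nephrotoxic-antibiotic exposure)
so the prediction harness has signal to find. Sampling is per-day
Bernoulli (default 0.7) with a boost around events, emulating sicker
patients being measured more; each patient draws from an independent
substream of the global seed, so enlarging a cohort never perturbs
earlier patients, and identical configs yield byte-identical CSVs.

Planted event days are placed with explicit margins against the detector
thresholds (for example, the transient spike is computed relative to the
realized minimum of the *sampled* prior window — exactly the baseline the
detector will see — and AKI stays are extended to keep the 7-day outcome
window in hospital), so that under daily sampling and jitter SD
0.05 mg/dL the planted class, onset day and recovery status are
recoverable by construction. That is what makes "sensitivity and
specificity ≥ 0.99 against ground truth" a meaningful check of the
labeler rather than of the generator's noise level.

What the generator does *not* emulate: correlated multi-organ physiology,
pharmacokinetics, drift in assay calibration, informative missingness
beyond the event-window boost, readmissions, and the long right tail of
real SCr distributions. Passing tests therefore demonstrate correctness
of the labeling logic and harness plumbing on data with known truth — not
clinical performance, which depends on real hospital data that are not
redistributable.

## Problem sizes and runtime choices

The shipped tests use 10^4 random trajectories for the subset and
oracle-equivalence properties, a 1000-patient daily-sampled cohort for
planted-event recovery, a (SCr 0.4–4.0 × age 19–90 × sex) grid for eGFR,
and n = 10^4 for the calibration check; the acceptance script additionally
trains the default logistic model on a ~700-patient labeled split. These
sizes give the properties enough power (e.g. a detector defect with
 >0.05% firing probability would be seen) while keeping a full run in the
low minutes on one CPU.

## Known limitations

* The standard-criteria comparator uses the raw in-admission 7-day
  minimum as baseline; outpatient baselines are not modelled.
* Urine-output criteria, AKI staging beyond stage 1, dialysis and
  transplantation are out of scope.
* The AKD window uses calendar days anchored at the onset day; a
  168-hour reading would shift borderline recoveries (configurable via
  `recovery_window_days`).
* Chained-equation imputation uses linear models without posterior draws;
  it is a deterministic simplification of multiple imputation, chosen for
  reproducibility.
* The delta features use medians of previous observed values and are
  undefined (missing) until a second observation exists.
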