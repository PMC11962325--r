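# wardaki

Electronic phenotyping of **acute kidney injury (AKI)** and **acute kidney
disease (AKD)** from general-ward EHR time series, with an early-warning
prediction harness and a synthetic cohort generator.

## The problem

The KDIGO creatinine criteria define AKI as a serum-creatinine (SCr) rise of
≥ 0.3 mg/dL within 48 h, or ≥ 1.5 × a baseline within 7 days. On
general-ward data — sparser and noisier than ICU data — the criteria misfire
in two ways: in patients with low baselines (< 0.6 mg/dL) ordinary
fluctuation crosses the 1.5-fold bar, and a single transiently low
measurement becomes the 7-day minimum so that the mere return to the
patient's usual level registers as a rise. A patient measured
0.9 → 0.6 → 0.9 mg/dL within 48 hours is "AKI" by the letter of the
criteria, with nothing wrong with their kidneys.

`wardaki` implements, alongside the standard criteria, a **refined
operational definition** built for retrospective ward phenotyping:

* baseline = the *lowest SCr of the previous 7 days*, after excluding any
  candidate that sits ≥ 0.3 mg/dL below **both** the median and the most
  recent of the other window values (a transient-dip filter, applied in a
  cascade until a candidate survives);
* AKI requires an absolute rise ≥ 0.3 mg/dL over that baseline, **and**
  either a baseline measured within the prior 48 h or a value ≥ 1.5 × the
  baseline;
* AKD = SCr not returning below 1.5 × the onset baseline within 7 days of
  onset, with an explicit *indeterminate* status when post-onset sampling is
  too sparse to adjudicate.

Every refined AKI call is provably also a standard call, so the two
detectors bound each other; the package ships a criteria-comparison report
that classifies standard-only calls into low-baseline artefacts and
pre-onset-decrease artefacts.

Around the labeling core sit the rest of a phenotyping-and-prediction
pipeline: cohort CSV readers with row-level validation, eligibility filters
(age ≥ 19, ≥ 3 SCr measurements, first-day eGFR > 60 by CKD-EPI 2021, no
day-1 onset), day-level label construction for early prediction (days 1–3
before onset labeled positive), a per-day feature pipeline (24-h
summarisation, delta-from-median features, two-stage imputation with
provenance, robust scaling), a training/evaluation harness with
patient-grouped cross-validation and binned calibration, and a rolling
yearly deployment simulation. A synthetic ward-cohort generator with
planted ground truth makes every stage testable without hospital data.

## Worked example

The canonical dip patient, then a simulated 500-patient ward cohort:

```r
library(wardaki)

w <- worked_example_series()   # SCr 0.9, 0.6, 0.9 mg/dL within 48 h
detect_aki(w$times, w$values, "standard")
#> AKI (standard) at 2020-03-03 00:00:00: SCr 0.9 vs baseline 0.6 [abs48h+rel7d+min_increase]
detect_aki(w$times, w$values, "refined")
#> NULL
```

The standard criteria latch onto the transient 0.6 as baseline and call AKI
on the return to 0.9; the refined criteria exclude the dip and call nothing.

```r
sim  <- simulate_cohort(sim_config(n_patients = 500, seed = 42))
elig <- apply_eligibility(sim$cohort)
elig$report
#> eligibility: 500 in; excluded 0 (age) + 5 (<3 SCr) + 3 (eGFR<=60) + 0 (day-1 AKI) + 0 (unevaluable); 492 retained

compare_criteria(elig$cohort)
#> AKI criteria comparison
#>            refined           standard      standard_only            neither
#>                 55                 88                 33                404
#>       low_baseline pre_onset_decrease              other
#>                 20                 13                  0
```

Of 88 standard-criteria calls, 33 are declassified by the refined criteria —
20 low-baseline artefacts and 13 pre-onset decreases. The generator planted
55 true AKI, 19 low-baseline and 13 dip patients among those retained; the
extra low-baseline call is an event-free patient whose measurement jitter
alone crossed the standard 1.5-fold bar — exactly the fragility the refined
criteria remove. AKD adjudication on the refined events:

```r
ev  <- detect_aki_cohort(elig$cohort, "refined")
out <- assess_akd_cohort(elig$cohort, ev)
table(out$status)
#>       akd recovered
#>         7        48
```

From there, `build_aki_day_labels()` / `build_akd_labels()` produce the
prediction tables, `summarize_days()` + `compute_deltas()` +
`impute_features()` + `fit_scaler()` the feature matrix, and
`train_models()` / `evaluate_model()` / `run_framework_sim()` the
evaluation. See the methods vignette
(`vignettes/wardaki-methods.Rmd`) for the full account of definitions,
boundary conventions and design decisions, and
`inst/scripts/wardaki-cli.R` for a thin command-line wrapper
(`simulate`, `label-aki`, `label-akd`, `compare`).

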