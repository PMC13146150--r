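# edcadence

How often should a clinical prediction model be retrained? `edcadence` is an
R laboratory for that question, built around paediatric emergency-department
(ED) admission prediction from triage data. A model that estimates each
patient's admission probability at triage can forecast the day's bed demand
by simply summing probabilities — but only while it stays calibrated. As the
case mix, documentation and admission practices drift, a frozen model's
forecasts decay; retraining repairs them at a compute cost that grows with
the cadence. This package simulates the whole trade-off end to end.

It is aimed at researchers studying temporal validation, concept drift and
model-maintenance policy for tabular clinical models, who need a controlled,
fully reproducible stand-in for restricted hospital data.

## What it does

* **Synthetic presentation stream** (`scenario_config()`, `desk_scenario()`,
  `generate_stream()`): seeded multi-year streams with negative-binomial
  daily volumes (quarterly index of dispersion ≈ 2–4, August peak, January
  trough), ~20% admission prevalence driven by a steep 1–5 triage-priority
  gradient, coherent patient-revisit history, optional pandemic-style volume
  trough, and injectable covariate + concept drift at configurable
  changepoints.
* **Stacking ensemble** (`ensemble_spec()`, `fit_ensemble()`,
  `predict_proba()`): a mandatory gradient-boosted learner plus optional MLP
  and ridge-logistic learners under a logistic meta-learner fitted on a
  strictly-later validation split, with SMOTE minority oversampling
  (`oversample_minority()`) on the training partition only. Temporal overlap
  between training, validation and test is refused outright.
* **Rolling prospective simulation** (`run_simulation()`): the test horizon
  is scored day by day while the model is refitted on each cadence's
  schedule on the pseudo-week grid (W1 = days 1–7, W2 = 8–15, W3 = 16–22,
  W4 = 23–month-end), with retrain-count accounting: monthly costs exactly
  25% of weekly, fortnightly exactly 50%.
* **Metrics** (`amdbe()`, `auroc()`, `brier()`,
  `calibration_slope_intercept()`, `ece()`, `threshold_metrics()`,
  `dispersion_index()`, `weekly_rollup()`): the central quantity is the
  absolute mean daily bed error

  AMDBE = mean over days of | Σᵢ p̂ᵢ − admissions | ,

  the average daily gap, in beds, between forecast and realised demand.
  Three patients predicted at 0.1, 0.4 and 0.7 pool to 1.2 expected beds;
  daily absolute errors of 1.5, 3.0, 4.5 and 3.0 beds average to an AMDBE
  of 3.0.
* **Drift diagnostics** (`domain_classifier_auroc()`,
  `reconstruction_drift()`, `drift_report()`, `performance_monitor()`):
  out-of-fold domain classification between time windows (AUROC ≈ 0.5 means
  indistinguishable), PCA reconstruction-error ratios, per-feature shift
  scores and repeated-period performance monitoring.
* **Cadence comparison** (`paired_wilcoxon()`, `build_comparison_table()`):
  paired Wilcoxon signed-rank tests of every cadence against weekly on the
  per-pseudo-week metric series, Bonferroni-corrected (α = 0.05/9), with
  matched-pairs rank-biserial effect sizes labelled at |r| = 0.2/0.5/0.8.
* **Orchestration** (`experiment_config()`, `run_experiment()`,
  `render_report()`): one call runs generator → simulation → metrics → drift
  → comparison and writes a reproducible artifact bundle (CSV tables, JSON
  reports, retrain log, manifest).

## Worked example

The packaged experiment (also available as the numbered scripts under
`analysis/`) runs the default drifting scenario — three simulated years at
~150 presentations/day, changepoint on 1 January 2022 — across five cadences:

```r
library(edcadence)
config <- experiment_config(
  scenario = desk_scenario(),
  ensemble = ensemble_spec(),
  cadences = c("weekly", "fortnightly", "monthly", "annual", "static"),
  output_dir = "results/experiment", seed = 1)
bundle <- run_experiment(config)
```

Retrain accounting and mean AMDBE before/after the changepoint, as printed
by `analysis/02_cadence_experiment.R`:

```
      cadence retrain_count
1      weekly            97
2 fortnightly            49
3     monthly            25
4      annual             3
5      static             0

  weekly       pre 3.55   post 4.09
  fortnightly  pre 3.61   post 4.11
  monthly      pre 3.65   post 4.25
  annual       pre 3.66   post 5.19
  static       pre 3.66   post 7.08
```

Before the changepoint every cadence sits at the irreducible daily-count
noise floor (~3.6 beds/day at this volume); after it, the static model's
forecasts are ~3 beds/day worse than weekly's, annual sits in between, and
weekly-to-monthly are indistinguishable. The paired comparison
(`analysis/04_cadence_comparison.R`) makes that inferential:

```
Cadence      Metric Mean (SD)        Median (IQR)     p vs weekly  Effect   Label
weekly       amdbe  3.936 (1.294)    3.819 (1.807)    N/A          N/A      N/A
fortnightly  amdbe  3.964 (1.328)    3.790 (1.948)    0.770        -0.049   Negligible
monthly      amdbe  4.066 (1.487)    3.846 (1.910)    0.608        -0.070   Negligible
annual       amdbe  4.779 (1.754)    4.572 (2.081)    0.000        -0.537   Medium
static       amdbe  6.174 (2.192)    6.202 (2.894)    0.000        -0.889   Large
```

AUROC stays at ~0.80 for every cadence — discrimination barely notices the
drift that doubles the static model's bed error, which is why calibration
metrics, not AUROC, should drive retraining policy. The drift diagnostics
(`analysis/03_drift_diagnostics.R`) confirm the mechanism: a domain
classifier scores 0.498 between two windows of a zero-drift control but
0.922 across the changepoint, with the embedding block carrying the largest
per-feature shifts.

## Layout

```
R/                  package code (generator, features, ensemble, simulator,
                    metrics, drift, comparison, orchestration)
analysis/           numbered narrative drivers: 01 stream, 02 experiment,
                    03 drift, 04 comparison (write under results/)
scripts/            acceptance.R
tests/testthat/     unit, property and acceptance tests with independent
                    oracles (pair-counting AUROC, sign-enumeration Wilcoxon,
                    eigendecomposition reconstruction)
vignettes/          methods vignette: model, assumptions, defaults, limits
```
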