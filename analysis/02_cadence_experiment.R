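#!/usr/bin/env Rscript
# Step 2 — rolling prospective simulation across retraining cadences.
#
# Runs the full experiment on the default drifting scenario: initial fit on
# the first simulated year, then two test years scored day-by-day while the
# stacking ensemble is retrained on each cadence's pseudo-week schedule
# (expanding window, last 28 days held out for the meta-learner). Fortnightly
# and annual share retrain dates with weekly, so five cadences cost the same
# 97 fits as weekly alone. Artifacts land in results/experiment/.

suppressPackageStartupMessages(library(edcadence))

config <- experiment_config(
  scenario = desk_scenario(),
  ensemble = ensemble_spec(),
  cadences = c("weekly", "fortnightly", "monthly", "annual", "static"),
  output_dir = "results/experiment",
  seed = 1L
)

bundle <- run_experiment(config)

cat("\nCompute ledger (scheduled retrains per cadence):\n")
print(bundle$simulation$ledger)

cp <- as.Date("2022-01-01")
cat("\nMean AMDBE (beds/day) before and after the 1 Jan 2022 changepoint:\n")
for (cad in config$cadences) {
  fc <- bundle$simulation$cadences[[cad]]$forecasts
  cat(sprintf("  %-12s pre %.2f   post %.2f\n", cad,
              amdbe(fc[fc$date < cp, ]), amdbe(fc[fc$date >= cp, ])))
}
cat("\nExpected: static degrades after the changepoint while weekly-to-monthly",
    "\ncadences stay near the irreducible daily-count noise floor.\n")
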