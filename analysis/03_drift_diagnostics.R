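#!/usr/bin/env Rscript
# Step 3 — covariate-drift diagnostics.
#
# Contrasts the drifting scenario with its zero-drift control: a domain
# classifier should be unable to distinguish two windows of the control
# (AUROC ~ 0.5) but should separate pre/post-changepoint windows of the
# drifting stream almost perfectly; the PCA reconstruction-error ratio and
# repeated-period monitoring corroborate. Outputs in results/drift/.

suppressPackageStartupMessages(library(edcadence))

seed <- 1L
out <- "results/drift"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
sub <- function(idx, n = 4000) idx[round(seq(1, length(idx), length.out = n))]

# Null control: no drift anywhere; compare two adjacent six-month windows
# after the first-year history burn-in.
s0 <- generate_stream(desk_scenario(seed = seed, drift_magnitude = 0))
d0 <- as.Date(s0$arrival_datetime, tz = "UTC")
x0 <- build_features(s0)
w1 <- sub(which(d0 >= as.Date("2021-07-01") & d0 < as.Date("2022-01-01")))
w2 <- sub(which(d0 >= as.Date("2022-01-01") & d0 < as.Date("2022-07-01")))
null_report <- drift_report(x0[w1, ], x0[w2, ], seed = seed)
write_drift_report(null_report, file.path(out, "drift_null.json"))
cat("Zero-drift control:\n"); print(null_report)

# Drifting scenario: reference = first simulated year, comparison = final year.
s1 <- generate_stream(desk_scenario(seed = seed))
d1 <- as.Date(s1$arrival_datetime, tz = "UTC")
x1 <- build_features(s1)
ref <- sub(which(d1 < as.Date("2021-07-01")))
cmp <- sub(which(d1 >= as.Date("2022-07-01")))
drift <- drift_report(x1[ref, ], x1[cmp, ], seed = seed)
write_drift_report(drift, file.path(out, "drift_post_changepoint.json"))
cat("\nDrifting scenario (reference year vs final year):\n"); print(drift)

# Repeated-period monitoring of the static model from step 2, if available.
wm_path <- "results/experiment/weekly_metrics.csv"
if (file.exists(wm_path)) {
  wm <- read.csv(wm_path)
  st <- wm[wm$cadence == "static", ]
  st$week_start <- as.Date(st$week_start)
  mon <- performance_monitor(st)
  write.csv(mon, file.path(out, "performance_monitor_static.csv"),
            row.names = FALSE)
  cat("\nStatic model by calendar year (deltas vs first test year):\n")
  print(mon, digits = 3)
  cat("\nCalibration (AMDBE) degrades far more than discrimination (AUROC)\n",
      "after the changepoint - the signature of concept drift.\n", sep = "")
} else {
  cat("\n(run analysis/02_cadence_experiment.R first for the monitoring table)\n")
}
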