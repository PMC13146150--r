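#!/usr/bin/env Rscript
# Step 1 — simulate the presentation stream.
#
# Draws the default desk-scale drifting scenario: three simulated years at
# ~150 presentations/day starting 1 July 2020, ~20% admission prevalence with
# a steep triage gradient, negative-binomial daily volumes peaking in August,
# and a combined covariate+concept changepoint on 1 January 2022. Writes the
# stream and a quarterly dispersion table under results/stream/.

suppressPackageStartupMessages(library(edcadence))

seed <- 1L
out <- "results/stream"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

scenario <- desk_scenario(seed = seed)
print(scenario)

stream <- generate_stream(scenario)
stream <- inject_missingness(stream, list(postcode_class = 0.0075), seed = seed)
write_stream(stream, file.path(out, "stream.csv"))

dates <- as.Date(stream$arrival_datetime, tz = "UTC")
daily <- table(dates)
quarter <- paste(format(as.Date(names(daily)), "%Y"),
                 paste0("Q", (as.integer(format(as.Date(names(daily)), "%m")) - 1) %/% 3 + 1))
disp <- dispersion_summary(as.numeric(daily), quarter)
write.csv(disp, file.path(out, "dispersion.csv"), row.names = FALSE)

pre <- dates < as.Date("2022-01-01")
cat(sprintf("\n%d presentations over %d days; admission prevalence %.3f\n",
            nrow(stream), length(daily), mean(stream$admitted)))
cat(sprintf("prevalence pre-changepoint %.3f, post-changepoint %.3f\n",
            mean(stream$admitted[pre]), mean(stream$admitted[!pre])))
cat(sprintf("quarterly index of dispersion: %.2f to %.2f (overdispersed, > 1)\n",
            min(disp$index_of_dispersion, na.rm = TRUE),
            max(disp$index_of_dispersion, na.rm = TRUE)))
mo <- format(as.Date(names(daily)), "%m")
mm <- tapply(as.numeric(daily), mo, mean)
cat(sprintf("seasonality: August mean %.0f/day vs January %.0f/day\n",
            mm[["08"]], mm[["01"]]))
cat(sprintf("missing postcode: %d records (rate %.4f)\n",
            sum(is.na(stream$postcode_class)), mean(is.na(stream$postcode_class))))
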