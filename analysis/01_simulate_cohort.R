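#!/usr/bin/env Rscript

# Step 1 — simulate a synthetic study cohort.
#
# Generates a small demonstration cohort with the default study protocol
# and writes it to the plain-text session store with a manifest so later
# steps (or external tools) can reload it. The store keeps raw 2000 Hz
# radar I/Q as text, so this demonstration uses the two shorter scenarios
# (Resting, Apnea); the model-fitting steps below generate their cohorts
# in memory instead and include all five scenarios.

library(hemoradar)

seed <- 20260930
out_dir <- "results/cohort"
n_subjects <- 2
scenarios <- c("Resting", "Apnea")

message("simulating ", n_subjects, " subjects x {",
        paste(scenarios, collapse = ", "), "} ...")
cohort <- generate_cohort(n_subjects, scenarios = scenarios,
                          config = session_config(), rng_seed = seed)
manifest <- write_cohort(cohort, out_dir)

durations <- vapply(cohort, function(s) s$script$total_duration, 1)
message(sprintf("wrote %d sessions (%.1f min of signal) to %s",
                nrow(manifest), sum(durations) / 60, out_dir))
print(manifest)
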