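#!/usr/bin/env Rscript

# Step 4 — the full modality x data-type experiment grid.
#
# Runs the 3 x 3 grid (contact / radar / fusion x temporal / frequency /
# both) on the scaled-down cohort with the published per-modality
# hyperparameters at a reduced epoch budget (20), and writes the grid of
# mean CV accuracies with row/column means. This is the expensive summary
# experiment; expect a long run on one CPU.

library(hemoradar)

seed <- 20260930
ds <- build_cohort_dataset(10, rng_seed = seed, verbose = TRUE)

grid <- run_full_grid(ds, hp_source = "published", n_epochs = 20L,
                      rng_seed = seed, verbose = TRUE)
print(round(grid, 3))
dir.create("results", showWarnings = FALSE)
write.csv(round(grid, 4), "results/experiment_grid.csv")
message("wrote results/experiment_grid.csv")
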