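#!/usr/bin/env Rscript

# Step 5 — random hyperparameter search (demonstration scale).
#
# Draws a handful of hyperparameter sets from the search grid and evaluates
# each with the 5-fold CV experiment on the radar/FFT task at a reduced
# epoch budget, then reports the ranking and the spread of the top sets.
# The full study-scale search (hundreds of draws at 100 epochs) uses the
# same call with larger n_draws / n_epochs.

library(hemoradar)

seed <- 20260930
ds <- build_cohort_dataset(6, rng_seed = seed, verbose = TRUE)

harness <- function(hp) {
  run_experiment(ds, "radar", "frequency", hp, rng_seed = seed)$mean_accuracy
}
ranked <- random_search(n_draws = 4, harness, rng_seed = seed,
                        n_epochs = 15L)
print(ranked[, c("rank", "accuracy")])
message(sprintf("top-3 accuracy spread: %.3f", attr(ranked, "top3_spread")))

dir.create("results", showWarnings = FALSE)
hp_df <- do.call(rbind, lapply(ranked$hp, function(h) {
  as.data.frame(h[c("n_hidden_layers", "n_units", "activation", "dropout",
                    "learning_rate", "optimizer", "regularizer",
                    "regularization", "batch_size")])
}))
write.csv(cbind(rank = ranked$rank, accuracy = ranked$accuracy, hp_df),
          "results/random_search.csv", row.names = FALSE)
message("wrote results/random_search.csv")
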