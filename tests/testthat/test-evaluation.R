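# Stacking, folds, internal split, metrics, and the CV experiment driver.

test_that("subject stacking keeps blocks contiguous and ordered", {
  dA <- make_toy_dataset(n_per_class = 2, n_subjects = 1, seed = 1)
  dA$meta$subject_id <- "A"
  dB <- make_toy_dataset(n_per_class = 1, n_subjects = 1, seed = 2)
  dB$meta$subject_id <- "B"
  st <- stack_subjects(list(dA, dB))
  expect_equal(nrow(st$meta), 15)
  expect_equal(st$meta$subject_id, rep(c("A", "B"), c(10, 5)))
  # within-subject start times non-decreasing within each scenario block
  expect_identical(st$meta$start_time[1:10], dA$meta$start_time)
  st2 <- stack_subjects(list(dA, dB))
  expect_identical(st, st2)
  expect_error(stack_subjects(list(dA, dA)), "duplicate")
})

test_that("contiguous folds partition the data with few border subjects", {
  folds <- make_folds(100, k = 5, mode = "contiguous")
  expect_length(folds, 5)
  tests <- lapply(folds, `[[`, "test")
  expect_true(all(lengths(tests) == 20))
  expect_equal(sort(unlist(tests)), 1:100)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(union(f$train, f$test), 1:100)
  }
  # subjects sitting on a block border: at most 2 per fold
  subj <- rep(sprintf("s%02d", 1:10), each = 10)
  for (f in folds) {
    expect_lte(fold_border_subjects(f, subj), 2)
  }
  expect_error(make_folds(3, k = 5), "fewer instances")
  expect_error(make_folds(100, k = 1), "k must be")
})

test_that("subject-grouped folds keep whole subjects together", {
  subj <- rep(sprintf("s%02d", 1:10), each = 7)
  folds <- make_folds(70, k = 5, mode = "subject_grouped",
                      subject_ids = subj)
  expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), 1:70)
  for (f in folds) {
    expect_equal(fold_border_subjects(f, subj), 0)
  }
})

test_that("internal split is stratified, sized, and seeded", {
  labels <- rep(1:5, each = 20)
  spl <- internal_split(1:100, labels, ratio = 0.8, rng_seed = 4)
  expect_length(spl$train, 80)
  expect_length(spl$validation, 20)
  expect_setequal(c(spl$train, spl$validation), 1:100)
  # class proportions preserved within one instance per class
  for (cls in 1:5) {
    expect_equal(sum(labels[spl$validation] == cls), 4, tolerance = 1)
  }
  spl2 <- internal_split(1:100, labels, ratio = 0.8, rng_seed = 4)
  expect_identical(spl, spl2)
  expect_error(internal_split(1:3, labels[1:3]), "too few")
})

test_that("categorical accuracy matches the argmax rule", {
  y <- onehot_encode(rep(1:5, each = 4))
  expect_equal(categorical_accuracy(y, y), 1.0)
  # constant majority-vote prediction on balanced 5-class labels: 20%
  const <- matrix(rep(c(1, 0, 0, 0, 0), each = 20), 20)
  expect_equal(categorical_accuracy(y, const), 0.20)
  # uniform probabilities: first-index tie-break predicts class 1 always
  unif <- matrix(0.2, 20, 5)
  expect_equal(categorical_accuracy(y, unif), mean(max.col(y, "first") == 1))
  expect_error(categorical_accuracy(y[0, , drop = FALSE],
                                    unif[0, , drop = FALSE]), "empty")
})

test_that("confusion matrices are row-normalized with flagged empty rows", {
  truth <- rep(1:5, each = 6)
  cm <- normalized_confusion(truth, truth)
  expect_equal(unname(cm), diag(5), ignore_attr = TRUE)
  pred <- c(rep(1, 6), rep(3, 6), rep(3, 6), rep(4, 6), rep(4, 6))
  cm2 <- normalized_confusion(truth, pred)
  expect_equal(unname(rowSums(cm2)), rep(1, 5))
  # missing class support: zeros and a flag
  cm3 <- normalized_confusion(c(1, 2), c(1, 2))
  expect_equal(sum(cm3[3, ]), 0)
  expect_true("Apnea" %in% attr(cm3, "unsupported_classes"))
  # averaging fold matrices is the elementwise mean
  expect_equal((cm + cm2) / 2, Reduce(`+`, list(cm, cm2)) / 2)
})

test_that("the CV experiment is partition-sound and reproducible", {
  ds <- make_toy_dataset(n_per_class = 14, wlen = 40, seed = 5)
  hp <- hyperparams(n_units = 32L, dropout = 0.2, learning_rate = 0.01,
                    n_epochs = 8L)
  ex <- run_experiment(ds, "radar", "frequency", hp, rng_seed = 2)
  expect_length(ex$folds, 5)
  expect_equal(ex$mean_accuracy, mean(ex$fold_accuracies))
  expect_equal(dim(ex$mean_confusion), c(5, 5))
  # balanced by SMOTE before splitting: all classes at the majority count
  expect_equal(ex$config$n_instances, 70) # already balanced toy -> unchanged
  # learns the separable toy structure
  expect_gt(ex$mean_accuracy, 0.5)

  ex2 <- run_experiment(ds, "radar", "frequency", hp, rng_seed = 2)
  expect_equal(ex2$fold_accuracies, ex$fold_accuracies)
  expect_equal(ex2$mean_confusion, ex$mean_confusion)

  # per fold, accuracy equals the support-weighted confusion diagonal
  folds <- make_folds(70, k = 5, mode = "contiguous") # balanced toy: no
  for (f in seq_len(5)) {                             # synthetics appended
    support <- as.numeric(table(factor(ds$meta$label[folds[[f]]$test],
                                       levels = 1:5)))
    fr <- ex$folds[[f]]
    expect_equal(fr$accuracy,
                 sum(diag(fr$confusion) * support) / sum(support))
  }
})

test_that("fold modes change assignment, not instance count", {
  ds <- make_toy_dataset(n_per_class = 10, wlen = 40, seed = 6)
  hp <- hyperparams(n_epochs = 3L, dropout = 0.2)
  e1 <- run_experiment(ds, "contact", "frequency", hp,
                       fold_mode = "contiguous", rng_seed = 3)
  e2 <- run_experiment(ds, "contact", "frequency", hp,
                       fold_mode = "subject_grouped", rng_seed = 3)
  expect_equal(e1$config$n_instances, e2$config$n_instances)
  n1 <- sum(vapply(e1$folds, `[[`, 1, "n_test"))
  n2 <- sum(vapply(e2$folds, `[[`, 1, "n_test"))
  expect_equal(n1, n2)
})

test_that("no-leakage mode oversamples inside the training folds only", {
  ds <- make_toy_dataset(n_per_class = 10, wlen = 40, seed = 7)
  # unbalance: drop most of class 5
  keep <- which(ds$meta$label != 5 | seq_len(nrow(ds$meta)) %in%
                  which(ds$meta$label == 5)[1:4])
  ds$signals <- lapply(ds$signals, function(m) m[keep, , drop = FALSE])
  ds$meta <- ds$meta[keep, ]
  ds$onehot <- ds$onehot[keep, ]
  hp <- hyperparams(n_epochs = 3L, dropout = 0.2)
  ex <- run_experiment(ds, "contact", "frequency", hp, leakage = "fold",
                       smote_k = 3, rng_seed = 4)
  # test folds contain only original instances
  expect_equal(ex$config$n_instances, length(keep))
  expect_equal(sum(vapply(ex$folds, `[[`, 1, "n_test")), length(keep))
})

test_that("the full grid reports a 3x3 table with means", {
  ds <- make_toy_dataset(n_per_class = 8, wlen = 40, seed = 8)
  hp_tiny <- function(modality, data_type) {
    hyperparams(n_units = 32L, dropout = 0.2, n_epochs = 2L)
  }
  grid <- run_full_grid(ds, hp_source = hp_tiny, rng_seed = 5)
  expect_equal(dim(grid), c(4, 4))
  expect_equal(rownames(grid), c("contact", "radar", "fusion", "Mean"))
  expect_equal(colnames(grid), c("temporal", "frequency", "both", "Mean"))
  expect_equal(grid["Mean", "temporal"],
               mean(grid[1:3, "temporal"]))
  expect_equal(grid["contact", "Mean"], mean(as.numeric(grid[1, 1:3])))
  exps <- attr(grid, "experiments")
  expect_length(exps, 9)
  grid2 <- run_full_grid(ds, hp_source = hp_tiny, rng_seed = 5)
  expect_equal(as.matrix(grid), as.matrix(grid2))
})
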