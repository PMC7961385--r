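## Subject-blocked stacking, stratified 5-fold cross-validation with an
## internal 80/20 validation split, categorical accuracy, normalized
## confusion matrices, and the full per-modality experiment.

#' Stack per-subject datasets in fixed subject order
#'
#' Concatenates per-subject windowed datasets, keeping each subject's data
#' contiguous and in temporal order; no shuffling across subjects happens.
#'
#' @param datasets list of `hr_dataset`, one per subject, each with
#'   `meta$subject_id`
#' @return a single `hr_dataset`
#' @export
stack_subjects <- function(datasets) {
  ids <- vapply(datasets, function(d) d$meta$subject_id[1], "")
  if (anyDuplicated(ids)) {
    stop("duplicate subject ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  sig_names <- names(datasets[[1]]$signals)
  sigs <- lapply(sig_names, function(nm) {
    do.call(rbind, lapply(datasets, function(d) d$signals[[nm]]))
  })
  names(sigs) <- sig_names
  meta <- do.call(rbind, lapply(datasets, function(d) d$meta))
  rownames(meta) <- NULL
  onehot <- do.call(rbind, lapply(datasets, function(d) d$onehot))
  counts <- table(factor(meta$label, levels = 0:5))
  report <- instance_accounting(setNames(as.integer(counts),
                                         names(class_codes())),
                                window_s = datasets[[1]]$window_s)
  structure(list(signals = sigs, meta = meta, onehot = onehot,
                 fs = datasets[[1]]$fs, window_s = datasets[[1]]$window_s,
                 report = report),
            class = "hr_dataset")
}

#' Build k cross-validation fold partitions
#'
#' `contiguous` mode splits the stacked order into k near-equal consecutive
#' test blocks: this mirrors the study design, where only the 1-2 subjects
#' sitting on a fold border have windows in both train and test sets.
#' `subject_grouped` mode assigns whole subjects to folds (the stricter
#' leave-subjects-out alternative). Test sets are disjoint and cover all
#' instances. Per-fold class proportions are attached for reporting (achieved
#' stratification is measured, not enforced, since exact contiguity and exact
#' stratification conflict).
#'
#' @param n number of instances
#' @param k number of folds (default 5; must be >= 2 and <= n)
#' @param mode `"contiguous"` or `"subject_grouped"`
#' @param subject_ids required for `subject_grouped` mode
#' @param labels optional labels used for the per-fold proportion report
#' @return list of k elements, each `list(train, test)` index vectors, with
#'   attribute `class_proportions` when labels are given
#' @export
make_folds <- function(n, k = 5, mode = c("contiguous", "subject_grouped"),
                       subject_ids = NULL, labels = NULL) {
  mode <- match.arg(mode)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("fewer instances (", n, ") than folds (", k, ")")
  all_idx <- seq_len(n)
  if (mode == "contiguous") {
    bounds <- floor(n * (0:k) / k)
    folds <- lapply(seq_len(k), function(f) {
      test <- (bounds[f] + 1):bounds[f + 1]
      list(train = setdiff(all_idx, test), test = test)
    })
  } else {
    if (is.null(subject_ids)) stop("subject_grouped mode needs subject_ids")
    subj <- unique(subject_ids)
    if (length(subj) < k) {
      stop("subject_grouped mode needs at least k = ", k, " subjects, got ",
           length(subj))
    }
    sizes <- table(subject_ids)[subj]
    fold_of <- integer(length(subj))
    load <- numeric(k)
    for (i in order(sizes, decreasing = TRUE)) {
      f <- which.min(load)
      fold_of[i] <- f
      load[f] <- load[f] + sizes[i]
    }
    folds <- lapply(seq_len(k), function(f) {
      test <- all_idx[subject_ids %in% subj[fold_of == f]]
      list(train = setdiff(all_idx, test), test = test)
    })
  }
  if (!is.null(labels)) {
    prop <- t(vapply(folds, function(f) {
      as.numeric(prop.table(table(factor(labels[f$test],
                                         levels = sort(unique(labels))))))
    }, numeric(length(unique(labels)))))
    colnames(prop) <- sort(unique(labels))
    attr(folds, "class_proportions") <- prop
  }
  folds
}

#' Count subjects split across a fold's train/test border
#'
#' @param fold a `list(train, test)` element from [make_folds()]
#' @param subject_ids subject id per instance
#' @return number of subjects with instances on both sides
#' @export
fold_border_subjects <- function(fold, subject_ids) {
  length(intersect(unique(subject_ids[fold$train]),
                   unique(subject_ids[fold$test])))
}

#' Stratified internal train/validation split
#'
#' Seeded stratified random split of the training indices; class proportions
#' are preserved to within one instance per class. A class absent from
#' either side raises a warning.
#'
#' @param train_idx training index vector
#' @param labels labels aligned with the full dataset
#' @param ratio internal-training fraction (default 0.8)
#' @param rng_seed integer seed
#' @return list with `train` and `validation` index vectors
#' @export
internal_split <- function(train_idx, labels, ratio = 0.8, rng_seed = 1L) {
  if (length(train_idx) < 5) stop("too few instances for an internal split")
  lab <- labels[train_idx]
  val <- integer(0)
  with_seed(derive_seed(rng_seed, 9), {
    for (cls in unique(lab)) {
      members <- train_idx[lab == cls]
      n_val <- round(length(members) * (1 - ratio))
      if (n_val > 0) val <- c(val, sample(members, n_val))
    }
  })
  tr <- setdiff(train_idx, val)
  if (length(unique(labels[tr])) < length(unique(lab)) ||
      length(unique(labels[val])) < length(unique(lab))) {
    warning("a class is absent from the internal train or validation part")
  }
  list(train = tr, validation = val)
}

#' Categorical accuracy
#'
#' Fraction of instances whose predicted argmax matches the true argmax.
#' Ties are broken toward the lowest class index.
#'
#' @param y_true one-hot matrix
#' @param y_prob predicted probability matrix of the same shape
#' @return accuracy in [0, 1]
#' @export
categorical_accuracy <- function(y_true, y_prob) {
  stopifnot(is.matrix(y_true), all(dim(y_true) == dim(y_prob)))
  if (nrow(y_true) == 0) stop("empty input")
  mean(max.col(y_prob, ties.method = "first") ==
         max.col(y_true, ties.method = "first"))
}

#' Row-normalized confusion matrix
#'
#' Counts of (true class, predicted class) normalized per true-class row.
#' Rows without support are left as zeros and flagged in the
#' `"unsupported_classes"` attribute.
#'
#' @param true integer class indices (1..n_classes) or one-hot matrix
#' @param predicted integer class indices or probability matrix
#' @param n_classes number of classes (default 5)
#' @return n_classes x n_classes matrix, rows summing to 1 where supported
#' @export
normalized_confusion <- function(true, predicted, n_classes = 5) {
  if (is.matrix(true)) true <- max.col(true, ties.method = "first")
  if (is.matrix(predicted)) predicted <- max.col(predicted,
                                                 ties.method = "first")
  stopifnot(all(true %in% seq_len(n_classes)),
            all(predicted %in% seq_len(n_classes)))
  cm <- table(factor(true, levels = seq_len(n_classes)),
              factor(predicted, levels = seq_len(n_classes)))
  cm <- matrix(as.numeric(cm), n_classes, n_classes,
               dimnames = list(names(class_codes())[-1],
                               names(class_codes())[-1]))
  support <- rowSums(cm)
  out <- cm
  out[support > 0, ] <- cm[support > 0, ] / support[support > 0]
  attr(out, "unsupported_classes") <- rownames(cm)[support == 0]
  out
}

#' Run the full cross-validation experiment for one modality
#'
#' For each fold: balance the classes with SMOTE (before the fold split in
#' the default `leakage = "pre"` mode, which reproduces the balanced-data
#' design; inside the training fold only with `leakage = "fold"`), assemble
#' the branch inputs, build the branched network, train it for the full
#' epoch budget with an internal stratified 80/20 validation split, and
#' evaluate categorical accuracy and the row-normalized confusion matrix on
#' the withheld test fold. Fold results are averaged.
#'
#' @param dataset an `hr_dataset` (stacked, Other removed)
#' @param modality `"contact"`, `"radar"`, or `"fusion"`
#' @param data_type `"temporal"`, `"frequency"`, or `"both"`
#' @param hp an `hr_hyperparams`
#' @param k folds (default 5)
#' @param fold_mode `"contiguous"` or `"subject_grouped"`
#' @param leakage `"pre"` (SMOTE before splitting, default) or `"fold"`
#'   (SMOTE on each training fold only)
#' @param smote_k SMOTE neighbour count
#' @param rng_seed integer seed controlling SMOTE, splits, initialization,
#'   shuffling and dropout
#' @param permute_labels if `TRUE`, randomly permute the class labels of the
#'   balanced instance set (seeded) before fold construction — the negative
#'   control: any mean accuracy beyond sampling noise from the 0.20 chance
#'   level of the balanced 5-class problem indicates leakage in the harness.
#'   The permutation is applied after balancing: permuting before SMOTE
#'   would let the oversampler manufacture genuine label-correlated
#'   structure (synthetic instances are interpolations), which the control
#'   would wrongly flag
#' @param verbose print fold progress
#' @return object of class `hr_experiment`: list with `folds` (per-fold
#'   accuracy, confusion, history, border-subject count), `mean_accuracy`,
#'   `mean_confusion`, `config`
#' @export
run_experiment <- function(dataset, modality, data_type, hp, k = 5,
                           fold_mode = "contiguous", leakage = c("pre", "fold"),
                           smote_k = 5, rng_seed = 1L, permute_labels = FALSE,
                           verbose = FALSE) {
  leakage <- match.arg(leakage)
  sig_names <- modality_signals(modality)
  flat <- flatten_signals(dataset$signals[sig_names])
  labels <- dataset$meta$label
  subjects <- dataset$meta$subject_id
  wlen <- ncol(dataset$signals[[1]])

  if (leakage == "pre") {
    sm <- smote(flat, labels, k = smote_k, rng_seed = derive_seed(rng_seed, 3))
    flat <- sm$x
    labels <- sm$labels
    subjects <- c(subjects, rep("synthetic", sum(sm$synthetic)))
  }
  n <- nrow(flat)
  if (permute_labels) {
    labels <- with_seed(derive_seed(rng_seed, 555), labels[sample.int(n)])
  }
  folds <- make_folds(n, k = k, mode = fold_mode, subject_ids = subjects,
                      labels = labels)
  # branch inputs for the fixed instance matrix are assembled once (the FFT
  # half-spectra do not depend on the fold split); folds subset rows
  inputs_all <- assemble_inputs(unflatten_signals(flat, sig_names, wlen),
                                modality, data_type)
  fold_results <- vector("list", k)
  for (f in seq_len(k)) {
    fd <- folds[[f]]
    tr_idx <- fd$train; te_idx <- fd$test
    tr_inputs <- inputs_all; tr_labels <- labels
    if (leakage == "fold") {
      sm <- smote(flat[tr_idx, , drop = FALSE], labels[tr_idx], k = smote_k,
                  rng_seed = derive_seed(rng_seed, 3, f))
      syn <- assemble_inputs(
        unflatten_signals(sm$x[sm$synthetic, , drop = FALSE], sig_names,
                          wlen), modality, data_type)
      tr_inputs <- Map(rbind, inputs_all, syn)
      tr_labels <- c(labels, sm$labels[sm$synthetic])
      tr_idx <- c(tr_idx, n + seq_len(sum(sm$synthetic)))
    }
    spl <- internal_split(tr_idx, tr_labels, ratio = 0.8,
                          rng_seed = derive_seed(rng_seed, f))
    take <- function(src, idx) lapply(src, function(m) m[idx, , drop = FALSE])
    x_tr <- take(tr_inputs, spl$train)
    y_tr <- onehot_encode(tr_labels[spl$train])
    x_va <- take(tr_inputs, spl$validation)
    y_va <- onehot_encode(tr_labels[spl$validation])
    x_te <- take(inputs_all, te_idx)
    y_te <- onehot_encode(labels[te_idx])
    dims <- vapply(x_tr, ncol, 1L)
    model <- build_branched_ann(dims, hp, rng_seed = derive_seed(rng_seed, 13, f))
    fit <- train_model(model, x_tr, y_tr, x_va, y_va,
                       rng_seed = derive_seed(rng_seed, 17, f))
    probs <- predict(fit$model, x_te)
    acc <- categorical_accuracy(y_te, probs)
    fold_results[[f]] <- list(
      fold = f, accuracy = acc, history = fit$history,
      confusion = normalized_confusion(y_te, probs),
      border_subjects = fold_border_subjects(fd, subjects),
      n_test = length(te_idx))
    if (verbose) message(sprintf("fold %d/%d: accuracy %.3f", f, k, acc))
  }
  accs <- vapply(fold_results, `[[`, 1, "accuracy")
  mean_cm <- Reduce(`+`, lapply(fold_results, `[[`, "confusion")) / k
  structure(list(folds = fold_results, mean_accuracy = mean(accs),
                 fold_accuracies = accs, mean_confusion = mean_cm,
                 config = list(modality = modality, data_type = data_type,
                               hp = hp, k = k, fold_mode = fold_mode,
                               leakage = leakage, rng_seed = rng_seed,
                               n_instances = n)),
            class = "hr_experiment")
}

#' @export
print.hr_experiment <- function(x, ...) {
  cat(sprintf("<experiment %s/%s: mean CV accuracy %.3f over %d folds (%s)>\n",
              x$config$modality, x$config$data_type, x$mean_accuracy,
              x$config$k,
              paste(sprintf("%.3f", x$fold_accuracies), collapse = ", ")))
  invisible(x)
}

# n x (S*L) flattening, signal blocks in order
flatten_signals <- function(signals) {
  do.call(cbind, signals)
}
unflatten_signals <- function(flat, sig_names, wlen) {
  out <- list()
  for (s in seq_along(sig_names)) {
    out[[sig_names[s]]] <- flat[, ((s - 1) * wlen + 1):(s * wlen),
                                drop = FALSE]
  }
  out
}

#' Run the full modality-by-data-type experiment grid
#'
#' Runs [run_experiment()] for the 3 x 3 grid of input modalities (contact,
#' radar, fusion) and data types (temporal, frequency, both) and tabulates
#' the mean CV accuracies with row and column means.
#'
#' @param dataset an `hr_dataset`
#' @param hp_source `"published"` (the per-modality optimized sets) or a
#'   function(modality, data_type) returning an `hr_hyperparams`
#' @param n_epochs epoch budget applied to every cell
#' @param rng_seed integer seed
#' @param k folds
#' @param verbose print progress
#' @return data.frame: rows contact/radar/fusion (+ Mean row), columns
#'   temporal/frequency/both (+ Mean column); experiments attached as
#'   attribute `"experiments"`
#' @export
run_full_grid <- function(dataset, hp_source = "published", n_epochs = 100L,
                          rng_seed = 1L, k = 5, verbose = FALSE) {
  modalities <- c("contact", "radar", "fusion")
  types <- c("temporal", "frequency", "both")
  acc <- matrix(NA_real_, 3, 3, dimnames = list(modalities, types))
  exps <- list()
  for (m in modalities) {
    for (ty in types) {
      hp <- if (is.function(hp_source)) {
        hp_source(m, ty)
      } else {
        published_hyperparams(m, n_epochs = n_epochs)
      }
      ex <- run_experiment(dataset, m, ty, hp, k = k,
                           rng_seed = derive_seed(rng_seed, match(m, modalities),
                                                  match(ty, types)))
      acc[m, ty] <- ex$mean_accuracy
      exps[[paste(m, ty, sep = "_")]] <- ex
      if (verbose) message(sprintf("%s / %s: %.3f", m, ty, ex$mean_accuracy))
    }
  }
  out <- as.data.frame(cbind(acc, Mean = rowMeans(acc)))
  out <- rbind(out, Mean = c(colMeans(acc), NA))
  attr(out, "experiments") <- exps
  out
}
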