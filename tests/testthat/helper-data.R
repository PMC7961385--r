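# Shared fixtures, built in code at test time.

# Small fabricated windowed dataset with class-separable structure: each of
# the 12 canonical signals carries a class-dependent tone plus noise so that
# classification well above chance is achievable by construction. Rows are
# subject-major with classes interleaved within each subject, mimicking the
# stacked ordering of a real cohort (so contiguous folds span all classes).
make_toy_dataset <- function(n_per_class = 12, wlen = 40, fs = 20,
                             n_subjects = 5, seed = 42) {
  set.seed(seed)
  n <- n_per_class * 5
  labels <- rep(1:5, length.out = n)
  subject_id <- sprintf("s%02d",
                        rep(seq_len(n_subjects),
                            each = ceiling(n / n_subjects))[seq_len(n)])
  tt <- (seq_len(wlen) - 1) / fs
  sig_names <- modality_signals("fusion")
  sigs <- list()
  for (s in seq_along(sig_names)) {
    m <- matrix(0, n, wlen)
    for (i in seq_len(n)) {
      f <- 1 + 0.8 * labels[i] + 0.05 * s         # class-dependent tone
      m[i, ] <- normalize01(sin(2 * pi * f * tt + 0.3 * s) +
                              0.1 * rnorm(wlen))
    }
    sigs[[sig_names[s]]] <- m
  }
  meta <- data.frame(
    start_time = as.numeric(stats::ave(labels, subject_id,
                                       FUN = seq_along)) * 10,
    label = labels,
    class = names(class_codes())[labels + 1],
    subject_id = subject_id,
    scenario = names(class_codes())[labels + 1])
  structure(list(signals = sigs, meta = meta, onehot = onehot_encode(labels),
                 fs = fs, window_s = wlen / fs,
                 report = instance_accounting(table(labels))),
            class = "hr_dataset")
}

# Short-session generator config so unit tests stay fast; the scenario
# grammar (3 maneuvers, 2 holds, one tilt) is unchanged.
short_config <- function(...) {
  session_config(script_overrides = list(resting_duration = 120,
                                         recovery_s = 40, tail_s = 40,
                                         lead_in = 33, gap_s = 30,
                                         hold_range = c(25, 30),
                                         continuation_s = 120),
                 ...)
}

# Amplitude of a single frequency component via complex projection.
tone_amplitude <- function(x, fs, f) {
  tt <- (seq_along(x) - 1) / fs
  2 * abs(mean(x * exp(-2i * pi * f * tt)))
}

# Memoised 10-subject cohort at the full default study conditions, shared by
# the cross-validation acceptance checks.
.cohort_cache <- new.env(parent = emptyenv())
acceptance_cohort <- function() {
  if (is.null(.cohort_cache$ds)) {
    .cohort_cache$ds <- build_cohort_dataset(10, rng_seed = 20260930)
  }
  .cohort_cache$ds
}
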