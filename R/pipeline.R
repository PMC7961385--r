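## End-to-end glue: raw session -> derived signals -> unified-rate windows
## -> marker-based labels; cohort -> stacked model-ready dataset.

#' Process one session into labeled windows
#'
#' Runs the full preparation chain on a raw session: derived-signal
#' computation (ellipse reconstruction, demodulation, distance, respiration,
#' heart sound, pulse), resampling to the unified rate, per-signal band-pass,
#' 20-s/50%-overlap windowing with per-window [0, 1] normalization, button
#' press detection and scenario-semantic labeling.
#'
#' @param session an `hr_session`
#' @param fs_target unified sampling rate (default 100 Hz)
#' @param window_s window length in seconds (default 20)
#' @param overlap window overlap fraction (default 0.5)
#' @param min_overlap labeling overlap threshold (default 0.5)
#' @param strict strict press-count checking (see [events_to_intervals()])
#' @param wavelength radar carrier wavelength (m)
#' @return labeled `hr_windows` with `meta` columns `start_time`, `label`,
#'   `class`, `subject_id`, `scenario`
#' @export
prepare_session_windows <- function(session, fs_target = 100, window_s = 20,
                                    overlap = 0.5, min_overlap = 0.5,
                                    strict = TRUE,
                                    wavelength = radar_wavelength()) {
  derived <- derive_all(session, wavelength = wavelength)
  prep <- preprocess_session(derived, fs_target = fs_target)
  windows <- segment_windows(prep$signals, prep$fs, window_s = window_s,
                             overlap = overlap)
  presses <- detect_presses(prep$marker)
  timeline <- events_to_intervals(presses, session$scenario,
                                  session_extent = nrow(prep$signals) / prep$fs,
                                  strict = strict)
  windows <- label_windows(windows, timeline, min_overlap = min_overlap)
  windows$meta$subject_id <- session$subject_id
  windows$meta$scenario <- session$scenario
  windows$timeline <- timeline
  windows
}

# ground-truth window labels (for generator validation): same overlap rule,
# but applied to the known script intervals instead of the marker channel
ground_truth_window_labels <- function(session, windows, min_overlap = 0.5) {
  gt <- session$ground_truth
  codes <- class_codes()
  iv <- data.frame(start = gt$start, end = gt$end,
                   code = as.integer(codes[gt$class]))
  iv <- iv[iv$code != 0L, , drop = FALSE]
  tl <- structure(list(intervals = iv), class = "hr_timeline")
  label_windows(windows, tl, min_overlap = min_overlap)$meta$label
}

#' Build a model-ready dataset from a synthetic cohort
#'
#' Generates each subject's sessions (physiology drawn once per subject),
#' runs [prepare_session_windows()] on each, concatenates a subject's
#' windows in session order, removes the Other class, one-hot encodes, and
#' stacks subjects in fixed order with [stack_subjects()]. Sessions are
#' processed one at a time so raw high-rate channels never accumulate.
#'
#' @param n_subjects number of subjects
#' @param scenarios scenarios per subject (default all five)
#' @param config an `hr_config`
#' @param rng_seed integer master seed
#' @param drop_other remove Other-class windows (default TRUE)
#' @param verbose print per-subject progress
#' @return a stacked `hr_dataset`
#' @export
build_cohort_dataset <- function(n_subjects = 30,
                                 scenarios = scenario_levels(),
                                 config = session_config(), rng_seed = 1L,
                                 drop_other = TRUE, verbose = FALSE) {
  per_subject <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%02d", s)
    cfg <- config
    cfg$physiology <- draw_subject_physiology(derive_seed(rng_seed, s, 101))
    win_list <- list()
    for (sc in scenarios) {
      sess <- generate_session(sid, sc, cfg,
                               rng_seed = derive_seed(rng_seed, s,
                                                      match(sc, scenario_levels())))
      win_list[[sc]] <- prepare_session_windows(sess)
    }
    merged <- merge_windows(win_list)
    per_subject[[s]] <- finalize_dataset(merged, drop_other = drop_other)
    if (verbose) {
      message(sprintf("subject %s: %d labeled windows", sid,
                      nrow(per_subject[[s]]$meta)))
    }
  }
  stack_subjects(per_subject)
}

# concatenate hr_windows objects (same signals/fs/window_s)
merge_windows <- function(win_list) {
  w1 <- win_list[[1]]
  sigs <- lapply(names(w1$signals), function(nm) {
    do.call(rbind, lapply(win_list, function(w) w$signals[[nm]]))
  })
  names(sigs) <- names(w1$signals)
  meta <- do.call(rbind, lapply(win_list, function(w) w$meta))
  rownames(meta) <- NULL
  structure(list(signals = sigs, meta = meta, fs = w1$fs,
                 window_s = w1$window_s),
            class = "hr_windows")
}
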