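## Button-press detection, scenario-semantic interval construction, window
## labeling, and the final one-hot dataset with "Other" removed.

#' Detect button presses in the marker channel
#'
#' The marker baseline is estimated by the median; presses are contiguous
#' runs where the signal falls below `drop_fraction * baseline` and that last
#' at least `debounce_s`. Runs shorter than `hold_threshold_s` are classified
#' as `pulse` (a quick press), longer runs as `hold` (press-and-hold, used to
#' span apnea breath-holds).
#'
#' @param marker an `hr_channel`
#' @param drop_fraction threshold as a fraction of baseline (default 0.5)
#' @param debounce_s minimum press duration in seconds (default 0.2)
#' @param hold_threshold_s pulse/hold boundary in seconds (default 2)
#' @param min_baseline minimum admissible baseline level in marker units
#'   (default 0.5, half the conventional baseline-high level of 1); an
#'   all-low signal — e.g. a stuck button — has no estimable baseline
#' @return data.frame with columns `start`, `end` (seconds), `kind`
#' @export
detect_presses <- function(marker, drop_fraction = 0.5, debounce_s = 0.2,
                           hold_threshold_s = 2, min_baseline = 0.5) {
  x <- marker$samples
  fs <- marker$fs
  baseline <- median(x)
  if (baseline < min_baseline || mean(x < drop_fraction * max(x)) > 0.5) {
    stop("marker baseline not estimable: signal is low for most of the session")
  }
  low <- x < drop_fraction * baseline
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= debounce_s * fs
  if (!any(keep)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      kind = character(0)))
  }
  s <- (starts[keep] - 1) / fs
  e <- ends[keep] / fs
  data.frame(start = s, end = e,
             kind = ifelse(e - s < hold_threshold_s, "pulse", "hold"))
}

#' Convert presses into scenario-labeled intervals
#'
#' Scenario semantics of the button presses: Resting sessions have none and
#' the whole extent is Resting; in Valsalva sessions consecutive pulse pairs
#' bound the maneuver intervals (remainder Other); in apnea sessions the
#' button is held for the whole breath-hold, so hold events directly bound
#' the Apnea intervals; in tilt sessions a pulse marks the start of the tilt
#' motion and everything from it to the end of the session carries the tilt
#' class (the continuation is the orthostatic response window), the lead-in
#' before it is Other.
#'
#' @param presses data.frame from [detect_presses()]
#' @param scenario one of `scenario_levels()`
#' @param session_extent session duration in seconds
#' @param strict if `TRUE`, inconsistent press counts (odd pulse count for
#'   Valsalva, no presses for apnea/tilt) are an error; if `FALSE`, the
#'   dominant pairing is inferred (trailing unpaired pulse dropped)
#' @return object of class `hr_timeline`: list with `presses` and `intervals`
#'   (data.frame `start`, `end`, `class`, `code`)
#' @export
events_to_intervals <- function(presses, scenario, session_extent,
                                strict = TRUE) {
  stopifnot(scenario %in% scenario_levels())
  iv <- data.frame(start = numeric(0), end = numeric(0), class = character(0))
  if (scenario == "Resting") {
    iv <- data.frame(start = 0, end = session_extent, class = "Resting")
  } else if (scenario == "Valsalva") {
    p <- presses[presses$kind == "pulse", ]
    if (nrow(p) == 0) stop("flagged session: no pulses in a Valsalva recording")
    if (nrow(p) %% 2 == 1) {
      if (strict) {
        stop("flagged session: odd pulse count (", nrow(p),
             ") in a Valsalva recording")
      }
      p <- p[-nrow(p), ]
    }
    k <- seq(1, nrow(p), by = 2)
    iv <- data.frame(start = p$start[k], end = p$start[k + 1],
                     class = "Valsalva")
  } else if (scenario == "Apnea") {
    h <- presses[presses$kind == "hold", ]
    if (nrow(h) == 0) stop("flagged session: no hold presses in an apnea recording")
    iv <- data.frame(start = h$start, end = h$end, class = "Apnea")
  } else { # tilt
    if (nrow(presses) == 0) {
      stop("flagged session: no presses in a tilt recording")
    }
    iv <- data.frame(start = min(presses$start), end = session_extent,
                     class = scenario)
  }
  iv <- iv[order(iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  iv$code <- unname(class_codes()[iv$class])
  structure(list(presses = presses, intervals = iv,
                 session_extent = session_extent, scenario = scenario),
            class = "hr_timeline")
}

#' Assign a class label to each window
#'
#' A window receives a non-Other class c if and only if strictly more than
#' `min_overlap` of its duration lies inside intervals of class c; otherwise
#' it is labeled Other (code 0).
#'
#' @param windows an `hr_windows` from [segment_windows()]
#' @param timeline an `hr_timeline` from [events_to_intervals()]
#' @param min_overlap minimum overlap fraction (default 0.5, strict)
#' @return `windows` with `meta$label` (integer code) and `meta$class` added
#' @export
label_windows <- function(windows, timeline, min_overlap = 0.5) {
  w <- windows$window_s
  iv <- timeline$intervals
  labs <- integer(nrow(windows$meta))
  for (k in seq_len(nrow(windows$meta))) {
    a <- windows$meta$start_time[k]; b <- a + w
    ov <- numeric(6) # overlap time per class code 0..5
    for (i in seq_len(nrow(iv))) {
      o <- max(0, min(b, iv$end[i]) - max(a, iv$start[i]))
      ov[iv$code[i] + 1] <- ov[iv$code[i] + 1] + o
    }
    best <- which.max(ov[-1]) # candidate non-Other class
    labs[k] <- if (ov[best + 1] > min_overlap * w) best else 0L
  }
  windows$meta$label <- labs
  codes <- class_codes()
  windows$meta$class <- names(codes)[match(labs, codes)]
  windows
}

#' Finalize a windowed dataset for modelling
#'
#' Optionally removes the ambiguous "Other" class (as done for evaluation),
#' one-hot encodes the remaining five classes, and attaches a per-class
#' accounting report (instance count, duration as count x window length,
#' fraction of all instances).
#'
#' @param windows a labeled `hr_windows` (see [label_windows()]); `meta` must
#'   contain `label`
#' @param drop_other remove class 0 instances (default `TRUE`)
#' @return object of class `hr_dataset`: list with `signals` (named list of
#'   n x L matrices), `meta`, `onehot` (n x 5 matrix, columns Resting..TiltDown),
#'   `fs`, `window_s`, and `report` (data.frame)
#' @export
finalize_dataset <- function(windows, drop_other = TRUE) {
  stopifnot(!is.null(windows$meta$label))
  keep <- if (drop_other) windows$meta$label != 0L else rep(TRUE, nrow(windows$meta))
  if (!any(keep)) stop("no instances left after removing the Other class")
  sigs <- lapply(windows$signals, function(m) m[keep, , drop = FALSE])
  meta <- windows$meta[keep, , drop = FALSE]
  rownames(meta) <- NULL
  onehot <- onehot_encode(meta$label)
  counts <- table(factor(meta$label, levels = 0:5))
  rep_classes <- names(class_codes())
  report <- instance_accounting(setNames(as.integer(counts), rep_classes),
                                window_s = windows$window_s)
  structure(list(signals = sigs, meta = meta, onehot = onehot,
                 fs = windows$fs, window_s = windows$window_s,
                 report = report),
            class = "hr_dataset")
}

#' One-hot encode class codes 1..5
#'
#' @param labels integer codes in 1..5 (Resting..TiltDown)
#' @return n x 5 matrix with a single 1 per row; column j corresponds to
#'   class code j
#' @export
onehot_encode <- function(labels) {
  stopifnot(all(labels %in% 1:5))
  m <- matrix(0, length(labels), 5,
              dimnames = list(NULL, names(class_codes())[-1]))
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

#' Per-class accounting from instance counts
#'
#' Recomputes, from window instance counts, the total signal duration each
#' class represents (`count * window_s`, in hours) and its fraction of all
#' instances (percent). With 20-s windows at 50% overlap the duration column
#' is the windowed-duration accounting used in the study's instance table.
#'
#' @param counts named integer vector of instance counts (names are classes)
#' @param window_s window length in seconds
#' @return data.frame with `class`, `count`, `duration_h`, `fraction_pct`
#' @export
instance_accounting <- function(counts, window_s = 20) {
  total <- sum(counts)
  data.frame(class = names(counts),
             count = as.integer(counts),
             duration_h = as.numeric(counts) * window_s / 3600,
             fraction_pct = 100 * as.numeric(counts) / total,
             row.names = NULL)
}

#' Published instance distribution of the clinical radar dataset
#'
#' Windowed-instance counts per class as published for the clinical
#' recordings (20-s windows, 50% overlap), used for accounting
#' cross-checks: durations and fractions are recomputed from these counts
#' with [instance_accounting()].
#'
#' @return named integer vector of instance counts
#' @export
reference_instance_counts <- function() {
  c(Other = 3021L, Resting = 1860L, Valsalva = 173L, Apnea = 184L,
    TiltUp = 1575L, TiltDown = 1630L)
}

#' Published per-scenario recording distribution of the clinical radar dataset
#'
#' Session-level metadata of the clinical recordings: number of subjects and
#' total recorded hours per scenario. The fraction column is recomputed from
#' the durations.
#'
#' @return data.frame with `scenario`, `subject_count`, `duration_h`,
#'   `fraction_pct`
#' @export
reference_scenario_distribution <- function() {
  d <- data.frame(scenario = scenario_levels(),
                  subject_count = c(30L, 27L, 24L, 27L, 27L),
                  duration_h = c(5.3, 7.8, 1.3, 4.8, 4.8))
  d$fraction_pct <- 100 * d$duration_h / sum(d$duration_h)
  d
}
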