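## Unify sampling rates, band-limit, normalize, window.

#' Resample a channel to a lower unified rate
#'
#' Anti-aliased, delay-compensated rate conversion. Integer decimation
#' factors (the common case: 2000/1000/500/100 Hz down to 100 Hz) use a
#' zero-phase FIR anti-aliasing low-pass (cutoff at 80% of the target
#' Nyquist) followed by subsampling, so no group delay is introduced at all;
#' non-integer ratios fall back to polyphase resampling.
#'
#' @param ch an `hr_channel`
#' @param fs_target target sampling rate in Hz (0 < fs_target <= ch$fs)
#' @return resampled `hr_channel`
#' @export
resample_channel <- function(ch, fs_target = 100) {
  if (fs_target <= 0) stop("fs_target must be positive")
  stopifnot(fs_target <= ch$fs)
  if (fs_target == ch$fs) return(ch)
  ratio <- ch$fs / fs_target
  if (abs(ratio - round(ratio)) < 1e-9) {
    y <- antialias_decimate(ch$samples, round(ratio))
  } else {
    y <- signal::resample(ch$samples, fs_target, ch$fs)
  }
  channel(ch$name, y, fs_target)
}

# Zero-phase FIR anti-aliased decimation by an integer factor q:
# Hamming-windowed linear-phase FIR (10q+1 taps, cutoff 80% of the target
# Nyquist), evaluated polyphase-style only at the retained sample positions
# with exact group-delay removal (the symmetric FIR has integer delay 5q).
antialias_decimate <- function(x, q) {
  if (q == 1) return(x)
  h <- as.numeric(signal::fir1(10 * q, 0.8 / q))
  nh <- length(h)
  d <- (nh - 1L) / 2L
  n <- length(x)
  xp <- c(numeric(d), x, numeric(d))
  idx <- as.integer(seq.int(1L, n, by = q) + 2L * d) # tap-1 positions
  y <- h[1] * xp[idx]
  for (j in 2:nh) {
    idx <- idx - 1L
    y <- y + h[j] * xp[idx]
  }
  y
}

#' Default band-pass specification per signal
#'
#' 4th-order Butterworth band-pass cutoffs: respiration-like signals
#' 0.1-1 Hz; everything else 0.1-20 Hz (the widest stated envelope, as used
#' for the ECG); the heart sound is exempt because it is already band-limited
#' to 16-40 Hz by its own derivation.
#'
#' @return data.frame with columns `signal`, `low_cut`, `high_cut`, `order`
#'   (`NA` cutoffs mean the signal is passed through unfiltered)
#' @export
default_filter_specs <- function() {
  sig <- modality_signals("fusion")
  low <- rep(0.1, length(sig))
  high <- rep(20, length(sig))
  resp <- sig %in% c("radar_respiration", "contact_respiration")
  high[resp] <- 1
  exempt <- sig == "heart_sound"
  low[exempt] <- NA_real_; high[exempt] <- NA_real_
  data.frame(signal = sig, low_cut = low, high_cut = high, order = 4L)
}

#' Band-pass filter a channel
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass.
#'
#' @param ch an `hr_channel`
#' @param low_cut,high_cut cutoff frequencies in Hz
#'   (0 < low_cut < high_cut < fs/2)
#' @param order filter design order (default 4)
#' @return filtered `hr_channel`
#' @export
bandpass <- function(ch, low_cut, high_cut, order = 4) {
  if (high_cut >= ch$fs / 2) {
    stop("high_cut ", high_cut, " Hz is at or above Nyquist for fs = ", ch$fs)
  }
  if (low_cut <= 0 || low_cut >= high_cut) stop("invalid band edges")
  channel(ch$name, butter_bandpass(ch$samples, ch$fs, low_cut, high_cut,
                                   order = order), ch$fs)
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)`; constant segments map to all zeros.
#'
#' @param x numeric vector with finite values
#' @return normalized vector
#' @export
normalize01 <- function(x) {
  if (!all(is.finite(x))) stop("non-finite values in segment")
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(numeric(length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Resample and band-limit all derived signals of a session
#'
#' Brings the 12 model-input signals and the marker to a unified sampling
#' rate and applies the per-signal Butterworth band-pass specification.
#'
#' @param derived an `hr_derived` from [derive_all()]
#' @param fs_target unified sampling rate in Hz (default 100)
#' @param specs filter specification table, see [default_filter_specs()]
#' @return list with `signals` (matrix T x 12, columns in
#'   `modality_signals("fusion")` order), `marker` (`hr_channel`), `fs`,
#'   `subject_id`, `scenario`, `ground_truth`
#' @export
preprocess_session <- function(derived, fs_target = 100,
                               specs = default_filter_specs()) {
  sig_names <- modality_signals("fusion")
  cols <- vector("list", length(sig_names))
  names(cols) <- sig_names
  for (nm in sig_names) {
    ch <- resample_channel(derived$channels[[nm]], fs_target)
    sp <- specs[specs$signal == nm, ]
    if (nrow(sp) == 1 && !is.na(sp$low_cut)) {
      ch <- bandpass(ch, sp$low_cut, sp$high_cut, sp$order)
    }
    cols[[nm]] <- ch$samples
  }
  n <- min(lengths(cols))
  m <- vapply(cols, function(v) v[seq_len(n)], numeric(n))
  marker <- resample_channel(derived$channels$marker, fs_target)
  list(signals = m, marker = marker, fs = fs_target,
       subject_id = derived$subject_id, scenario = derived$scenario,
       ground_truth = derived$ground_truth)
}

#' Segment session signals into overlapping windows
#'
#' Windows are anchored at t = 0 and advance by `window_s * (1 - overlap)`;
#' a trailing partial window is dropped. The number of windows for a session
#' of duration T is `floor((T - window_s) / hop) + 1` when T >= window_s,
#' else 0. Each window of each signal is min-max normalized to [0, 1]
#' (per window, per signal) when `normalize = TRUE`.
#'
#' @param signals numeric matrix (samples x signals) at a common rate
#' @param fs sampling rate in Hz
#' @param window_s window length in seconds (default 20)
#' @param overlap fractional overlap between consecutive windows (default 0.5)
#' @param normalize normalize each window of each signal to [0, 1]
#' @return object of class `hr_windows`: list with `signals` (named list of
#'   n_windows x window_len matrices), `meta` (data.frame `start_time`),
#'   `fs`, `window_s`
#' @export
segment_windows <- function(signals, fs, window_s = 20, overlap = 0.5,
                            normalize = TRUE) {
  stopifnot(is.matrix(signals), overlap >= 0, overlap < 1, window_s > 0)
  wlen <- round(window_s * fs)
  hop_s <- window_s * (1 - overlap)
  hop <- round(hop_s * fs)
  n_total <- nrow(signals)
  T <- n_total / fs
  n_win <- if (T >= window_s) floor((T - window_s) / hop_s + 1e-9) + 1 else 0
  starts <- (seq_len(n_win) - 1) * hop + 1
  out <- list()
  for (j in seq_len(ncol(signals))) {
    m <- matrix(0, n_win, wlen)
    for (w in seq_len(n_win)) {
      seg <- signals[starts[w]:(starts[w] + wlen - 1), j]
      m[w, ] <- if (normalize) normalize01(seg) else seg
    }
    out[[colnames(signals)[j] %||% paste0("sig", j)]] <- m
  }
  structure(list(signals = out,
                 meta = data.frame(start_time = (starts - 1) / fs),
                 fs = fs, window_s = window_s),
            class = "hr_windows")
}

#' Number of whole windows in a session
#'
#' Counting rule used by [segment_windows()]: windows anchored at 0,
#' hop `window_s * (1 - overlap)`, trailing partial windows dropped.
#'
#' @param duration_s session duration in seconds
#' @param window_s window length in seconds
#' @param overlap fractional overlap
#' @return integer window count
#' @export
count_windows <- function(duration_s, window_s = 20, overlap = 0.5) {
  hop <- window_s * (1 - overlap)
  if (duration_s < window_s) return(0L)
  as.integer(floor((duration_s - window_s) / hop + 1e-9) + 1)
}
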