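## Derived-signal chain: I/Q ellipse reconstruction, arctangent demodulation,
## phase-to-displacement conversion, and the cardiorespiratory signals
## (radar respiration, heart sound, pulse, contact respiration).

#' Ellipse reconstruction of the I/Q trajectory
#'
#' Compensates quadrature receiver non-idealities (DC offsets, amplitude
#' imbalance, phase skew) by fitting the (I, Q) point cloud to an ellipse
#' with a direct constrained algebraic least-squares fit (the numerically
#' stable Halir-Flusser formulation of the Fitzgibbon method), then mapping
#' the ellipse onto the centered unit circle: translate by the center, rotate
#' by the tilt, rescale the semi-axes. The tilt is canonicalized into
#' (-pi/4, pi/4] so that the compensated I axis stays aligned with the raw I
#' axis for realistic (mild) distortions.
#'
#' @param i,q numeric vectors (>= 6 samples, not colinear)
#' @return list with compensated `i`, `q`, the fitted `model`
#'   (`center`, `semi_axes`, `tilt`), and `radial_deviation`
#'   (mean absolute deviation of compensated radii from 1)
#' @export
ellipse_reconstruction <- function(i, q) {
  stopifnot(length(i) == length(q))
  if (length(i) < 6) stop("ellipse reconstruction needs >= 6 samples")
  x <- as.numeric(i); y <- as.numeric(q)
  if (sd(x) < 1e-12 && sd(y) < 1e-12) {
    stop("degenerate I/Q input: constant point, no ellipse is defined")
  }
  if (sd(x) < 1e-12 || sd(y) < 1e-12 ||
      abs(stats::cor(x, y)) > 1 - 1e-12) {
    stop("degenerate I/Q input: colinear samples, no ellipse is defined")
  }
  model <- fit_ellipse_direct(x, y)
  comp <- apply_ellipse_model(x, y, model)
  r <- sqrt(comp$i^2 + comp$q^2)
  list(i = comp$i, q = comp$q, model = model,
       radial_deviation = mean(abs(r - 1)))
}

# Halir & Flusser direct least squares ellipse fit.
# Returns center (cx, cy), semi_axes (a >= along canonical u-axis), tilt.
fit_ellipse_direct <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sc <- max(sd(x), sd(y))
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M2)
  V <- Re(eg$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  k <- which(cond > 0)
  if (length(k) == 0) stop("ellipse fit failed: no admissible eigenvector")
  a1 <- V[, k[1]]
  coef <- c(a1, as.vector(Tm %*% a1)) # A B C D E F in scaled frame
  conic_to_ellipse(coef, mx, my, sc)
}

conic_to_ellipse <- function(coef, mx, my, sc) {
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- 4 * A * C - B^2
  if (den <= 0) stop("fitted conic is not an ellipse")
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  # constant at center
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  # eigen-decomposition of the quadratic form
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  eq <- eigen(Q, symmetric = TRUE)
  lam <- eq$values # decreasing
  axes <- sqrt(-Fc / lam)          # semi-axes in scaled frame
  vecs <- eq$vectors
  # order: take the eigenvector of the first column as the u-axis
  tilt <- atan2(vecs[2, 1], vecs[1, 1])
  a <- axes[1]; b <- axes[2]
  # canonicalize tilt into (-pi/4, pi/4], swapping axes as needed
  while (tilt <= -pi / 4) { tilt <- tilt + pi / 2; tmp <- a; a <- b; b <- tmp }
  while (tilt > pi / 4)   { tilt <- tilt - pi / 2; tmp <- a; a <- b; b <- tmp }
  list(center = c(cx * sc + mx, cy * sc + my),
       semi_axes = c(a * sc, b * sc), tilt = tilt)
}

apply_ellipse_model <- function(x, y, model) {
  ct <- cos(model$tilt); st <- sin(model$tilt)
  u <- (x - model$center[1]) * ct + (y - model$center[2]) * st
  v <- -(x - model$center[1]) * st + (y - model$center[2]) * ct
  list(i = u / model$semi_axes[1], q = v / model$semi_axes[2])
}

#' Arctangent demodulation of compensated I/Q
#'
#' Per-sample four-quadrant arctangent phase followed by 2-pi unwrapping
#' (jump threshold pi). The phase is undefined near the origin, so any sample
#' with radius below `eps` is rejected.
#'
#' @param i,q compensated quadrature components
#' @param eps minimum admissible radius (default 1e-6)
#' @return unwrapped phase in radians
#' @export
arctangent_demodulation <- function(i, q, eps = 1e-6) {
  stopifnot(length(i) == length(q))
  r <- sqrt(i^2 + q^2)
  if (any(r < eps)) {
    stop("I/Q radius below ", eps,
         " at sample ", which(r < eps)[1], ": phase undefined near origin")
  }
  unwrap_phase(atan2(q, i))
}

# 2*pi unwrapping with jump threshold pi
unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  adj <- d - jumps * 2 * pi
  # only correct jumps exceeding pi
  corr <- ifelse(abs(d) > pi, adj, d)
  c(p[1], p[1] + cumsum(corr))
}

#' Convert radar phase to displacement
#'
#' Two-way path relation dx = dphi / (2*pi) * lambda / 2, applied elementwise
#' relative to the first sample.
#'
#' @param dphi unwrapped phase in radians
#' @param wavelength carrier wavelength in metres
#' @return displacement in metres, zero at the first sample
#' @export
phase_to_displacement <- function(dphi, wavelength = radar_wavelength()) {
  stopifnot(wavelength > 0)
  (dphi - dphi[1]) / (2 * pi) * wavelength / 2
}

## Band-limited derived signals ----------------------------------------------

# zero-phase 4th-order Butterworth band-pass
butter_bandpass <- function(x, fs, low, high, order = 4) {
  stopifnot(low > 0, high > low, high < fs / 2)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Extract a respiration signal
#'
#' Zero-phase 4th-order Butterworth band-pass, 0.1-1 Hz, applied to either
#' the radar distance trace (radar respiration) or the thoracic impedance
#' channel (contact respiration).
#'
#' At high input rates the 0.1 Hz lower edge sits so close to DC in
#' normalized frequency that a direct transfer-function filter is
#' numerically unstable, so the signal is internally decimated to ~100 Hz,
#' filtered there, and interpolated back to the input grid (exact for a
#' band limited to 1 Hz).
#'
#' @param x numeric input trace
#' @param fs sampling rate in Hz (> 2)
#' @return filtered respiration signal at the input rate
#' @export
extract_respiration <- function(x, fs) {
  if (fs <= 2) stop("fs too low for the 0.1-1 Hz respiration band")
  if (fs > 400) {
    q <- floor(fs / 100)
    xl <- antialias_decimate(x, q)
    y <- butter_bandpass(xl, fs / q, 0.1, 1)
    return(stats::approx(seq(1, length(x), by = q), y,
                         xout = seq_along(x), rule = 2)$y)
  }
  butter_bandpass(x, fs, 0.1, 1)
}

#' Extract the radar heart-sound signal
#'
#' Zero-phase 4th-order Butterworth band-pass in the 16-40 Hz auscultation
#' band, applied to the distance trace at its native rate (before
#' downsampling).
#'
#' @param x distance trace
#' @param fs sampling rate in Hz (>= 100, i.e. at least twice the 40 Hz
#'   upper cutoff with margin)
#' @return heart-sound band signal
#' @export
extract_heart_sound <- function(x, fs) {
  if (fs < 2 * 40) stop("fs below twice the 40 Hz heart-sound upper cutoff")
  butter_bandpass(x, fs, 16, 40)
}

#' Compute the pulse wave from the heart sound
#'
#' Magnitude envelope of the heart-sound signal: full-wave rectification
#' followed by a zero-phase 4th-order Butterworth 3 Hz low-pass. Envelope
#' peaks mark heart beats.
#'
#' @param hs heart-sound signal from [extract_heart_sound()]
#' @param fs sampling rate in Hz
#' @return pulse envelope
#' @export
heart_sound_to_pulse <- function(hs, fs) {
  bf <- signal::butter(4, 3 / (fs / 2), type = "low")
  signal::filtfilt(bf, abs(hs))
}

#' Derive all model-input signals from a raw session
#'
#' Chains ellipse reconstruction -> arctangent demodulation -> displacement,
#' then the band-limited derived signals. The result carries exactly six
#' radar-side signals (I, Q, distance, radar respiration, heart sound, pulse)
#' and six contact-side signals (blood pressure, two ECG leads, ICG,
#' impedance Z0, contact respiration), plus the untouched marker channel.
#'
#' @param session an `hr_session` with channels `radar_i`, `radar_q`, `z0`
#' @param wavelength radar carrier wavelength in metres
#' @return a session-like object of class `hr_derived` whose `channels` are
#'   the 12 model-input signals plus `marker`, each an `hr_channel`; the
#'   fitted ellipse model is attached as `$ellipse`
#' @export
derive_all <- function(session, wavelength = radar_wavelength()) {
  ch <- session$channels
  for (nm in c("radar_i", "radar_q", "z0")) {
    if (is.null(ch[[nm]])) stop("session is missing required channel: ", nm)
  }
  fs_r <- ch$radar_i$fs
  rec <- ellipse_reconstruction(ch$radar_i$samples, ch$radar_q$samples)
  phi <- arctangent_demodulation(rec$i, rec$q)
  dist <- phase_to_displacement(phi, wavelength)
  hs <- extract_heart_sound(dist, fs_r)
  # respiration (<= 1 Hz) and the pulse envelope (<= 3 Hz) live far below
  # the unified 100 Hz rate, so they are computed on the anti-aliased
  # decimated traces; the heart sound is decimated after its 16-40 Hz
  # band extraction at the native rate
  q <- max(1L, as.integer(round(fs_r / 100)))
  fs_lo <- fs_r / q
  dist_lo <- antialias_decimate(dist, q)
  hs_lo <- antialias_decimate(hs, q)
  out <- list(
    radar_i = ch$radar_i,
    radar_q = ch$radar_q,
    radar_distance = channel("radar_distance", dist, fs_r),
    radar_respiration = channel("radar_respiration",
                                extract_respiration(dist_lo, fs_lo), fs_lo),
    heart_sound = channel("heart_sound", hs_lo, fs_lo),
    pulse = channel("pulse", heart_sound_to_pulse(hs_lo, fs_lo), fs_lo),
    bp = ch$bp, ecg1 = ch$ecg1, ecg2 = ch$ecg2, icg = ch$icg, z0 = ch$z0,
    contact_respiration = channel("contact_respiration",
                                  extract_respiration(ch$z0$samples,
                                                      ch$z0$fs), ch$z0$fs),
    marker = ch$marker
  )
  structure(list(subject_id = session$subject_id, scenario = session$scenario,
                 channels = out, ground_truth = session$ground_truth,
                 ellipse = rec$model, script = session$script),
            class = "hr_derived")
}

#' Signal names per input modality
#'
#' @param modality `"radar"`, `"contact"`, or `"fusion"`
#' @return character vector of canonical signal names
#' @export
modality_signals <- function(modality = c("radar", "contact", "fusion")) {
  modality <- match.arg(modality)
  radar <- c("radar_i", "radar_q", "radar_distance", "radar_respiration",
             "heart_sound", "pulse")
  contact <- c("bp", "ecg1", "ecg2", "icg", "z0", "contact_respiration")
  switch(modality, radar = radar, contact = contact,
         fusion = c(contact, radar))
}
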