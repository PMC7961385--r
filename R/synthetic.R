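## Synthetic cohort generator: scenario scripts, chest displacement, radar
## I/Q synthesis, contact reference channels, button-press marker channel.

#' Construct a single-channel signal container
#'
#' @param name channel name
#' @param samples numeric vector of samples
#' @param fs sampling rate in Hz (> 0)
#' @return an object of class `hr_channel`
#' @export
channel <- function(name, samples, fs) {
  stopifnot(is.numeric(samples), length(fs) == 1, fs > 0)
  if (!all(is.finite(samples))) stop("channel '", name, "': non-finite samples")
  structure(list(name = name, samples = as.numeric(samples), fs = fs),
            class = "hr_channel")
}

#' @export
print.hr_channel <- function(x, ...) {
  cat(sprintf("<channel %s: %d samples @ %g Hz (%.1f s)>\n",
              x$name, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Radar receiver imperfection model
#'
#' Describes the quadrature receiver non-idealities that turn the ideal unit
#' circle traced by (I, Q) into a translated, squashed and skewed ellipse:
#' DC offsets on each channel, an amplitude imbalance (I-channel gain relative
#' to Q), a phase skew between the two mixers, and additive white noise.
#'
#' @param dc_offsets length-2 numeric, offsets added to (I, Q)
#' @param amplitude_imbalance I/Q gain ratio, must be > 0
#' @param phase_skew quadrature phase error in radians
#' @param noise_sd standard deviation of additive Gaussian noise
#' @return an object of class `hr_imperfection`
#' @export
radar_imperfection <- function(dc_offsets = c(0, 0), amplitude_imbalance = 1,
                               phase_skew = 0, noise_sd = 0) {
  stopifnot(length(dc_offsets) == 2, amplitude_imbalance > 0, noise_sd >= 0)
  structure(list(dc_offsets = as.numeric(dc_offsets),
                 amplitude_imbalance = amplitude_imbalance,
                 phase_skew = phase_skew, noise_sd = noise_sd),
            class = "hr_imperfection")
}

## Scenario scripts ----------------------------------------------------------

default_physiology <- function() {
  list(
    breath_rate  = 0.25,   # Hz, ~15 breaths/min
    heart_rate   = 1.15,   # Hz, ~69 bpm
    breath_amp   = 4e-3,   # m, chest wall respiratory excursion
    cardiac_amp  = 3e-4,   # m, cardiac micro-motion
    # scenario modulation
    hold_breath_residual = 0.04,  # breathing amplitude factor inside holds
    valsalva_strain_amp  = 6e-3,  # m, strain-induced chest excursion
    tilt_shift           = 5e-3,  # m, baseline shift during tilt (signed later)
    tiltup_hr_factor     = 1.35,  # orthostatic HR increase
    tiltdown_hr_factor   = 0.75,
    tiltup_br_factor     = 1.2,
    tiltdown_br_factor   = 0.85,
    bp_baseline          = 90,    # mmHg
    bp_pulse_amp         = 30,    # mmHg pulse pressure
    bp_valsalva_excursion = 25,   # mmHg transient during strain
    bp_tilt_shift        = 10     # mmHg sustained shift after tilt (signed)
  )
}

draw_subject_physiology <- function(rng_seed) {
  with_seed(rng_seed, {
    p <- default_physiology()
    p$breath_rate <- runif(1, 0.20, 0.30)
    p$heart_rate  <- runif(1, 1.00, 1.30)
    p$breath_amp  <- runif(1, 3e-3, 5e-3)
    p$cardiac_amp <- runif(1, 2e-4, 4e-4)
    p
  })
}

#' Build a scenario script
#'
#' A script is the deterministic timeline of one recording session: total
#' duration, the maneuver/hold/tilt events, and the physiological parameters
#' driving the signal generators. Defaults follow the study protocol: the
#' Valsalva maneuver is performed 3 times for 20 s each with 5 min recovery
#' in between; apnea is two breath-holds (duration drawn from a configured
#' range, default 30-60 s); tilt sessions move the table once and then
#' continue recording for 10 min; resting has no events.
#'
#' @param scenario one of `scenario_levels()`
#' @param rng_seed integer seed (hold durations are drawn from it)
#' @param overrides named list overriding timeline/physiology defaults
#'   (e.g. `resting_duration`, `recovery_s`, `hold_range`, `continuation_s`,
#'   `physiology = list(...)`)
#' @return an object of class `hr_script` with fields `scenario`,
#'   `total_duration`, `events` (data.frame kind/time) and `physiology`
#' @export
make_scenario_script <- function(scenario, rng_seed = 1L, overrides = list()) {
  if (!is.character(scenario) || length(scenario) != 1 ||
      !scenario %in% scenario_levels()) {
    stop("unknown scenario: ", paste(scenario, collapse = ","))
  }
  o <- overrides
  phys <- default_physiology()
  if (!is.null(o$physiology)) phys[names(o$physiology)] <- o$physiology

  ev <- data.frame(kind = character(0), time = numeric(0))
  if (scenario == "Resting") {
    total <- o$resting_duration %||% 600
  } else if (scenario == "Valsalva") {
    lead_in  <- o$lead_in %||% 65
    man_s    <- o$maneuver_s %||% 20
    recovery <- o$recovery_s %||% 300
    tail_s   <- o$tail_s %||% 300
    starts <- lead_in + (0:2) * (man_s + recovery)
    ev <- data.frame(
      kind = rep(c("maneuver_start", "maneuver_end"), 3),
      time = as.vector(rbind(starts, starts + man_s)))
    total <- starts[3] + man_s + tail_s
  } else if (scenario == "Apnea") {
    lead_in <- o$lead_in %||% 45
    gap     <- o$gap_s %||% 60
    tail_s  <- o$tail_s %||% 45
    hr_rng  <- o$hold_range %||% c(30, 60)
    durs <- with_seed(derive_seed(rng_seed, 11),
                      runif(2, hr_rng[1], hr_rng[2]))
    s1 <- lead_in; e1 <- s1 + durs[1]
    s2 <- e1 + gap; e2 <- s2 + durs[2]
    ev <- data.frame(kind = c("hold_start", "hold_end", "hold_start", "hold_end"),
                     time = c(s1, e1, s2, e2))
    total <- e2 + tail_s
  } else { # TiltUp / TiltDown
    lead_in <- o$lead_in %||% 30
    motion  <- o$tilt_motion_s %||% 10
    cont    <- o$continuation_s %||% 600
    ev <- data.frame(kind = c("tilt_start", "tilt_end"),
                     time = c(lead_in, lead_in + motion))
    total <- lead_in + motion + cont
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(scenario = scenario, total_duration = total,
                 events = ev, physiology = phys, seed = rng_seed),
            class = "hr_script")
}

#' @export
print.hr_script <- function(x, ...) {
  cat(sprintf("<scenario script %s: %.0f s, %d events>\n",
              x$scenario, x$total_duration, nrow(x$events)))
  invisible(x)
}

# paired (start, end) intervals of a given event kind prefix
script_intervals <- function(script, prefix) {
  ev <- script$events
  s <- ev$time[ev$kind == paste0(prefix, "_start")]
  e <- ev$time[ev$kind == paste0(prefix, "_end")]
  if (length(s) != length(e)) stop("unpaired ", prefix, " events")
  if (length(s) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = s, end = e)
}

# 0/1 indicator over time t for a set of intervals, with smooth cosine ramps
smooth_indicator <- function(t, intervals, ramp = 1) {
  ind <- numeric(length(t))
  for (i in seq_len(nrow(intervals))) {
    a <- intervals$start[i]; b <- intervals$end[i]
    up   <- pmin(pmax((t - a) / ramp, 0), 1)
    down <- pmin(pmax((b - t) / ramp, 0), 1)
    seg <- pmin(up, down)
    seg <- 0.5 - 0.5 * cos(pi * pmin(seg * 2, 1)) # cosine-smoothed edges
    ind <- pmax(ind, seg * (t >= a - ramp) * (t <= b + ramp))
  }
  ind
}

# Shared physiological time course (rates, envelopes, strain, tilt shift)
# used by both the displacement and the contact-channel generators so that
# all modalities stay mutually consistent. Deterministic given the script.
physiology_timecourse <- function(script, fs) {
  n <- round(script$total_duration * fs)
  t <- (seq_len(n) - 1) / fs
  p <- script$physiology
  holds <- rbind(script_intervals(script, "hold"),
                 script_intervals(script, "maneuver"))
  hold_ind <- if (nrow(holds)) smooth_indicator(t, holds, ramp = 1) else numeric(n)

  fb <- rep(p$breath_rate, n)
  fh <- rep(p$heart_rate, n)
  tilt <- script_intervals(script, "tilt")
  tilt_shift <- numeric(n)
  if (nrow(tilt)) {
    # smooth transition of rates and baseline over the tilt motion interval
    tr <- pmin(pmax((t - tilt$start[1]) / (tilt$end[1] - tilt$start[1]), 0), 1)
    tr <- 0.5 - 0.5 * cos(pi * tr)
    if (script$scenario == "TiltUp") {
      fh <- p$heart_rate * (1 + (p$tiltup_hr_factor - 1) * tr)
      fb <- p$breath_rate * (1 + (p$tiltup_br_factor - 1) * tr)
      tilt_shift <- p$tilt_shift * tr
    } else {
      fh <- p$heart_rate * (1 + (p$tiltdown_hr_factor - 1) * tr)
      fb <- p$breath_rate * (1 + (p$tiltdown_br_factor - 1) * tr)
      tilt_shift <- -p$tilt_shift * tr
    }
  }
  breath_env <- 1 - (1 - p$hold_breath_residual) * hold_ind

  strain <- numeric(n)
  man <- script_intervals(script, "maneuver")
  if (nrow(man)) {
    for (i in seq_len(nrow(man))) {
      a <- man$start[i]; b <- man$end[i]
      inside <- t >= a & t <= b
      # raised-cosine strain bump peaking mid-maneuver
      strain[inside] <- strain[inside] +
        0.5 * (1 - cos(2 * pi * (t[inside] - a) / (b - a)))
    }
  }
  # apnea holds at full inhale (first) / full exhale (second): small sustained
  # chest offset of opposite sign
  lung_offset <- numeric(n)
  ap <- script_intervals(script, "hold")
  if (nrow(ap)) {
    for (i in seq_len(nrow(ap))) {
      sgn <- if (i %% 2 == 1) 1 else -1
      lung_offset <- lung_offset +
        sgn * smooth_indicator(t, ap[i, , drop = FALSE], ramp = 2)
    }
  }
  # integrated phases (rates may vary over time)
  theta_b <- 2 * pi * cumsum(fb) / fs
  theta_h <- 2 * pi * cumsum(fh) / fs
  list(t = t, n = n, fb = fb, fh = fh, theta_b = theta_b, theta_h = theta_h,
       breath_env = breath_env, strain = strain, tilt_shift = tilt_shift,
       lung_offset = lung_offset)
}

# periodic sharp pulse train, one bump per 2*pi of phase; kappa sets sharpness
vm_pulse <- function(theta, kappa) {
  exp(kappa * (cos(theta) - 1))
}

#' Generate the chest-wall displacement trace for a scenario script
#'
#' Additive model: a breathing sinusoid (suppressed to a small residual inside
#' apnea/Valsalva holds), a sharp periodic cardiac micro-motion pulse train
#' (so that heart-sound band harmonics exist), a Valsalva strain excursion, a
#' step-like baseline shift during tilt, a sustained lung-volume offset during
#' breath-holds, and white Gaussian noise.
#'
#' @param script an `hr_script`
#' @param fs sampling rate in Hz, must be at least 4x the heart rate
#' @param rng_seed integer seed (noise)
#' @param noise_sd displacement noise standard deviation in metres
#' @return numeric vector of displacement in metres, length
#'   `round(total_duration * fs)`
#' @export
generate_displacement <- function(script, fs = 2000, rng_seed = 1L,
                                  noise_sd = 2e-5) {
  p <- script$physiology
  if (p$breath_amp <= 0 || p$cardiac_amp <= 0)
    stop("non-positive displacement amplitudes")
  if (fs < 4 * p$heart_rate) stop("fs too low for the cardiac component")
  tc <- physiology_timecourse(script, fs)
  breathing <- p$breath_amp * tc$breath_env * sin(tc$theta_b)
  cardiac   <- p$cardiac_amp * vm_pulse(tc$theta_h, 400)
  strain    <- p$valsalva_strain_amp * tc$strain
  baseline  <- tc$tilt_shift + 0.5 * p$breath_amp * tc$lung_offset
  noise <- if (noise_sd > 0) {
    with_seed(derive_seed(rng_seed, 21), rnorm(tc$n, 0, noise_sd))
  } else numeric(tc$n)
  breathing + cardiac + strain + baseline + noise
}

#' Convert a displacement trace into radar I/Q channels
#'
#' The ideal receiver phase is phi(t) = 2*pi * 2*x(t) / lambda + phi0 (two-way
#' path), giving I = cos(phi), Q = sin(phi) on the unit circle. The
#' imperfection model then applies amplitude imbalance to I, phase skew to Q,
#' DC offsets, and additive noise, which turns the circle into an ellipse.
#'
#' @param x displacement in metres
#' @param wavelength carrier wavelength in metres
#' @param imperfection an `hr_imperfection`
#' @param rng_seed integer seed (receiver noise)
#' @param phi0 static path phase in radians (default 0.7, kept away from the
#'   arctangent branch points)
#' @return list with numeric vectors `i` and `q`
#' @export
displacement_to_iq <- function(x, wavelength = radar_wavelength(),
                               imperfection = radar_imperfection(),
                               rng_seed = 1L, phi0 = 0.7) {
  stopifnot(wavelength > 0)
  phi <- 2 * pi * 2 * x / wavelength + phi0
  imp <- imperfection
  i <- imp$amplitude_imbalance * cos(phi) + imp$dc_offsets[1]
  q <- sin(phi + imp$phase_skew) + imp$dc_offsets[2]
  if (imp$noise_sd > 0) {
    noise <- with_seed(derive_seed(rng_seed, 31),
                       rnorm(2 * length(x), 0, imp$noise_sd))
    i <- i + noise[seq_along(x)]
    q <- q + noise[length(x) + seq_along(x)]
  }
  list(i = i, q = q)
}

#' Generate the contact reference channels for a scenario script
#'
#' Produces surrogates of the clinical reference monitor channels:
#' two ECG leads (sharp R-wave pulse trains of different amplitude/polarity),
#' an impedance cardiogram (differentiated cardiac pulse), continuous blood
#' pressure (baseline + pulse wave + Valsalva transient + sustained tilt
#' shift), and thoracic impedance Z0 (breathing-correlated slow wave,
#' suppressed during breath-holds). All channels share the physiological time
#' course of the displacement generator.
#'
#' @param script an `hr_script`
#' @param fs_map named sampling rates in Hz for `ecg1`, `ecg2`, `icg`, `bp`,
#'   `z0` (each >= 100)
#' @param rng_seed integer seed (channel noise)
#' @return named list of `hr_channel` objects
#' @export
generate_contact_channels <- function(script,
                                      fs_map = c(ecg1 = 1000, ecg2 = 1000,
                                                 icg = 500, bp = 100, z0 = 100),
                                      rng_seed = 1L) {
  need <- c("ecg1", "ecg2", "icg", "bp", "z0")
  stopifnot(all(need %in% names(fs_map)))
  if (any(fs_map[need] < 100)) stop("contact channel fs must be >= 100 Hz")
  p <- script$physiology
  out <- list()
  tc_cache <- list() # physiology time course per unique sampling rate
  for (nm in need) {
    fs <- fs_map[[nm]]
    tc <- tc_cache[[as.character(fs)]]
    if (is.null(tc)) {
      tc <- physiology_timecourse(script, fs)
      tc_cache[[as.character(fs)]] <- tc
    }
    ns <- derive_seed(rng_seed, match(nm, need), 41)
    x <- switch(nm,
      ecg1 = vm_pulse(tc$theta_h, 2000) +
        with_seed(ns, rnorm(tc$n, 0, 0.03)),
      ecg2 = -0.6 * vm_pulse(tc$theta_h + 0.3, 2000) +
        with_seed(ns, rnorm(tc$n, 0, 0.03)),
      icg = c(0, diff(vm_pulse(tc$theta_h, 150))) * fs / 50 +
        with_seed(ns, rnorm(tc$n, 0, 0.05)),
      bp = p$bp_baseline + p$bp_pulse_amp * vm_pulse(tc$theta_h, 15) +
        p$bp_valsalva_excursion * tc$strain +
        p$bp_tilt_shift * (tc$tilt_shift / p$tilt_shift) +
        with_seed(ns, rnorm(tc$n, 0, 0.5)),
      z0 = 0.5 * tc$breath_env * sin(tc$theta_b) +
        0.2 * tc$lung_offset +
        with_seed(ns, rnorm(tc$n, 0, 0.02))
    )
    out[[nm]] <- channel(nm, x, fs)
  }
  out
}

#' Generate the button-press marker channel for a scenario script
#'
#' The marker is a baseline-high electrical signal; button presses appear as
#' sharp drops. Short rectangular drops (default 0.5 s wide, to 20% of
#' baseline) mark the start and end of each Valsalva maneuver and of the tilt
#' motion; apnea breath-holds are marked by pressing and holding the button
#' for the whole hold. Resting sessions have a constant baseline.
#'
#' @param script an `hr_script`
#' @param fs sampling rate in Hz (>= 10)
#' @param press_width_s short-press width in seconds
#' @param baseline baseline level
#' @param drop_depth fractional drop (0.8 means the signal falls to 20% of
#'   baseline during a press)
#' @return an `hr_channel` named "marker"
#' @export
generate_marker <- function(script, fs = 100, press_width_s = 0.5,
                            baseline = 1, drop_depth = 0.8) {
  stopifnot(fs >= 10)
  n <- round(script$total_duration * fs)
  t <- (seq_len(n) - 1) / fs
  if (nrow(script$events) &&
      (min(script$events$time) < 0 ||
       max(script$events$time) > script$total_duration)) {
    stop("script events outside the session extent")
  }
  x <- rep(baseline, n)
  low <- baseline * (1 - drop_depth)
  pulses <- script$events$time[script$events$kind %in%
    c("maneuver_start", "maneuver_end", "tilt_start", "tilt_end")]
  for (tp in pulses) x[t >= tp & t < tp + press_width_s] <- low
  holds <- script_intervals(script, "hold")
  for (i in seq_len(nrow(holds))) {
    x[t >= holds$start[i] & t < holds$end[i]] <- low
  }
  channel("marker", x, fs)
}

## Sessions and cohorts ------------------------------------------------------

#' Session generation configuration
#'
#' Bundles the knobs of one recording session: sampling rates, radar carrier
#' wavelength, receiver imperfection, displacement noise, and per-scenario
#' script overrides.
#'
#' @param fs_radar radar I/Q sampling rate (Hz)
#' @param fs_contact named contact-channel sampling rates (Hz)
#' @param fs_marker marker sampling rate (Hz)
#' @param wavelength radar carrier wavelength (m)
#' @param imperfection an `hr_imperfection`; the default models a mildly
#'   non-ideal receiver so that ellipse reconstruction is genuinely exercised
#' @param displacement_noise_sd metres
#' @param script_overrides named list passed to [make_scenario_script()]
#' @param physiology optional fixed physiology (otherwise drawn per subject)
#' @return list of class `hr_config`
#' @export
session_config <- function(fs_radar = 2000,
                           fs_contact = c(ecg1 = 1000, ecg2 = 1000, icg = 500,
                                          bp = 100, z0 = 100),
                           fs_marker = 100,
                           wavelength = radar_wavelength(),
                           imperfection = radar_imperfection(
                             dc_offsets = c(0.15, -0.1),
                             amplitude_imbalance = 1.3,
                             phase_skew = 0.05, noise_sd = 0.01),
                           displacement_noise_sd = 2e-5,
                           script_overrides = list(),
                           physiology = NULL) {
  structure(list(fs_radar = fs_radar, fs_contact = fs_contact,
                 fs_marker = fs_marker, wavelength = wavelength,
                 imperfection = imperfection,
                 displacement_noise_sd = displacement_noise_sd,
                 script_overrides = script_overrides,
                 physiology = physiology),
            class = "hr_config")
}

#' Generate one synthetic recording session
#'
#' Assembles scenario script -> displacement -> radar I/Q -> contact channels
#' -> marker, and records the ground-truth labeled intervals (non-active
#' periods are "Other").
#'
#' @param subject_id subject identifier
#' @param scenario one of `scenario_levels()`
#' @param config an `hr_config`
#' @param rng_seed integer seed; identical (subject, scenario, config, seed)
#'   gives a bit-identical session
#' @return object of class `hr_session` with fields `subject_id`, `scenario`,
#'   `channels` (named `hr_channel` list: radar_i, radar_q, ecg1, ecg2, icg,
#'   bp, z0, marker), `ground_truth` (data.frame start/end/class),
#'   `script`, `config`
#' @export
generate_session <- function(subject_id, scenario, config = session_config(),
                             rng_seed = 1L) {
  ov <- config$script_overrides
  if (!is.null(config$physiology)) {
    ov$physiology <- utils::modifyList(config$physiology,
                                       ov$physiology %||% list())
  }
  script <- make_scenario_script(scenario, rng_seed = derive_seed(rng_seed, 1),
                                 overrides = ov)
  x <- generate_displacement(script, fs = config$fs_radar,
                             rng_seed = derive_seed(rng_seed, 2),
                             noise_sd = config$displacement_noise_sd)
  iq <- displacement_to_iq(x, wavelength = config$wavelength,
                           imperfection = config$imperfection,
                           rng_seed = derive_seed(rng_seed, 3))
  contact <- generate_contact_channels(script, fs_map = config$fs_contact,
                                       rng_seed = derive_seed(rng_seed, 4))
  marker <- generate_marker(script, fs = config$fs_marker)

  gt <- ground_truth_from_script(script)
  chans <- c(list(radar_i = channel("radar_i", iq$i, config$fs_radar),
                  radar_q = channel("radar_q", iq$q, config$fs_radar)),
             contact, list(marker = marker))
  structure(list(subject_id = subject_id, scenario = scenario,
                 channels = chans, ground_truth = gt, script = script,
                 config = config, seed = rng_seed),
            class = "hr_session")
}

#' @export
print.hr_session <- function(x, ...) {
  cat(sprintf("<session %s/%s: %.0f s, channels: %s>\n", x$subject_id,
              x$scenario, x$script$total_duration,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# ground-truth labeled intervals from the script; gaps are Other
ground_truth_from_script <- function(script) {
  total <- script$total_duration
  sc <- script$scenario
  active <- switch(sc,
    Resting = data.frame(start = 0, end = total),
    Valsalva = script_intervals(script, "maneuver"),
    Apnea = script_intervals(script, "hold"),
    { ti <- script_intervals(script, "tilt")
      data.frame(start = ti$start[1], end = total) })
  active$class <- sc
  # fill gaps with Other
  gaps <- data.frame(start = numeric(0), end = numeric(0), class = character(0))
  cur <- 0
  for (i in seq_len(nrow(active))) {
    if (active$start[i] > cur) {
      gaps <- rbind(gaps, data.frame(start = cur, end = active$start[i],
                                     class = "Other"))
    }
    cur <- active$end[i]
  }
  if (cur < total) gaps <- rbind(gaps, data.frame(start = cur, end = total,
                                                  class = "Other"))
  out <- rbind(active, gaps)
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic cohort
#'
#' Per-subject physiology (resting heart and breathing rate, motion
#' amplitudes) is drawn once and shared across all of that subject's
#' sessions. The default cohort mirrors the study: 30 subjects, each
#' recorded in all five scenarios.
#'
#' @param n_subjects number of subjects (>= 1)
#' @param scenarios character vector of scenarios per subject
#' @param config an `hr_config`
#' @param rng_seed integer master seed
#' @return list of `hr_session`
#' @export
generate_cohort <- function(n_subjects = 30, scenarios = scenario_levels(),
                            config = session_config(), rng_seed = 1L) {
  stopifnot(n_subjects >= 1)
  sessions <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%02d", s)
    cfg <- config
    cfg$physiology <- draw_subject_physiology(derive_seed(rng_seed, s, 101))
    for (sc in scenarios) {
      sess <- generate_session(sid, sc, cfg,
                               rng_seed = derive_seed(rng_seed, s,
                                                      match(sc, scenario_levels())))
      sessions[[length(sessions) + 1]] <- sess
    }
  }
  sessions
}
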