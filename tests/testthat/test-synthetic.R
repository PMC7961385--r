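# Scenario scripts, displacement physics, radar I/Q synthesis, contact
# surrogates, marker semantics, session/cohort assembly.

test_that("scenario scripts encode the study protocol", {
  v <- make_scenario_script("Valsalva", rng_seed = 1)
  man <- v$events[v$events$kind == "maneuver_start", "time"]
  stop_ <- v$events[v$events$kind == "maneuver_end", "time"]
  expect_length(man, 3)
  expect_equal(stop_ - man, rep(20, 3))
  # 5 min recovery between consecutive maneuvers
  expect_equal(man[2] - stop_[1], 300)
  expect_equal(man[3] - stop_[2], 300)

  r <- make_scenario_script("Resting", rng_seed = 1)
  expect_equal(nrow(r$events), 0)

  a1 <- make_scenario_script("Apnea", rng_seed = 2)
  a2 <- make_scenario_script("Apnea", rng_seed = 2)
  holds <- a1$events[a1$events$kind == "hold_start", "time"]
  expect_length(holds, 2)
  durs <- a1$events[a1$events$kind == "hold_end", "time"] - holds
  expect_true(all(durs >= 30 & durs <= 60))
  expect_identical(a1, a2) # seeded determinism

  t <- make_scenario_script("TiltUp", rng_seed = 1)
  tilt_end <- t$events[t$events$kind == "tilt_end", "time"]
  expect_equal(t$total_duration - tilt_end, 600) # 10 min continuation

  expect_error(make_scenario_script("Jogging"), "unknown scenario")
})

test_that("script events are sorted, nested, and inside the session", {
  for (sc in scenario_levels()) {
    s <- make_scenario_script(sc, rng_seed = 3)
    ev <- s$events
    expect_true(!is.unsorted(ev$time))
    if (nrow(ev)) {
      expect_true(all(ev$time >= 0 & ev$time <= s$total_duration))
      starts <- grepl("_start$", ev$kind)
      expect_equal(sum(starts), sum(!starts))
    }
  }
})

test_that("displacement has breathing peak at the scripted rate", {
  sc <- make_scenario_script("Resting", 1,
                             overrides = list(resting_duration = 120,
                                              physiology = list(breath_rate = 0.25)))
  x <- generate_displacement(sc, fs = 200, rng_seed = 1, noise_sd = 0)
  sp <- Mod(stats::fft(x - mean(x)))^2
  freqs <- (seq_along(x) - 1) * 200 / length(x)
  half <- seq_len(length(x) / 2)
  expect_equal(freqs[half][which.max(sp[half])], 0.25, tolerance = 0.02)
})

test_that("breathing band power is suppressed inside apnea holds", {
  sc <- make_scenario_script("Apnea", 2)
  fs <- 200
  x <- generate_displacement(sc, fs = fs, rng_seed = 1, noise_sd = 0)
  holds <- sc$events[sc$events$kind == "hold_start", "time"]
  hold_end <- sc$events[sc$events$kind == "hold_end", "time"]
  band_power <- function(seg) {
    sp <- Mod(stats::fft(seg - mean(seg)))^2
    f <- (seq_along(seg) - 1) * fs / length(seg)
    sum(sp[f >= 0.1 & f <= 0.5])
  }
  # interior of the first hold vs an equally long resting stretch before it
  i1 <- round((holds[1] + 3) * fs):round((hold_end[1] - 3) * fs)
  n1 <- length(i1)
  i0 <- round(5 * fs) + seq_len(n1)
  expect_lt(band_power(x[i1]), 0.1 * band_power(x[i0]))
})

test_that("displacement degenerates to a constant without components", {
  sc <- make_scenario_script("Resting", 1,
                             overrides = list(resting_duration = 30))
  sc$physiology$breath_amp <- 1e-300
  sc$physiology$cardiac_amp <- 1e-300
  x <- generate_displacement(sc, fs = 100, rng_seed = 1, noise_sd = 0)
  expect_lt(diff(range(x)), 1e-12)
  sc$physiology$breath_amp <- -1
  expect_error(generate_displacement(sc, fs = 100), "non-positive")
})

test_that("I/Q synthesis follows the two-way phase model", {
  # constant displacement -> constant point at the static phase
  iq <- displacement_to_iq(numeric(100), imperfection = radar_imperfection())
  expect_equal(iq$i, rep(cos(0.7), 100))
  expect_equal(iq$q, rep(sin(0.7), 100))
  expect_equal(iq$i^2 + iq$q^2, rep(1, 100)) # unit circle

  # ramp of lambda/2 -> full 2*pi phase turn; demodulated round trip exact
  lam <- radar_wavelength()
  x <- seq(0, lam / 2, length.out = 2000)
  iq <- displacement_to_iq(x, imperfection = radar_imperfection())
  phi <- arctangent_demodulation(iq$i, iq$q)
  expect_equal(phi[2000] - phi[1], 2 * pi, tolerance = 1e-9)
  xr <- phase_to_displacement(phi, lam)
  expect_lt(max(abs(xr - (x - x[1]))), 1e-9)

  # amplitude imbalance 2 -> elliptical trajectory with axis ratio 2
  x2 <- seq(0, 2 * lam, length.out = 4000)
  iq2 <- displacement_to_iq(x2, imperfection = radar_imperfection(
    amplitude_imbalance = 2.0))
  fit <- ellipse_reconstruction(iq2$i, iq2$q)
  expect_equal(fit$model$semi_axes[1] / fit$model$semi_axes[2], 2.0,
               tolerance = 1e-6)
})

test_that("contact surrogates carry the scripted physiology", {
  sc <- make_scenario_script("Resting", 1,
                             overrides = list(resting_duration = 60,
                                              physiology = list(heart_rate = 1.2,
                                                                breath_rate = 0.25)))
  ch <- generate_contact_channels(sc, rng_seed = 1)
  # ECG dominant inter-spike interval ~ 1/1.2 s
  e <- ch$ecg1$samples
  peaks <- which(e > 0.5 & e >= c(e[-1], 0) & e >= c(0, e[-length(e)]))
  gaps <- diff(peaks) / ch$ecg1$fs
  expect_equal(median(gaps), 1 / 1.2, tolerance = 0.01)
  # z0 breathing peak at the scripted breath rate
  z <- ch$z0$samples
  sp <- Mod(stats::fft(z - mean(z)))^2
  f <- (seq_along(z) - 1) * ch$z0$fs / length(z)
  half <- seq_len(length(z) / 2)
  expect_equal(f[half][which.max(sp[half])], 0.25, tolerance = 0.03)

  # tilt produces a sustained blood-pressure shift
  tu <- make_scenario_script("TiltUp", 1,
                             overrides = list(continuation_s = 120))
  bp <- generate_contact_channels(tu, rng_seed = 1)$bp
  tilt_start <- tu$events$time[tu$events$kind == "tilt_start"]
  tilt_end <- tu$events$time[tu$events$kind == "tilt_end"]
  before <- mean(bp$samples[seq_len(round(tilt_start * bp$fs))])
  after <- mean(bp$samples[round((tilt_end + 5) * bp$fs):length(bp$samples)])
  expect_equal(after - before,
               hemoradar:::default_physiology()$bp_tilt_shift,
               tolerance = 0.5)
})

test_that("marker channel encodes button-press semantics", {
  v <- make_scenario_script("Valsalva", 1)
  mk <- generate_marker(v, fs = 100)
  r <- rle(mk$samples < 0.5)
  expect_equal(sum(r$values), 6) # press at start and end of 3 maneuvers

  rest <- make_scenario_script("Resting", 1)
  mkr <- generate_marker(rest, fs = 100)
  expect_equal(diff(range(mkr$samples)), 0)

  a <- make_scenario_script("Apnea", 1)
  mka <- generate_marker(a, fs = 100)
  holds <- a$events$time[a$events$kind == "hold_start"]
  hold_end <- a$events$time[a$events$kind == "hold_end"]
  low <- which(mka$samples < 0.5)
  runs <- split(low, cumsum(c(1, diff(low) > 1)))
  expect_length(runs, 2)
  expect_equal((runs[[1]][1] - 1) / 100, holds[1], tolerance = 1 / 100)
  expect_equal(runs[[1]][length(runs[[1]])] / 100, hold_end[1],
               tolerance = 1 / 100)

  bad <- v
  bad$events$time[1] <- -5
  expect_error(generate_marker(bad, fs = 100), "outside")
})

test_that("sessions are deterministic and carry ground truth", {
  cfg <- short_config()
  s1 <- generate_session("s01", "Valsalva", cfg, rng_seed = 5)
  s2 <- generate_session("s01", "Valsalva", cfg, rng_seed = 5)
  expect_identical(s1, s2)
  gt <- s1$ground_truth
  expect_equal(sum(gt$class == "Valsalva"), 3)
  expect_true(all(gt$class %in% c("Valsalva", "Other")))

  r <- generate_session("s01", "Resting", cfg, rng_seed = 5)
  expect_equal(r$ground_truth$class, "Resting")
  expect_equal(r$ground_truth$end, r$script$total_duration)
  expect_equal(r$channels$radar_i$fs, 2000)
})

test_that("cohorts share per-subject physiology across scenarios", {
  cfg <- short_config()
  co <- generate_cohort(2, c("Resting", "Apnea"), cfg, rng_seed = 7)
  expect_length(co, 4)
  hr <- vapply(co, function(s) s$script$physiology$heart_rate, 1)
  ids <- vapply(co, function(s) s$subject_id, "")
  expect_equal(hr[ids == "s01"][1], hr[ids == "s01"][2])
  expect_false(hr[ids == "s01"][1] == hr[ids == "s02"][1])

  co2 <- generate_cohort(2, "Resting", cfg, rng_seed = 7)
  expect_length(co2, 2)
  expect_true(all(vapply(co2, function(s) s$ground_truth$class[1], "") ==
                    "Resting"))
})
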