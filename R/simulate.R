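# Ground-truth-labeled synthetic recordings. The generator emulates the
# signal taxonomy the detector must separate: burst-like gross fetal
# movements; the regular ~1.0 Hz maternal heartbeat; REM-irregular
# respiration transients at 3-5 s intervals; maternal gross movements
# visible on both channels; periodic limb movement trains at 5-90 s
# intervals; fetal hiccup trains at ~2-s periods lasting 5-15 min; and
# wake/restroom episodes of dense maternal movement. Amplitudes are in
# arbitrary device units calibrated so the default minimum integral
# thresholds (15 FM / 20 MM) sit between the noise-floor integrals and
# typical burst integrals; the FM sensor is 6x as sensitive as the MM
# sensor, so shared physical signals appear at a 6:1 FM:MM amplitude ratio.

#' Simulation configuration
#'
#' Builds a `SimulationConfig` with the stated defaults; override any field
#' via `...` (unknown names are an error). Rates are per hour so shorter
#' test recordings keep the same statistics. Setting a component's
#' `amplitude` (or rate/count) to 0 removes it.
#'
#' @param duration_s recording length in seconds (> 60; default 3600).
#' @param sampling_rate Hz (default 100).
#' @param seed RNG seed; identical config + seed gives bit-identical output.
#' @param ... named overrides of the component blocks (`fetal`,
#'   `heartbeat`, `respiration`, `maternal`, `plm`, `hiccup`, `wake`,
#'   `restroom`, `noise_sd`, `crosstalk_gain`, `fm_mm_gain`).
#' @return A list of class `fm_simconfig`.
#' @export
sim_config <- function(duration_s = 3600, sampling_rate = 100, seed = 1L, ...) {
  cfg <- list(
    duration_s = duration_s,
    sampling_rate = sampling_rate,
    seed = as.integer(seed),
    fetal = list(rate_per_hour = 100, duration_range_s = c(0.5, 3),
                 amplitude_range = c(20, 40)),
    heartbeat = list(frequency_hz = 1.0, amplitude = 6, jitter_s = 0.02),
    respiration = list(period_range_s = c(3, 5), slow_amplitude = 10,
                       transient_amplitude_range = c(1.5, 3),
                       transient_duration_s = 0.7,
                       rem_fraction_of_last_third = 0.6),
    maternal = list(rate_per_hour = 12, duration_range_s = c(1, 4),
                    amplitude_range = c(8, 14)),
    plm = list(n_runs = 0, run_length_range = c(4, 10),
               interval_range_s = c(20, 40), duration_s = 1.5,
               amplitude = 10),
    hiccup = list(n_bouts = 0, bout_duration_range_s = c(300, 900),
                  period_s = 2, period_jitter_s = 0.15,
                  pulse_duration_s = 0.35, amplitude = 25),
    wake = list(n_episodes = 1, duration_range_s = c(60, 180),
                events_per_minute = 6),
    restroom = list(n_episodes = 0, duration_range_s = c(330, 480),
                    events_per_minute = 8),
    noise_sd = 1.0,
    crosstalk_gain = 0.3,   # fraction of a maternal movement reaching the abdomen
    fm_mm_gain = 6          # FM sensor sensitivity relative to MM
  )
  cfg <- modify_config(cfg, list(...))
  if (cfg$duration_s <= 60) stop_fm("fm_config_error", "duration_s must exceed 60")
  if (cfg$sampling_rate < 20) stop_fm("fm_config_error", "sampling_rate must be >= 20 Hz")
  structure(cfg, class = "fm_simconfig")
}

# --- waveform primitives (all add in place into a numeric vector) --------

# Enveloped sinusoidal burst; carrier frequency in the 0.5-2.5 Hz band.
# envelope "hann" for waxing/waning fetal movement bursts; "flat" (tapered
# cosine with 0.15-s ramps) for abrupt-onset maternal muscle jerks (gross
# movement, PLM), whose supra-threshold extent then tracks their duration.
render_burst <- function(x, fs, t0, dur, amp, carrier_hz, phase,
                         envelope = c("hann", "flat")) {
  envelope <- match.arg(envelope)
  i0 <- floor(t0 * fs) + 1L
  n <- max(round(dur * fs), 2L)
  i1 <- min(i0 + n - 1L, length(x))
  if (i0 > length(x)) return(x)
  tt <- (seq.int(i0, i1) - i0) / fs
  env <- if (envelope == "hann") {
    0.5 * (1 - cos(2 * pi * tt / dur))
  } else {
    ramp <- min(0.15, dur / 4)
    pmin(1, pmin(tt, dur - tt) / ramp)
  }
  x[i0:i1] <- x[i0:i1] + amp * env * sin(2 * pi * carrier_hz * tt + phase)
  x
}

# Single biphasic (one-cycle sine) pulse.
render_biphasic <- function(x, fs, t0, dur, amp) {
  i0 <- floor(t0 * fs) + 1L
  n <- max(round(dur * fs), 2L)
  i1 <- min(i0 + n - 1L, length(x))
  if (i0 > length(x)) return(x)
  tt <- (seq.int(i0, i1) - i0) / fs
  x[i0:i1] <- x[i0:i1] + amp * sin(2 * pi * tt / dur)
  x
}

truth_row <- function(class, channel, start_s, end_s) {
  data.frame(class = class, channel = channel, start_s = start_s,
             end_s = end_s, stringsAsFactors = FALSE)
}

#' Simulate a two-channel recording with ground truth
#'
#' @param cfg a [sim_config()].
#' @return List with `recording` (an [fm_recording()]) and `truth`, a data
#'   frame of annotations (`class`, `channel`, `start_s`, `end_s`) with
#'   class in `fetal_burst`, `heartbeat`, `respiration`, `maternal_move`,
#'   `plm`, `hiccup`, `wake`, `restroom`. Every injected waveform is
#'   annotated; the continuous heartbeat and each breath are annotated as
#'   spans/per-breath rows respectively. Deterministic per seed.
#' @examples
#' sim <- simulate_recording(sim_config(duration_s = 120, seed = 7))
#' table(sim$truth$class)
#' @export
simulate_recording <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "fm_simconfig"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  fs <- cfg$sampling_rate
  total <- cfg$duration_s
  n <- round(total * fs)
  fm <- numeric(n); mm <- numeric(n)
  truth <- list()
  hours <- total / 3600

  # ---- wake / restroom episodes (placed first; other events avoid them) --
  busy <- data.frame(start_s = numeric(0), end_s = numeric(0))
  place_episode <- function(dur) {
    # uniform placement avoiding previously placed busy intervals
    for (try in 1:50) {
      t0 <- stats::runif(1, 30, total - dur - 30)
      if (!any(t0 < busy$end_s + 60 & busy$start_s - 60 < t0 + dur)) return(t0)
    }
    NA_real_
  }
  add_movement_cluster <- function(t0, dur, per_min) {
    k <- max(round(per_min * dur / 60), 1L)
    onsets <- sort(stats::runif(k, t0, t0 + dur - 2))
    for (o in onsets) {
      d <- stats::runif(1, 1, 2.5)
      a <- stats::runif(1, cfg$maternal$amplitude_range[1], cfg$maternal$amplitude_range[2])
      car <- stats::runif(1, 0.8, 2.2); ph <- stats::runif(1, 0, 2 * pi)
      mm <<- render_burst(mm, fs, o, d, a, car, ph, "flat")
      fm <<- render_burst(fm, fs, o, d, cfg$crosstalk_gain * cfg$fm_mm_gain * a,
                          car, ph, "flat")
      truth[[length(truth) + 1L]] <<- truth_row("maternal_move", "both", o, o + d)
    }
  }
  for (kind in c("restroom", "wake")) {
    kc <- cfg[[kind]]
    for (i in seq_len(kc$n_episodes)) {
      dur <- stats::runif(1, kc$duration_range_s[1], kc$duration_range_s[2])
      t0 <- place_episode(dur)
      if (is.na(t0)) next
      busy <- rbind(busy, data.frame(start_s = t0, end_s = t0 + dur))
      add_movement_cluster(t0, dur, kc$events_per_minute)
      truth[[length(truth) + 1L]] <- truth_row(kind, "both", t0, t0 + dur)
    }
  }
  in_busy <- function(t0, dur) {
    nrow(busy) > 0 && any(t0 < busy$end_s & busy$start_s < t0 + dur)
  }

  # ---- isolated maternal movements --------------------------------------
  n_mat <- stats::rpois(1, cfg$maternal$rate_per_hour * hours)
  for (i in seq_len(n_mat)) {
    t0 <- stats::runif(1, 15, total - 20)
    d <- stats::runif(1, cfg$maternal$duration_range_s[1], cfg$maternal$duration_range_s[2])
    if (in_busy(t0, d)) next
    a <- stats::runif(1, cfg$maternal$amplitude_range[1], cfg$maternal$amplitude_range[2])
    car <- stats::runif(1, 0.8, 2.2); ph <- stats::runif(1, 0, 2 * pi)
    mm <- render_burst(mm, fs, t0, d, a, car, ph, "flat")
    fm <- render_burst(fm, fs, t0, d, cfg$crosstalk_gain * cfg$fm_mm_gain * a,
                       car, ph, "flat")
    truth[[length(truth) + 1L]] <- truth_row("maternal_move", "both", t0, t0 + d)
  }

  # ---- PLM trains (MM channel, crosstalk to FM) -------------------------
  for (r in seq_len(cfg$plm$n_runs)) {
    len <- sample(cfg$plm$run_length_range[1]:cfg$plm$run_length_range[2], 1L)
    ivs <- stats::runif(len - 1L, cfg$plm$interval_range_s[1], cfg$plm$interval_range_s[2])
    span <- sum(ivs) + cfg$plm$duration_s
    t0 <- place_episode(span)
    if (is.na(t0)) next
    busy <- rbind(busy, data.frame(start_s = t0, end_s = t0 + span))
    onsets <- t0 + c(0, cumsum(ivs))
    for (o in onsets) {
      car <- stats::runif(1, 1.0, 2.0); ph <- stats::runif(1, 0, 2 * pi)
      mm <- render_burst(mm, fs, o, cfg$plm$duration_s, cfg$plm$amplitude,
                         car, ph, "flat")
      fm <- render_burst(fm, fs, o, cfg$plm$duration_s,
                         cfg$crosstalk_gain * cfg$fm_mm_gain * cfg$plm$amplitude,
                         car, ph, "flat")
      truth[[length(truth) + 1L]] <- truth_row("plm", "both", o, o + cfg$plm$duration_s)
    }
  }

  # ---- fetal hiccup bouts (FM only) -------------------------------------
  for (b in seq_len(cfg$hiccup$n_bouts)) {
    dur <- stats::runif(1, cfg$hiccup$bout_duration_range_s[1],
                        cfg$hiccup$bout_duration_range_s[2])
    t0 <- place_episode(dur)
    if (is.na(t0)) next
    busy <- rbind(busy, data.frame(start_s = t0, end_s = t0 + dur))
    t <- t0
    while (t < t0 + dur) {
      fm <- render_biphasic(fm, fs, t, cfg$hiccup$pulse_duration_s, cfg$hiccup$amplitude)
      truth[[length(truth) + 1L]] <- truth_row("hiccup", "FM", t,
                                               t + cfg$hiccup$pulse_duration_s)
      t <- t + cfg$hiccup$period_s +
        stats::runif(1, -cfg$hiccup$period_jitter_s, cfg$hiccup$period_jitter_s)
    }
  }

  # ---- gross fetal movement bursts (FM only) ----------------------------
  n_fet <- stats::rpois(1, cfg$fetal$rate_per_hour * hours)
  placed <- data.frame(start_s = numeric(0), end_s = numeric(0))
  for (i in seq_len(n_fet)) {
    d <- stats::runif(1, cfg$fetal$duration_range_s[1], cfg$fetal$duration_range_s[2])
    t0 <- stats::runif(1, 15, total - d - 15)
    # keep injected bursts resolvable: no overlap with busy episodes or
    # other bursts (within the 6-s baseline window)
    if (in_busy(t0 - 2, d + 4)) next
    if (nrow(placed) && any(t0 - 4 < placed$end_s & placed$start_s < t0 + d + 4)) next
    placed <- rbind(placed, data.frame(start_s = t0, end_s = t0 + d))
    a <- stats::runif(1, cfg$fetal$amplitude_range[1], cfg$fetal$amplitude_range[2])
    car <- stats::runif(1, 0.8, 2.2); ph <- stats::runif(1, 0, 2 * pi)
    fm <- render_burst(fm, fs, t0, d, a, car, ph)
    truth[[length(truth) + 1L]] <- truth_row("fetal_burst", "FM", t0, t0 + d)
  }

  # ---- maternal heartbeat: contiguous biphasic beat cycles ---------------
  hb <- cfg$heartbeat
  if (hb$amplitude > 0) {
    t <- 0
    period0 <- 1 / hb$frequency_hz
    while (t < total) {
      p <- period0 + stats::runif(1, -hb$jitter_s, hb$jitter_s)
      fm <- render_biphasic(fm, fs, t, p, hb$amplitude)
      mm <- render_biphasic(mm, fs, t, p, hb$amplitude / cfg$fm_mm_gain)
      t <- t + p
    }
    truth[[length(truth) + 1L]] <- truth_row("heartbeat", "both", 0, total)
  }

  # ---- maternal respiration (FM only): slow quasi-sinusoid + REM
  # transients at 3-5 s breath intervals in the final third of the night ---
  rs <- cfg$respiration
  if (rs$slow_amplitude > 0 || rs$transient_amplitude_range[2] > 0) {
    rem_start <- total * (1 - rs$rem_fraction_of_last_third / 3)
    t <- 0
    while (t < total) {
      p <- stats::runif(1, rs$period_range_s[1], rs$period_range_s[2])
      if (rs$slow_amplitude > 0) {
        fm <- render_biphasic(fm, fs, t, p, rs$slow_amplitude)
      }
      if (t >= rem_start && rs$transient_amplitude_range[2] > 0) {
        a <- stats::runif(1, rs$transient_amplitude_range[1],
                          rs$transient_amplitude_range[2])
        fm <- render_biphasic(fm, fs, t, rs$transient_duration_s, a)
        truth[[length(truth) + 1L]] <- truth_row("respiration", "FM", t,
                                                 t + rs$transient_duration_s)
      }
      t <- t + p
    }
  }

  # ---- noise floor -------------------------------------------------------
  if (cfg$noise_sd > 0) {
    fm <- fm + stats::rnorm(n, 0, cfg$noise_sd)
    mm <- mm + stats::rnorm(n, 0, cfg$noise_sd)
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    truth_row(character(0), character(0), numeric(0), numeric(0))
  truth <- truth[order(truth$start_s), , drop = FALSE]
  rownames(truth) <- NULL
  list(recording = fm_recording(fm, mm, fs, subject_id = sprintf("sim%03d", cfg$seed),
                                gestational_week = 30L),
       truth = truth)
}

#' Named scenario library
#'
#' Fixed-seed simulation configs spanning every artifact class:
#' `quiet_night` (bursts + heartbeat + noise, no REM respiration),
#' `rem_breathing` (REM-irregular respiration all night), `plm_sleeper`
#' (a periodic-limb-movement train), `hiccup_night` (one 5-15 min hiccup
#' bout), `restless_night` (wake + restroom + frequent maternal movement)
#' and `heartbeat_only`.
#'
#' @return Named list of `fm_simconfig` objects.
#' @export
scenario_library <- function() {
  list(
    quiet_night = sim_config(
      seed = 101L,
      respiration = list(transient_amplitude_range = c(0, 0)),
      maternal = list(rate_per_hour = 4),
      wake = list(n_episodes = 0)),
    rem_breathing = sim_config(
      seed = 102L,
      fetal = list(rate_per_hour = 60),
      respiration = list(rem_fraction_of_last_third = 3),  # whole night
      maternal = list(rate_per_hour = 4),
      wake = list(n_episodes = 0)),
    plm_sleeper = sim_config(
      seed = 103L,
      plm = list(n_runs = 2, run_length_range = c(5, 8)),
      wake = list(n_episodes = 0)),
    hiccup_night = sim_config(
      seed = 104L,
      hiccup = list(n_bouts = 1),
      wake = list(n_episodes = 0)),
    restless_night = sim_config(
      seed = 105L,
      maternal = list(rate_per_hour = 30),
      wake = list(n_episodes = 2),
      restroom = list(n_episodes = 1)),
    heartbeat_only = sim_config(
      seed = 106L,
      fetal = list(rate_per_hour = 0),
      respiration = list(slow_amplitude = 0, transient_amplitude_range = c(0, 0)),
      maternal = list(rate_per_hour = 0),
      wake = list(n_episodes = 0),
      heartbeat = list(jitter_s = 0),
      noise_sd = 0.2)
  )
}
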