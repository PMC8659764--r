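#' Describe a synthetic overnight recording
#'
#' A `night_scenario` fixes everything the generator randomizes: the
#' piecewise-constant heart- and breathing-rate profiles, the
#' sleep-disordered-breathing events to inject, per-minute arrhythmia
#' segments, the intended sleep stage per minute (which drives movement
#' bursts), noise levels and the seed. The generator's defaults emulate a
#' clean night on the device: HR 60 bpm, BR 15 breaths/min, SpO2 baseline
#' 97 %, PPG pulse of unit amplitude with a 40 % dicrotic notch, respiratory
#' amplitude/frequency/baseline modulations, additive Gaussian noise.
#'
#' @param duration_h Recording length, hours.
#' @param hr_bpm Either a single heart rate or a tibble `from_min`, `value`.
#' @param br_bpm Either a single breathing rate or a tibble `from_min`,
#'   `value` (piecewise-constant, breaths/min).
#' @param events Tibble of injected events: `type` in `CA`, `CH`, `OA`, `OH`,
#'   `control_dap`; `onset_s`; `duration_s`; optional `depth` (fractional
#'   amplitude decrease) and `desat_drop` (SpO2 points; 0 for none), which
#'   default by type (apnea 0.6/5, hypopnea 0.3/3, control 0.5/0). Events
#'   must not overlap.
#' @param arrhythmia Tibble `minute`, `kind` in `brady`, `tachy`, `af_like`,
#'   `pvc_like`: whole minutes with IPI 1300 ms, IPI 450 ms, intermittent
#'   +150 ms interval prolongations, or intermittent -150 ms premature
#'   intervals.
#' @param stage_profile Character vector of intended stages per minute
#'   (`"DS"`, `"LS"`, `"AW"`), recycled; drives accelerometer movement
#'   bursts (0, 2 and 8 bursts/min).
#' @param am_depth,fm_depth,bw_depth Respiratory modulation depths: pulse
#'   amplitude (fractional), pulse timing (fractional), baseline wander
#'   (fraction of pulse amplitude).
#' @param noise_sd PPG additive noise, fraction of pulse amplitude.
#' @param ppg_gain Integer device units per unit pulse amplitude; with the
#'   default modulations this keeps successive deltas inside signed 8 bits.
#' @param spo2_baseline Baseline saturation, percent.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `night_scenario`.
#' @export
night_scenario <- function(duration_h = 8, hr_bpm = 60, br_bpm = 15,
                           events = NULL, arrhythmia = NULL,
                           stage_profile = "DS",
                           am_depth = 0.25, fm_depth = 0.03, bw_depth = 0.15,
                           noise_sd = 0.01, ppg_gain = 800,
                           spo2_baseline = 97, seed = 1) {
  as_profile <- function(p) {
    if (is.data.frame(p)) tibble(from_min = p$from_min, value = p$value)
    else tibble(from_min = 0, value = p)
  }
  if (is.null(events)) {
    events <- tibble(type = character(), onset_s = numeric(),
                     duration_s = numeric(), depth = numeric(),
                     desat_drop = numeric())
  } else {
    events <- as_tibble(events)
    if (!"depth" %in% names(events)) events$depth <- NA_real_
    if (!"desat_drop" %in% names(events)) events$desat_drop <- NA_real_
    def_depth <- c(CA = 0.6, OA = 0.6, CH = 0.3, OH = 0.3, control_dap = 0.5)
    def_desat <- c(CA = 5, OA = 5, CH = 3, OH = 3, control_dap = 0)
    events$depth <- ifelse(is.na(events$depth), def_depth[events$type],
                           events$depth)
    events$desat_drop <- ifelse(is.na(events$desat_drop),
                                def_desat[events$type], events$desat_drop)
    ev <- events[order(events$onset_s), ]
    if (nrow(ev) > 1 &&
        any(ev$onset_s[-1] < (ev$onset_s + ev$duration_s)[-nrow(ev)])) {
      stop("injected events overlap", call. = FALSE)
    }
    if (any(ev$onset_s < 0 | ev$onset_s + ev$duration_s > duration_h * 3600)) {
      stop("event outside the recording", call. = FALSE)
    }
    events <- ev
  }
  if (is.null(arrhythmia)) {
    arrhythmia <- tibble(minute = integer(), kind = character())
  }
  n_min <- as.integer(duration_h * 60)
  structure(list(
    duration_h = duration_h,
    hr_bpm = as_profile(hr_bpm), br_bpm = as_profile(br_bpm),
    events = events, arrhythmia = as_tibble(arrhythmia),
    stage_profile = rep_len(stage_profile, n_min),
    am_depth = am_depth, fm_depth = fm_depth, bw_depth = bw_depth,
    noise_sd = noise_sd, ppg_gain = ppg_gain, spo2_baseline = spo2_baseline,
    seed = seed
  ), class = "night_scenario")
}

profile_at <- function(profile, t_min) {
  profile$value[findInterval(t_min, profile$from_min)]
}

#' Generate a synthetic overnight recording with its ground truth
#'
#' Builds the three device channels from a [night_scenario()]:
#'
#' * PPG at 100 Hz: a template pulse (systolic peak plus a dicrotic notch at
#'   40 % amplitude) placed at IPI-driven times, with respiratory amplitude,
#'   frequency and baseline-wander modulations at the breathing-rate profile.
#'   DAP events scale the amplitude by `1 - depth`; central events suspend
#'   the respiratory modulations (no breathing); obstructive events append a
#'   20 s post-event sympathetic surge (intervals shortened 15 %), the
#'   recoverable surrogate of the arousal that separates obstructive from
#'   central events.
#' * SpO2 at 1 Hz: baseline plus coupled desaturations lagged 5-15 s after
#'   the event onset.
#' * Accelerometer at 50 Hz (and the derived per-minute movement counts):
#'   sensor noise plus movement bursts according to the intended stage.
#'
#' All channels are integer-quantized to the 18-bit device range, so output
#' is platform-independent and byte-identical under a fixed seed.
#'
#' @param scenario A [night_scenario()].
#' @return A list of class `synthetic_night`: `stream` (a [sample_stream()]),
#'   `truth` (list: `minutes` tibble with intended per-minute stage, cardiac
#'   flags, true HR/BR; `events` tibble with subtypes; `pulse_times`), and
#'   `accel` (the raw 50 Hz accelerometer tibble).
#' @export
generate_night <- function(scenario) {
  stopifnot(inherits(scenario, "night_scenario"))
  set.seed(scenario$seed)
  fs <- 100
  dur_s <- scenario$duration_h * 3600
  n <- as.integer(dur_s * fs)
  n_min <- as.integer(scenario$duration_h * 60)

  ev <- scenario$events
  central <- ev[ev$type %in% c("CA", "CH"), , drop = FALSE]
  obstructive <- ev[ev$type %in% c("OA", "OH"), , drop = FALSE]

  in_any <- function(t, tab, pad_end = 0) {
    if (nrow(tab) == 0) return(rep(FALSE, length(t)))
    out <- rep(FALSE, length(t))
    for (i in seq_len(nrow(tab))) {
      out <- out | (t >= tab$onset_s[i] &
                      t < tab$onset_s[i] + tab$duration_s[i] + pad_end)
    }
    out
  }

  # ---- pulse times (interval domain) ----
  arr <- setNames(as.character(scenario$arrhythmia$kind),
                  scenario$arrhythmia$minute)
  pulse_t <- numeric(ceiling(dur_s / 0.3) + 2)
  k <- 0L; t <- 0; beat_in_min <- 0L; cur_min <- -1L
  while (t < dur_s) {
    k <- k + 1L
    pulse_t[k] <- t
    m <- floor(t / 60)
    if (m != cur_min) { cur_min <- m; beat_in_min <- 0L }
    beat_in_min <- beat_in_min + 1L
    kind <- arr[as.character(m)]
    base_ipi <- 60 / profile_at(scenario$hr_bpm, t / 60)
    ipi <- if (!is.na(kind) && kind == "brady") 1.3
    else if (!is.na(kind) && kind == "tachy") 0.45
    else base_ipi
    # respiratory frequency modulation, suspended while breathing is stopped
    # and in arrhythmic minutes (irregular rhythm, no respiratory sinus
    # arrhythmia)
    breathing <- !in_any(t, central) && is.na(kind)
    if (breathing) {
      br <- profile_at(scenario$br_bpm, t / 60)
      ipi <- ipi * (1 + scenario$fm_depth * sin(2 * pi * br / 60 * t))
    }
    if (!is.na(kind) && kind == "af_like" && beat_in_min %% 4L == 0L) {
      ipi <- ipi + 0.15
    }
    if (!is.na(kind) && kind == "pvc_like" && beat_in_min %% 8L == 0L) {
      ipi <- ipi - 0.15
    }
    # post-obstructive sympathetic surge: 20 s of shortened intervals
    if (nrow(obstructive) > 0) {
      after <- obstructive$onset_s + obstructive$duration_s
      if (any(t >= after & t < after + 20)) ipi <- ipi * 0.85
    }
    t <- t + ipi
  }
  pulse_t <- pulse_t[seq_len(k)]

  # ---- waveform (sample domain) ----
  t_all <- (seq_len(n) - 1) / fs
  beat <- findInterval(t_all, pulse_t)
  beat[beat < 1] <- 1L
  period <- c(diff(pulse_t), 60 / profile_at(scenario$hr_bpm, dur_s / 60))
  u <- (t_all - pulse_t[beat]) / period[beat]

  br_all <- profile_at(scenario$br_bpm, t_all / 60)
  breathing_all <- !in_any(t_all, central)
  amp_mod <- 1 + scenario$am_depth * sin(2 * pi * br_all / 60 * t_all)
  amp_mod[!breathing_all] <- 1
  dap_scale <- rep(1, n)
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      sel <- t_all >= ev$onset_s[i] & t_all < ev$onset_s[i] + ev$duration_s[i]
      dap_scale[sel] <- 1 - ev$depth[i]
    }
  }
  amp <- amp_mod * dap_scale
  shape <- exp(-((u - 0.28) / 0.075)^2 / 2) +
    0.4 * exp(-((u - 0.58) / 0.10)^2 / 2)
  bw <- scenario$bw_depth * sin(2 * pi * br_all / 60 * t_all + pi / 3)
  bw[!breathing_all] <- 0
  ppg_rel <- amp * shape + bw + stats::rnorm(n, sd = scenario$noise_sd)
  ppg <- as.integer(round(2^17 + scenario$ppg_gain * ppg_rel))
  ppg <- pmin(pmax(ppg, 0L), 262143L)

  # ---- SpO2 (1 Hz) ----
  t_sec <- seq_len(floor(dur_s)) - 1
  spo2 <- rep(scenario$spo2_baseline, length(t_sec)) +
    round(stats::rnorm(length(t_sec), sd = 0.4))
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      if (ev$desat_drop[i] <= 0) next
      # desaturation follows the event with a short circulatory lag; the
      # drop reaches criterion depth within the physiologic 20 s of the
      # event onset
      lag <- stats::runif(1, 5, 10)
      d0 <- ev$onset_s[i] + lag
      dN <- d0 + max(ev$duration_s[i], 15)
      ramp <- 6
      prof <- pmin(
        pmax(0, (t_sec - d0) / ramp),        # descend
        1,
        pmax(0, (dN + ramp - t_sec) / ramp)  # recover
      )
      spo2 <- spo2 - round(ev$desat_drop[i] * pmax(0, prof))
    }
  }
  spo2 <- pmin(pmax(as.integer(spo2), 60L), 100L)
  spo2_tab <- tibble(sample_idx = as.integer(t_sec * fs), percent = spo2)

  # ---- accelerometer (50 Hz) and movement counts ----
  fa <- 50
  na <- as.integer(dur_s * fa)
  ax <- stats::rnorm(na, sd = 0.01)
  ay <- stats::rnorm(na, sd = 0.01)
  az <- 1 + stats::rnorm(na, sd = 0.01)
  bursts_per_min <- c(DS = 0L, LS = 2L, AW = 8L)[scenario$stage_profile]
  for (m in seq_len(n_min) - 1) {
    nb <- bursts_per_min[m + 1]
    if (is.na(nb) || nb == 0) next
    at <- sort(stats::runif(nb, m * 60 + 1, (m + 1) * 60 - 2))
    for (b in at) {
      i0 <- as.integer(b * fa)
      len <- as.integer(stats::runif(1, 0.2, 0.6) * fa)
      step <- stats::runif(3, 0.5, 1.2) * sample(c(-1, 1), 3, replace = TRUE)
      sel <- i0:min(i0 + len, na)
      ax[sel] <- ax[sel] + step[1]
      ay[sel] <- ay[sel] + step[2]
      az[sel] <- az[sel] + step[3]
    }
  }
  accel <- tibble(x = round(ax, 3), y = round(ay, 3), z = round(az, 3))
  counts <- movement_counts(accel, fs = fa, n_minutes = n_min)
  move_tab <- tibble(
    sample_idx = pmin(as.integer((counts$minute_index + 1) * 60 * fs) - 1L,
                      n - 1L),
    count = counts$n_movements
  )

  stream <- sample_stream(ppg, spo2 = spo2_tab, movements = move_tab, fs = fs)

  # ---- ground truth ----
  minute_of <- function(kind) {
    out <- rep(FALSE, n_min)
    sel <- scenario$arrhythmia$minute[scenario$arrhythmia$kind == kind]
    out[sel + 1] <- TRUE
    out
  }
  mid_min <- (seq_len(n_min) - 0.5)
  apneic_min <- rep(FALSE, n_min)
  ap_ev <- ev[ev$type != "control_dap", , drop = FALSE]
  if (nrow(ap_ev) > 0) {
    for (i in seq_len(nrow(ap_ev))) {
      m0 <- floor(ap_ev$onset_s[i] / 60)
      m1 <- floor((ap_ev$onset_s[i] + ap_ev$duration_s[i]) / 60)
      apneic_min[seq.int(m0, min(m1, n_min - 1)) + 1] <- TRUE
    }
  }
  truth_min <- tibble(
    minute_index = seq_len(n_min) - 1,
    stage = scenario$stage_profile,
    hr_bpm = profile_at(scenario$hr_bpm, mid_min),
    br_bpm = profile_at(scenario$br_bpm, mid_min),
    is_brady = minute_of("brady"), is_tachy = minute_of("tachy"),
    is_af = minute_of("af_like"), is_pvc = minute_of("pvc_like"),
    is_apnea = apneic_min,
    n_movements = counts$n_movements
  )
  truth_min$hr_bpm[truth_min$is_brady] <- 60 / 1.3
  truth_min$hr_bpm[truth_min$is_tachy] <- 60 / 0.45

  structure(list(
    stream = stream,
    truth = list(minutes = truth_min,
                 events = dplyr::rename(ev, subtype = "type"),
                 pulse_times = pulse_t),
    accel = accel
  ), class = "synthetic_night")
}

#' @export
print.synthetic_night <- function(x, ...) {
  cat(sprintf(
    "<synthetic_night> %.1f h, %d injected events, %d arrhythmic minutes\n",
    length(x$stream$ppg) / x$stream$fs / 3600, nrow(x$truth$events),
    sum(x$truth$minutes$is_brady | x$truth$minutes$is_tachy |
          x$truth$minutes$is_af | x$truth$minutes$is_pvc)))
  invisible(x)
}
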