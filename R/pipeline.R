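#' Run the full overnight analysis
#'
#' Decode (if needed), then execute the six analyses in the platform's order
#' -- heart-rate estimation, bradycardia/tachycardia detection, AF/PVC
#' detection, breathing-rate estimation, apnea/hypopnea detection (and
#' subtype classification when models are supplied), sleep staging -- and
#' assemble the two report tables: the per-minute `SleepEvents` table and the
#' one-row `NightSleepSummary`. Minutes falling in corrupted or garbage
#' segments propagate as null rows; re-running on the same input yields
#' identical outputs.
#'
#' @param input A [sample_stream()], a path to a `.bin` file from
#'   [write_bin()], or a path to a signals CSV in the [stream_to_table()]
#'   dialect.
#' @param config A [sleepglove_config()].
#' @param models Optional list of `sdb_svm` models (e.g. from
#'   [pairwise_subtype_models()]) used to label apneic events; without them
#'   `ApneaType` is reported as `"unclassified"` for apneic minutes.
#' @param out_dir Optional output directory; when given, writes
#'   `sleep_events.csv`, `night_summary.csv`, `events.csv` and `report.json`
#'   atomically (temp file + rename) and a plain-text run log.
#' @return A list of class `sleepglove_night`: `sleep_events` (tibble, one
#'   row per minute, Table-style field names), `night_summary` (one-row
#'   tibble), `events` (labeled DAP table), `stages`, `br_windows`, `pulses`,
#'   `stream`, `timings` (per-stage seconds).
#' @export
run_night <- function(input, config = sleepglove_config(), models = NULL,
                      out_dir = NULL) {
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, s = proc.time()[["elapsed"]] - t0)
  }
  timings <- list()

  # ---- decode ----
  dec <- t_stage({
    if (inherits(input, "sample_stream")) {
      input
    } else if (is.character(input) && grepl("\\.bin$", input)) {
      decode_file(read_bin(input))
    } else if (is.character(input)) {
      table_to_stream(utils::read.csv(input))
    } else {
      stop("undecodable input: expected sample_stream, .bin or CSV path",
           call. = FALSE)
    }
  })
  stream <- dec$val
  timings$decode <- dec$s
  fs <- stream$fs
  rec_len_s <- length(stream$ppg) / fs
  n_minutes <- as.integer(ceiling(rec_len_s / 60))
  if (n_minutes < 10) {
    stop("input decodes to fewer than 10 minutes of signal", call. = FALSE)
  }

  ppg <- as.numeric(stream$ppg)
  if (!is.null(stream$valid)) ppg[!stream$valid] <- NA

  # ---- heart ----
  hr <- t_stage({
    z <- zscore_normalize(ppg)
    pulses <- detect_pulses(z, fs = fs, thresholds = config$heart)
    labels <- minute_cardiac_labels(pulses, n_minutes = n_minutes,
                                    thresholds = config$heart)
    list(pulses = pulses, labels = labels, z = z)
  })
  pulses <- hr$val$pulses
  cardiac <- hr$val$labels
  timings$heart <- hr$s

  # ---- respiration ----
  br <- t_stage({
    mods <- extract_modulations(ppg, pulses, fs = fs,
                                config = config$respiration)
    wins <- estimate_br(mods, window_len_s = config$respiration_window_s,
                        config = config$respiration)
    list(windows = wins,
         minutes = minute_breathing_rate(wins, n_minutes))
  })
  timings$respiration <- br$s

  # ---- sdb ----
  spo2_tab <- tibble(
    time_s = stream$spo2$sample_idx / fs,
    percent = if ("percent" %in% names(stream$spo2)) stream$spo2$percent
    else stream$spo2$value
  )
  sdb <- t_stage({
    env <- amplitude_envelope(ppg, pulses, fs = fs, config = config$sdb)
    daps <- detect_dap(env, config = config$sdb)
    desats <- detect_desaturation(spo2_tab, config = config$sdb)
    daps <- couple_dap_desat(daps, desats, config = config$sdb)
    daps$subtype <- NA_character_
    ap <- which(daps$label == "apneic_hypopneic")
    if (length(ap) > 0 && !is.null(models)) {
      feats <- sdb_feature_table(pulses, env, spo2_tab, daps[ap, ])
      if (nrow(feats) > 0) {
        usable <- match(feats$onset_s, daps$onset_s)
        m <- models$C_O
        if (!is.null(m)) {
          daps$subtype[usable] <- as.character(classify_events(m, feats))
        }
      }
    }
    minute_flags <- minute_apnea_labels(daps, rec_len_s)
    list(env = env, daps = daps, desats = desats, minutes = minute_flags)
  })
  timings$sdb <- sdb$s

  # ---- stages ----
  st <- t_stage({
    counts <- tibble(
      minute_index = seq_len(n_minutes) - 1,
      n_movements = {
        v <- rep(0L, n_minutes)
        m <- floor(stream$movements$sample_idx / fs / 60)
        val <- if ("count" %in% names(stream$movements))
          stream$movements$count else stream$movements$value
        v[m + 1] <- val
        v
      }
    )
    classify_stages(counts, sd_estimator = config$stages$sd_estimator)
  })
  stages <- st$val
  timings$stages <- st$s

  # ---- assemble report tables ----
  spo2_min <- spo2_tab |>
    dplyr::mutate(minute_index = floor(.data$time_s / 60)) |>
    dplyr::group_by(.data$minute_index) |>
    dplyr::summarise(spo2 = mean(.data$percent, na.rm = TRUE),
                     .groups = "drop")

  apnea_min <- sdb$val$minutes$minutes
  sleep_events <- tibble(
    UserId = stream$user_id,
    EventStartDate = stream$start_time + (seq_len(n_minutes) - 1) * 60,
    HeartRate = cardiac$mean_hr_bpm,
    BreathingRate = br$val$minutes$mean_br_bpm,
    OxygenSaturation = spo2_min$spo2[match(seq_len(n_minutes) - 1,
                                           spo2_min$minute_index)],
    IsApnea = apnea_min$is_apnea[seq_len(n_minutes)],
    ApneaType = minute_apnea_type(sdb$val$daps, n_minutes),
    IsPrematureVentricularContraction = cardiac$is_pvc,
    IsAtrialFibrillation = cardiac$is_af,
    IsBradycardia = cardiac$is_brady,
    IsTachycardia = cardiac$is_tachy
  )

  ssum <- stage_summary(stages)
  night_summary <- tibble(
    UserId = stream$user_id,
    UpNEAId = stream$device_id,
    EventStartDate = stream$start_time,
    EventEndDate = stream$start_time + rec_len_s,
    LightSleepDuration = ssum$LightSleepDuration,
    DeepSleepDuration = ssum$DeepSleepDuration,
    SleepDuration = ssum$SleepDuration,
    WakeUpsCounter = ssum$WakeUpsCounter,
    ApneaCounter = sdb$val$minutes$n_events,
    MeanHeartRate = mean(sleep_events$HeartRate, na.rm = TRUE),
    MeanBreathingRate = mean(sleep_events$BreathingRate, na.rm = TRUE),
    MeanOxygenSaturation = mean(sleep_events$OxygenSaturation, na.rm = TRUE),
    PrematureVentricularContractionCounter =
      sum(sleep_events$IsPrematureVentricularContraction, na.rm = TRUE),
    AtrialFibrillationCounter =
      sum(sleep_events$IsAtrialFibrillation, na.rm = TRUE),
    BradycardiaCounter = sum(sleep_events$IsBradycardia, na.rm = TRUE),
    TachycardiaCounter = sum(sleep_events$IsTachycardia, na.rm = TRUE)
  )

  out <- structure(list(
    sleep_events = sleep_events, night_summary = night_summary,
    events = sdb$val$daps, desaturations = sdb$val$desats, stages = stages,
    br_windows = br$val$windows, pulses = pulses, stream = stream,
    ahi = sdb$val$minutes$ahi,
    apnea_minute_count = sum(apnea_min$is_apnea),
    timings = timings
  ), class = "sleepglove_night")

  if (!is.null(out_dir)) write_night_outputs(out, out_dir)
  out
}

# ApneaType per minute: subtype of the apneic event overlapping the minute
# ("unclassified" when no model labeled it), NA for clear minutes.
minute_apnea_type <- function(daps, n_minutes) {
  out <- rep(NA_character_, n_minutes)
  ap <- daps[daps$label == "apneic_hypopneic", , drop = FALSE]
  if (nrow(ap) == 0) return(out)
  for (i in seq_len(nrow(ap))) {
    m0 <- floor(ap$onset_s[i] / 60)
    m1 <- min(floor((ap$onset_s[i] + ap$duration_s[i]) / 60), n_minutes - 1)
    lab <- ap$subtype[i]
    out[seq.int(m0, m1) + 1] <- if (is.na(lab)) "unclassified" else lab
  }
  out
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write the report files of an analyzed night
#'
#' @param night A `sleepglove_night` from [run_night()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_night_outputs <- function(night, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_atomic(function(p) utils::write.csv(night$sleep_events, p,
                                            row.names = FALSE),
               file.path(out_dir, "sleep_events.csv"))
  write_atomic(function(p) utils::write.csv(night$night_summary, p,
                                            row.names = FALSE),
               file.path(out_dir, "night_summary.csv"))
  write_atomic(function(p) utils::write.csv(night$events, p,
                                            row.names = FALSE),
               file.path(out_dir, "events.csv"))
  report <- list(
    night_summary = as.list(night$night_summary),
    ahi = night$ahi,
    apnea_minute_count = night$apnea_minute_count,
    n_events = nrow(night$events),
    timings_s = night$timings
  )
  write_atomic(function(p) jsonlite::write_json(report, p, auto_unbox = TRUE,
                                                digits = NA, POSIXt = "ISO8601"),
               file.path(out_dir, "report.json"))
  log_lines <- c(
    sprintf("sleepglove run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                        tz = "UTC")),
    sprintf("stage %-12s %8.2f s", names(night$timings),
            unlist(night$timings))
  )
  write_atomic(function(p) writeLines(log_lines, p),
               file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.sleepglove_night <- function(x, ...) {
  s <- x$night_summary
  cat(sprintf(
    paste0("<sleepglove_night> %d min | HR %.1f bpm | BR %.1f /min | SpO2 ",
           "%.1f%% | apneic events %d (AHI %.1f) | brady/tachy/AF/PVC minutes ",
           "%d/%d/%d/%d | LS/DS/AW %d/%d/%d min\n"),
    s$SleepDuration, s$MeanHeartRate, s$MeanBreathingRate,
    s$MeanOxygenSaturation, s$ApneaCounter, x$ahi,
    s$BradycardiaCounter, s$TachycardiaCounter, s$AtrialFibrillationCounter,
    s$PrematureVentricularContractionCounter,
    s$LightSleepDuration, s$DeepSleepDuration,
    s$SleepDuration - s$LightSleepDuration - s$DeepSleepDuration))
  invisible(x)
}
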