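#' Movement derivative of consecutive accelerometer samples
#'
#' Every sampling step (nominally 20 ms at 50 Hz) the absolute axis-wise
#' differences are summed and divided by the step: `D = (|dx| + |dy| + |dz|) /
#' delta`. A movement is registered when `D` crosses the movement threshold.
#' The absolute values make the magnitude non-negative and invariant to axis
#' permutation and sign flips.
#'
#' @param accel A data frame/tibble with numeric columns `x`, `y`, `z`
#'   (device units), uniformly sampled.
#' @param delta_s Sampling interval, seconds (0.02 at 50 Hz).
#' @return Numeric vector of length `nrow(accel) - 1`, units/s.
#' @export
movement_derivative <- function(accel, delta_s = 0.02) {
  stopifnot(delta_s > 0, nrow(accel) >= 2)
  (abs(diff(accel$x)) + abs(diff(accel$y)) + abs(diff(accel$z))) / delta_s
}

#' Per-minute movement counts from raw accelerometry
#'
#' Counts upward threshold crossings (rising edges) of the movement
#' derivative in each minute: a sustained excursion above threshold counts
#' once, not once per sample. The threshold is hardware-dependent; the
#' default of 25 units/s is calibrated so that bursts with per-axis steps of
#' at least 0.5 device units register while sensor noise (s.d. ~0.01 units)
#' does not.
#'
#' @inheritParams movement_derivative
#' @param fs Accelerometer sampling rate, Hz.
#' @param threshold Movement threshold, units/s.
#' @param n_minutes Recording length in minutes; defaults to covering the
#'   samples provided.
#' @return A tibble `minute_index`, `n_movements`.
#' @export
movement_counts <- function(accel, fs = 50, threshold = 25,
                            n_minutes = NULL) {
  d <- movement_derivative(accel, delta_s = 1 / fs)
  above <- d > threshold
  rising <- which(above & !c(FALSE, above[-length(above)]))
  t_s <- rising / fs
  if (is.null(n_minutes)) n_minutes <- ceiling(nrow(accel) / fs / 60)
  counts <- tabulate(floor(t_s / 60) + 1, nbins = n_minutes)
  tibble(minute_index = seq_len(n_minutes) - 1, n_movements = counts)
}

#' Classify sleep stages from per-minute movement counts
#'
#' Whole-night thresholding: with `mN` and `sN` the night mean and standard
#' deviation of the per-minute counts (computed only after the recording
#' ends), minute `j` is Awake when `N_j > mN + 3 sN`, Light Sleep when `N_j >
#' mN + sN`, otherwise Deep Sleep. Inequalities are strict, so a night of
#' identical counts (s.d. 0) is all Deep Sleep. Labels are invariant under
#' positive scaling of all counts, since the thresholds scale along.
#'
#' @param counts Integer vector of per-minute movement counts, or the tibble
#'   from [movement_counts()].
#' @param sd_estimator `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @return A tibble `minute_index`, `n_movements`, `stage` (factor with
#'   levels `DS`, `LS`, `AW`).
#' @export
classify_stages <- function(counts, sd_estimator = c("sample", "population")) {
  sd_estimator <- match.arg(sd_estimator)
  if (is.data.frame(counts)) {
    n <- counts$n_movements
    idx <- counts$minute_index
  } else {
    n <- as.numeric(counts)
    idx <- seq_along(n) - 1
  }
  stopifnot(length(n) >= 2, all(n >= 0))
  mN <- mean(n)
  sN <- sd(n)
  if (sd_estimator == "population") sN <- sN * sqrt((length(n) - 1) / length(n))
  stage <- ifelse(n > mN + 3 * sN, "AW", ifelse(n > mN + sN, "LS", "DS"))
  tibble(minute_index = idx, n_movements = n,
         stage = factor(stage, levels = c("DS", "LS", "AW")))
}

#' Night stage-duration summary
#'
#' Stage totals in minutes plus the wake-ups counter, defined as the number
#' of maximal runs of Awake minutes.
#'
#' @param stages Tibble from [classify_stages()].
#' @return A one-row tibble: `LightSleepDuration`, `DeepSleepDuration`,
#'   `AwakeDuration`, `SleepDuration` (total minutes), `WakeUpsCounter`.
#' @export
stage_summary <- function(stages) {
  r <- rle(as.character(stages$stage))
  tibble(
    LightSleepDuration = sum(stages$stage == "LS"),
    DeepSleepDuration = sum(stages$stage == "DS"),
    AwakeDuration = sum(stages$stage == "AW"),
    SleepDuration = nrow(stages),
    WakeUpsCounter = sum(r$values == "AW")
  )
}
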