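#' Default detection thresholds for cardiac analytics
#'
#' Bradycardia is a one-minute window whose average inter-pulse interval
#' exceeds 1200 ms (HR < 50 bpm); tachycardia one whose average does not
#' exceed 500 ms (HR > 120 bpm). Irregularity flags use the 50 ms
#' deviation-from-mean rule. The pulse-detector prominence is empirical (the
#' device papers fix it on their own database without printing a value): 0.8
#' on the z-scored signal suppresses dicrotic notches up to half the pulse
#' amplitude, with a 300 ms refractory period.
#'
#' @param brady_ibi_ms,tachy_ibi_ms Interval thresholds in ms.
#' @param af_pvc_delta_ms Deviation from the minute mean (ms) that flags a
#'   possible atrial-fibrillation (above) or premature-ventricular-contraction
#'   (below) interval.
#' @param min_prominence Minimum topographic peak prominence on the z-scored
#'   PPG (adimensional).
#' @param refractory_ms Minimum spacing between detected pulses.
#' @param episode_rule `"mean"` (default: the minute's average interval
#'   crosses the threshold) or `"any"` (any single interval does).
#' @param af_pvc_rule `"mean"` (deviation from the minute mean, default) or
#'   `"successive"` (difference between consecutive intervals).
#' @param ectopic_tol Fractional deviation from the running median of 5 that
#'   masks an interval as ectopic.
#' @return A list of class `detection_thresholds`.
#' @export
detection_thresholds <- function(brady_ibi_ms = 1200, tachy_ibi_ms = 500,
                                 af_pvc_delta_ms = 50, min_prominence = 0.8,
                                 refractory_ms = 300,
                                 episode_rule = c("mean", "any"),
                                 af_pvc_rule = c("mean", "successive"),
                                 ectopic_tol = 0.3) {
  stopifnot(brady_ibi_ms > tachy_ibi_ms, tachy_ibi_ms > 0, af_pvc_delta_ms > 0)
  structure(
    list(
      brady_ibi_ms = brady_ibi_ms, tachy_ibi_ms = tachy_ibi_ms,
      af_pvc_delta_ms = af_pvc_delta_ms, min_prominence = min_prominence,
      refractory_ms = refractory_ms, episode_rule = match.arg(episode_rule),
      af_pvc_rule = match.arg(af_pvc_rule), ectopic_tol = ectopic_tol
    ),
    class = "detection_thresholds"
  )
}

#' Z-score normalize a signal
#'
#' Removes the mean and divides by the (sample) standard deviation, the
#' standing first step before pulse detection so the prominence threshold is
#' amplitude-scale free.
#'
#' @param x Numeric vector, length at least 2, non-constant; `NA`s are
#'   ignored for the moments and propagated.
#' @return Numeric vector with mean 0 and standard deviation 1.
#' @export
zscore_normalize <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("constant signal has no z-score", call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / s
}

#' Detect pulses in a normalized PPG signal
#'
#' Local maxima with a minimum topographic prominence, thinned with a
#' refractory period so the dicrotic notch within a pulse is never counted as
#' a second pulse. Samples flagged invalid (artifact/garbage segments) split
#' the signal; pulse pairs straddling an invalid stretch produce no interval.
#'
#' @param ppg Z-scored PPG samples (`NA` allowed over invalid stretches).
#' @param fs Sampling frequency, Hz.
#' @param thresholds A [detection_thresholds()].
#' @return A list of class `pulse_series`: `pulse_times` (seconds, strictly
#'   increasing), `ipi` tibble with `t_s` (time of the interval's starting
#'   pulse), `ipi_ms`, and `valid` (FALSE where the interval bridges an
#'   invalid gap or is implausible, outside `[300, 2000]` ms).
#' @export
detect_pulses <- function(ppg, fs = 100, thresholds = detection_thresholds()) {
  x <- ppg
  nas <- is.na(x)
  x[nas] <- -1e9 # never a peak, never raises a neighbour's prominence
  idx <- cpp_find_peaks(x, thresholds$min_prominence,
                        as.integer(round(thresholds$refractory_ms / 1000 * fs)))
  # sub-sample refinement: parabola through the peak and its neighbours,
  # otherwise intervals carry +/- one-sample quantization jitter
  frac <- rep(0, length(idx))
  inner <- idx > 1 & idx < length(x)
  if (any(inner)) {
    i <- idx[inner]
    denom <- x[i - 1] - 2 * x[i] + x[i + 1]
    f <- ifelse(abs(denom) > 1e-12, 0.5 * (x[i - 1] - x[i + 1]) / denom, 0)
    frac[inner] <- pmin(pmax(f, -0.5), 0.5)
  }
  pulse_times <- (idx - 1 + frac) / fs
  if (length(idx) < 2) {
    return(structure(list(
      pulse_times = pulse_times,
      ipi = tibble(t_s = numeric(), ipi_ms = numeric(), valid = logical()),
      fs = fs
    ), class = "pulse_series"))
  }
  ipi_ms <- diff(pulse_times) * 1000
  # an interval is untrustworthy if any sample between its pulses is invalid
  bridge <- vapply(seq_len(length(idx) - 1), function(k) {
    any(nas[idx[k]:idx[k + 1]])
  }, logical(1))
  valid <- !bridge & ipi_ms >= 300 & ipi_ms <= 2000
  structure(list(
    pulse_times = pulse_times,
    ipi = tibble(t_s = pulse_times[-length(pulse_times)], ipi_ms = ipi_ms,
                 valid = valid),
    fs = fs
  ), class = "pulse_series")
}

#' @export
print.pulse_series <- function(x, ...) {
  cat(sprintf("<pulse_series> %d pulses, %d intervals (%d valid)\n",
              length(x$pulse_times), nrow(x$ipi), sum(x$ipi$valid)))
  invisible(x)
}

#' Mask and interpolate ectopic intervals
#'
#' Intervals deviating more than `tol` (fraction) from the running median of
#' five are masked as ectopic and replaced by linear interpolation *for
#' heart-rate averaging only*; the raw intervals are preserved for the
#' irregularity rules, which must see the ectopy.
#'
#' @param ipi_ms Numeric vector of inter-pulse intervals, ms (at least 3).
#' @param tol Fractional deviation threshold (default 0.3).
#' @return A tibble with `ipi_ms` (raw), `ipi_clean_ms` (interpolated where
#'   masked) and `ectopic` (logical mask); the masked fraction is attached as
#'   attribute `mask_fraction`.
#' @export
clean_ectopic <- function(ipi_ms, tol = 0.3) {
  n <- length(ipi_ms)
  if (n < 3) {
    return(structure(tibble(ipi_ms = ipi_ms, ipi_clean_ms = ipi_ms,
                            ectopic = rep(FALSE, n)), mask_fraction = 0))
  }
  med <- stats::runmed(ipi_ms, k = min(5L, n - (n %% 2 == 0)), endrule = "median")
  ect <- abs(ipi_ms - med) > tol * med
  clean <- ipi_ms
  if (any(ect)) {
    if (all(ect)) {
      clean[] <- med
    } else {
      clean[ect] <- approx(which(!ect), ipi_ms[!ect], xout = which(ect),
                           rule = 2)$y
    }
  }
  structure(tibble(ipi_ms = ipi_ms, ipi_clean_ms = clean, ectopic = ect),
            mask_fraction = mean(ect))
}

#' Flag bradycardic / tachycardic minutes from interval series
#'
#' Under the default `episode_rule = "mean"`, a minute is bradycardic when
#' its average inter-pulse interval exceeds `brady_ibi_ms` and tachycardic
#' when the average is below `tachy_ibi_ms` (strict inequalities); with
#' `"any"`, a single interval crossing the threshold suffices.
#'
#' @param ipi_ms Intervals falling in the minute (ectopy-cleaned for the
#'   averaging).
#' @param thresholds A [detection_thresholds()].
#' @return A list `(is_brady, is_tachy)`; both `NA` when fewer than 1
#'   interval is available.
#' @export
label_brady_tachy <- function(ipi_ms, thresholds = detection_thresholds()) {
  ipi_ms <- ipi_ms[!is.na(ipi_ms)]
  if (length(ipi_ms) < 1) return(list(is_brady = NA, is_tachy = NA))
  if (thresholds$episode_rule == "mean") {
    m <- mean(ipi_ms)
    list(is_brady = m > thresholds$brady_ibi_ms,
         is_tachy = m < thresholds$tachy_ibi_ms)
  } else {
    list(is_brady = any(ipi_ms > thresholds$brady_ibi_ms),
         is_tachy = any(ipi_ms < thresholds$tachy_ibi_ms))
  }
}

#' Flag possible atrial fibrillation / premature ventricular contraction
#'
#' Over one minute of *raw* intervals, the mean interval defines an average
#' threshold; an interval more than `af_pvc_delta_ms` above it marks possible
#' AF (a sudden lengthening of the pulse-to-pulse time), one more than the
#' same margin below marks a possible PVC (the premature beat arrives early).
#' One detection suffices to label the minute. Inequalities are strict:
#' an interval at exactly mean +/- 50 ms is not a detection.
#'
#' @param ipi_ms Raw intervals within the minute (at least 4).
#' @param thresholds A [detection_thresholds()].
#' @return A list `(is_af, is_pvc)`; both `NA` with fewer than 4 intervals.
#' @export
detect_af_pvc <- function(ipi_ms, thresholds = detection_thresholds()) {
  ipi_ms <- ipi_ms[!is.na(ipi_ms)]
  if (length(ipi_ms) < 4) return(list(is_af = NA, is_pvc = NA))
  d <- thresholds$af_pvc_delta_ms
  if (thresholds$af_pvc_rule == "mean") {
    m <- mean(ipi_ms)
    list(is_af = any(ipi_ms > m + d), is_pvc = any(ipi_ms < m - d))
  } else {
    dif <- diff(ipi_ms)
    list(is_af = any(dif > d), is_pvc = any(dif < -d))
  }
}

#' Per-minute cardiac labels for a pulse series
#'
#' Chops the night into one-minute segments and labels each with its mean
#' heart rate and the bradycardia/tachycardia/AF/PVC flags. Heart rate uses
#' ectopy-cleaned intervals; the irregularity rules see the raw ones.
#' Minutes with fewer than 2 valid pulses are unanalyzable (`NA` row).
#'
#' @param pulses A [detect_pulses()] result.
#' @param n_minutes Total recording length in minutes (trailing empty minutes
#'   are reported as unanalyzable); default covers the last pulse.
#' @param thresholds A [detection_thresholds()].
#' @return A tibble with one row per minute: `minute_index` (0-based),
#'   `mean_hr_bpm`, `is_brady`, `is_tachy`, `is_af`, `is_pvc`,
#'   `n_intervals`.
#' @export
minute_cardiac_labels <- function(pulses, n_minutes = NULL,
                                  thresholds = detection_thresholds()) {
  stopifnot(inherits(pulses, "pulse_series"))
  if (is.null(n_minutes)) {
    n_minutes <- if (length(pulses$pulse_times))
      floor(max(pulses$pulse_times) / 60) + 1 else 0
  }
  iv <- dplyr::filter(pulses$ipi, .data$valid)
  cleaned <- clean_ectopic(iv$ipi_ms, tol = thresholds$ectopic_tol)
  iv$ipi_clean_ms <- cleaned$ipi_clean_ms
  iv$minute <- floor(iv$t_s / 60)
  purrr::map_dfr(seq_len(n_minutes) - 1, function(m) {
    seg <- iv[iv$minute == m, ]
    if (nrow(seg) < 1) {
      return(tibble(minute_index = m, mean_hr_bpm = NA_real_, is_brady = NA,
                    is_tachy = NA, is_af = NA, is_pvc = NA, n_intervals = 0L))
    }
    bt <- label_brady_tachy(seg$ipi_clean_ms, thresholds)
    ap <- detect_af_pvc(seg$ipi_ms, thresholds)
    tibble(
      minute_index = m,
      mean_hr_bpm = 60000 / mean(seg$ipi_clean_ms),
      is_brady = bt$is_brady, is_tachy = bt$is_tachy,
      is_af = ap$is_af, is_pvc = ap$is_pvc,
      n_intervals = nrow(seg)
    )
  })
}
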