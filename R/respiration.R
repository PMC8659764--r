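#' Respiration analysis parameters
#'
#' Breathing rate is read out of three respiratory modulations of the PPG --
#' baseline wander (intensity, RIIV), pulse amplitude (RIAV) and pulse timing
#' (frequency, RIFV) -- resampled to a common uniform grid, windowed, and
#' fused. Defaults: 4 Hz grid with cubic interpolation; Welch spectra (Hann
#' window, 50 % segment overlap); respiratory search band 4-60 breaths/min
#' (0.067-1 Hz); a window's modulation is used only when its spectral quality
#' (peak power / band power) clears `quality_floor`; the fused estimate comes
#' from a scalar random-walk Kalman smoother whose measurement variance
#' scales inversely with quality.
#'
#' @param grid_hz Uniform resampling rate for modulations.
#' @param band_bpm Respiratory search band in breaths/min.
#' @param quality_floor Minimum quality index in `[0, 1]`.
#' @param process_sd_bpm Random-walk process standard deviation per window
#'   step, breaths/min.
#' @param meas_sd_bpm Measurement standard deviation at quality 1.
#' @param baseline_cutoff_hz Low-pass cutoff isolating the intensity
#'   (baseline) modulation.
#' @return A list of class `respiration_config`.
#' @export
respiration_config <- function(grid_hz = 4, band_bpm = c(4, 60),
                               quality_floor = 0.2, process_sd_bpm = 0.5,
                               meas_sd_bpm = 2, baseline_cutoff_hz = 0.5) {
  structure(list(grid_hz = grid_hz, band_bpm = band_bpm,
                 quality_floor = quality_floor,
                 process_sd_bpm = process_sd_bpm, meas_sd_bpm = meas_sd_bpm,
                 baseline_cutoff_hz = baseline_cutoff_hz),
            class = "respiration_config")
}

#' Extract the three respiratory modulations of a PPG signal
#'
#' Per pulse, RIAV is the peak-to-trough amplitude (peak minus the minimum
#' since the previous peak) and RIFV the inter-pulse interval; RIIV is the
#' low-pass (< `baseline_cutoff_hz`) baseline of the PPG sampled at the pulse
#' times. All three are cubic-interpolated to the uniform grid.
#'
#' @param ppg Numeric PPG samples (raw or normalized; RIAV and RIFV are
#'   offset-invariant, RIIV is used only for its fluctuation).
#' @param pulses A [detect_pulses()] result on the same signal.
#' @param fs PPG sampling rate, Hz.
#' @param config A [respiration_config()].
#' @return A list of class `modulation_set`: `time_s` (the grid) and numeric
#'   series `riiv`, `riav`, `rifv` (ms), plus `grid_hz`.
#' @export
extract_modulations <- function(ppg, pulses, fs = 100,
                                config = respiration_config()) {
  pt <- pulses$pulse_times
  if (length(pt) < 2) stop("need at least 2 pulses", call. = FALSE)
  idx <- round(pt * fs) + 1

  # per-pulse peak-to-trough amplitude
  riav <- vapply(seq_along(idx), function(k) {
    lo <- if (k == 1) max(1, idx[k] - fs) else idx[k - 1]
    ppg[idx[k]] - min(ppg[lo:idx[k]], na.rm = TRUE)
  }, numeric(1))

  # interval series stamped at the later pulse of each pair
  rifv_t <- pt[-1]
  rifv <- diff(pt) * 1000

  # baseline: bin-average to the grid, then low-pass below the cutoff
  grid_dt <- 1 / config$grid_hz
  t_all <- (seq_along(ppg) - 1) / fs
  bins <- floor(t_all / grid_dt)
  base_coarse <- tapply(ppg, bins, mean, na.rm = TRUE)
  bt <- (as.numeric(names(base_coarse)) + 0.5) * grid_dt
  keep <- is.finite(base_coarse)
  bf <- signal::butter(2, config$baseline_cutoff_hz / (config$grid_hz / 2),
                       type = "low")
  base_f <- as.numeric(signal::filtfilt(bf, base_coarse[keep]))

  t_grid <- seq(min(pt), max(pt), by = grid_dt)
  interp <- function(x0, y0) {
    ok <- is.finite(y0)
    if (sum(ok) < 4) return(approx(x0[ok], y0[ok], xout = t_grid, rule = 2)$y)
    spline(x0[ok], y0[ok], xout = t_grid, method = "natural")$y
  }
  structure(list(
    time_s = t_grid,
    riiv = interp(bt[keep], base_f),
    riav = interp(pt, riav),
    rifv = interp(rifv_t, rifv),
    grid_hz = config$grid_hz
  ), class = "modulation_set")
}

# Welch power spectral density: Hann window, 50% overlap, zero-padded FFT.
# Returns freq (Hz) and power for positive frequencies.
welch_psd <- function(x, fs, seg_len = NULL, nfft = NULL) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- max(16, 2^floor(log2(n / 2)))
  seg_len <- min(seg_len, n)
  if (is.null(nfft)) nfft <- max(1024, 2^ceiling(log2(seg_len)))
  hop <- max(1, floor(seg_len / 2))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  starts <- seq(1, n - seg_len + 1, by = hop)
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(c(seg, numeric(nfft - seg_len))))^2
  }
  acc <- acc / length(starts)
  half <- seq_len(floor(nfft / 2))
  list(freq = (half - 1) * fs / nfft, power = acc[half])
}

#' Single-window breathing-rate estimates from the modulations
#'
#' For each modulation covering the window, the dominant Welch spectral peak
#' inside the respiratory band gives the breathing-rate reading; the quality
#' index is the fraction of in-band power concentrated around that peak
#' (+/- 1 bin either side). Qualities below the floor yield no reading.
#'
#' @param mods A [extract_modulations()] result.
#' @param window_start_s Window start, seconds.
#' @param window_len_s Window length, seconds (32 or 64 in the device
#'   protocol; any length >= 16 s is accepted).
#' @param config A [respiration_config()].
#' @return A one-row tibble: `window_start_s`, `window_len_s`, per-modulation
#'   `br_*_bpm` and `q_*` columns (`NA` below the quality floor), and
#'   `n_valid` (how many modulations passed).
#' @export
window_estimate <- function(mods, window_start_s, window_len_s = 64,
                            config = respiration_config()) {
  sel <- mods$time_s >= window_start_s &
    mods$time_s < window_start_s + window_len_s
  out <- tibble(window_start_s = window_start_s, window_len_s = window_len_s,
                br_riiv_bpm = NA_real_, q_riiv = NA_real_,
                br_riav_bpm = NA_real_, q_riav = NA_real_,
                br_rifv_bpm = NA_real_, q_rifv = NA_real_, n_valid = 0L)
  if (sum(sel) < window_len_s * mods$grid_hz * 0.9) return(out) # not covered
  band_hz <- config$band_bpm / 60
  for (m in c("riiv", "riav", "rifv")) {
    x <- mods[[m]][sel]
    if (!all(is.finite(x)) || sd(x) == 0) next
    ps <- welch_psd(x, mods$grid_hz)
    inband <- ps$freq >= band_hz[1] & ps$freq <= band_hz[2]
    if (!any(inband)) next
    fi <- ps$freq[inband]; pi_ <- ps$power[inband]
    pk <- which.max(pi_)
    # quality: concentration of in-band power around the dominant peak,
    # peak width taken as the Welch main-lobe (~ fs/seg_len either side)
    lobe <- mods$grid_hz / max(16, 2^floor(log2(sum(sel) / 2)))
    around <- abs(fi - fi[pk]) <= lobe
    q <- sum(pi_[around]) / sum(pi_)
    if (q >= config$quality_floor) {
      out[[paste0("br_", m, "_bpm")]] <- fi[pk] * 60
      out[[paste0("q_", m)]] <- q
      out$n_valid <- out$n_valid + 1L
    }
  }
  out
}

#' Fuse per-window modulation readings with a Kalman smoother
#'
#' Scalar random-walk state (the breathing rate), up to three measurements
#' per window step, measurement variance `meas_sd_bpm^2 / quality`; a forward
#' Kalman filter followed by a Rauch-Tung-Striebel backward pass. Windows
#' with no valid measurement are bridged by the process model.
#'
#' @param estimates Matrix/data frame of per-window readings (windows x
#'   modulations), breaths/min, `NA` where absent.
#' @param qualities Same shape, quality indices in `[0, 1]`.
#' @param config A [respiration_config()].
#' @return Numeric vector of fused breathing rates, one per window (`NA`
#'   where nothing was ever measurable).
#' @export
kalman_fuse <- function(estimates, qualities, config = respiration_config()) {
  z <- as.matrix(estimates)
  q <- as.matrix(qualities)
  n <- nrow(z)
  if (n == 0 || !any(is.finite(z))) return(rep(NA_real_, n))
  Q <- config$process_sd_bpm^2
  R0 <- config$meas_sd_bpm^2

  xf <- numeric(n); pf <- numeric(n)   # filtered
  xp <- numeric(n); pp <- numeric(n)   # predicted
  first <- which(apply(z, 1, function(r) any(is.finite(r))))[1]
  x <- NA_real_; p <- NA_real_
  for (t in seq_len(n)) {
    if (t < first) { xp[t] <- NA; pp[t] <- NA; xf[t] <- NA; pf[t] <- NA; next }
    if (t == first) {
      # diffuse start: initialise on the first window's best fusion
      zi <- z[t, ]; qi <- q[t, ]
      ok <- is.finite(zi) & is.finite(qi) & qi > 0
      w <- qi[ok] / sum(qi[ok])
      x <- sum(w * zi[ok]); p <- R0 / sum(qi[ok])
      xp[t] <- x; pp[t] <- p + Q; xf[t] <- x; pf[t] <- p
      next
    }
    x_pred <- x; p_pred <- p + Q
    xp[t] <- x_pred; pp[t] <- p_pred
    zi <- z[t, ]; qi <- q[t, ]
    ok <- is.finite(zi) & is.finite(qi) & qi > 0
    for (j in which(ok)) { # sequential scalar updates
      Rj <- R0 / qi[j]
      k <- p_pred / (p_pred + Rj)
      x_pred <- x_pred + k * (zi[j] - x_pred)
      p_pred <- (1 - k) * p_pred
    }
    x <- x_pred; p <- p_pred
    xf[t] <- x; pf[t] <- p
  }

  # RTS backward smoothing
  xs <- xf; ps <- pf
  if (n > first) {
    for (t in seq(n - 1, first)) {
      g <- pf[t] / pp[t + 1]
      xs[t] <- xf[t] + g * (xs[t + 1] - xp[t + 1])
      ps[t] <- pf[t] + g^2 * (ps[t + 1] - pp[t + 1])
    }
  }
  xs
}

#' Breathing-rate series for a whole recording
#'
#' Slides windows over the modulation set, estimates per-modulation rates and
#' qualities, fuses them with the Kalman smoother, and (optionally) averages
#' to one value per minute for the report tables.
#'
#' @param mods A [extract_modulations()] result.
#' @param window_len_s Window length, seconds.
#' @param hop_s Window hop; defaults to half the window.
#' @param config A [respiration_config()].
#' @return A tibble: one row per window with the per-modulation readings,
#'   qualities and `fused_br_bpm`.
#' @export
estimate_br <- function(mods, window_len_s = 64, hop_s = window_len_s / 2,
                        config = respiration_config()) {
  t0 <- min(mods$time_s); t1 <- max(mods$time_s)
  starts <- seq(t0, t1 - window_len_s, by = hop_s)
  if (length(starts) == 0) {
    return(tibble(window_start_s = numeric(), window_len_s = numeric(),
                  fused_br_bpm = numeric()))
  }
  wins <- purrr::map_dfr(starts, window_estimate, mods = mods,
                         window_len_s = window_len_s, config = config)
  est <- as.matrix(wins[, c("br_riiv_bpm", "br_riav_bpm", "br_rifv_bpm")])
  qual <- as.matrix(wins[, c("q_riiv", "q_riav", "q_rifv")])
  wins$fused_br_bpm <- kalman_fuse(est, qual, config)
  wins
}

#' Per-minute mean breathing rate
#'
#' Averages the fused window estimates whose centres fall in each minute.
#'
#' @param br_windows Output of [estimate_br()].
#' @param n_minutes Recording length in minutes.
#' @return A tibble `minute_index`, `mean_br_bpm`.
#' @export
minute_breathing_rate <- function(br_windows, n_minutes) {
  if (nrow(br_windows) == 0) {
    return(tibble(minute_index = seq_len(n_minutes) - 1, mean_br_bpm = NA_real_))
  }
  ctr <- br_windows$window_start_s + br_windows$window_len_s / 2
  m <- floor(ctr / 60)
  agg <- tibble(minute_index = m, br = br_windows$fused_br_bpm) |>
    dplyr::filter(is.finite(.data$br)) |>
    dplyr::group_by(.data$minute_index) |>
    dplyr::summarise(mean_br_bpm = mean(.data$br), .groups = "drop")
  tibble(minute_index = seq_len(n_minutes) - 1) |>
    dplyr::left_join(agg, by = "minute_index") |>
    tidyr::fill("mean_br_bpm", .direction = "downup")
}
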