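#' Plot an analyzed night
#'
#' The overnight report chart: per-minute heart rate, breathing rate and
#' oxygen saturation as time series, sleep stages as a background band, and
#' apneic minutes shaded.
#'
#' @param object A `sleepglove_night` from [run_night()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sleepglove_night <- function(object, ...) {
  se <- object$sleep_events
  df <- tibble(
    minute = seq_len(nrow(se)) - 1,
    HeartRate = se$HeartRate,
    BreathingRate = se$BreathingRate,
    OxygenSaturation = se$OxygenSaturation,
    stage = object$stages$stage,
    is_apnea = se$IsApnea
  ) |>
    tidyr::pivot_longer(c("HeartRate", "BreathingRate", "OxygenSaturation"),
                        names_to = "channel", values_to = "value")
  shade <- df |> dplyr::filter(.data$is_apnea)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$minute, y = .data$value)) +
    ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$minute - 0.5, xmax = .data$minute + 0.5),
      ymin = -Inf, ymax = Inf, fill = "gold", alpha = 0.4,
      inherit.aes = FALSE
    ) +
    ggplot2::geom_line(ggplot2::aes(color = .data$stage, group = 1),
                       linewidth = 0.4) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::scale_color_manual(
      values = c(DS = "#1f4e79", LS = "#5b9bd5", AW = "#d65f5f")
    ) +
    ggplot2::labs(x = "minute of night", y = NULL, color = "stage",
                  title = "Overnight report",
                  subtitle = "apneic minutes shaded") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the amplitude envelope and detected DAP events
#'
#' @param env Envelope tibble from [amplitude_envelope()].
#' @param daps Event tibble from [detect_dap()] (optionally labeled).
#' @param config An [sdb_config()] (for the detection threshold line).
#' @return A ggplot object.
#' @export
plot_dap_events <- function(env, daps, config = sdb_config()) {
  p <- ggplot2::ggplot(env, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$envelope), color = "grey30",
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$baseline), color = "steelblue") +
    ggplot2::geom_line(
      ggplot2::aes(y = (1 - config$depth_threshold) * .data$baseline),
      color = "steelblue", linetype = "dashed"
    ) +
    ggplot2::labs(x = "time (s)", y = "pulse amplitude",
                  title = "PPG amplitude envelope and DAP events") +
    ggplot2::theme_minimal()
  if (nrow(daps) > 0) {
    daps$fill <- if ("label" %in% names(daps)) daps$label else "event"
    p <- p + ggplot2::geom_rect(
      data = daps,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$onset_s + .data$duration_s,
                   fill = .data$fill),
      ymin = -Inf, ymax = Inf, alpha = 0.25, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(
        values = c(apneic_hypopneic = "tomato", control = "grey60",
                   event = "gold"), name = NULL
      )
  }
  p
}

#' Plot breathing-rate window estimates and the fused track
#'
#' @param br_windows Tibble from [estimate_br()].
#' @return A ggplot object.
#' @export
plot_breathing_rate <- function(br_windows) {
  long <- br_windows |>
    tidyr::pivot_longer(c("br_riiv_bpm", "br_riav_bpm", "br_rifv_bpm"),
                        names_to = "modulation", values_to = "br") |>
    dplyr::mutate(modulation = sub("^br_(.*)_bpm$", "\\1", .data$modulation))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$window_start_s / 60, y = .data$br)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$modulation), size = 0.7,
                        alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_line(
      data = br_windows,
      ggplot2::aes(x = .data$window_start_s / 60, y = .data$fused_br_bpm),
      color = "black", linewidth = 0.6, na.rm = TRUE
    ) +
    ggplot2::labs(x = "time (min)", y = "breaths/min",
                  title = "Breathing rate: modulation readings and fused track") +
    ggplot2::theme_minimal()
}
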