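#' Assemble a full run configuration
#'
#' Bundles every module's tunables into one list, the shape the pipeline and
#' the command-line tool consume. Any component can be replaced; YAML run
#' files (see [read_config()]) override defaults key by key.
#'
#' @param heart A [detection_thresholds()].
#' @param respiration A [respiration_config()].
#' @param sdb An [sdb_config()].
#' @param stages List: `movement_threshold` (units/s), `accel_fs` (Hz),
#'   `sd_estimator`.
#' @param respiration_window_s Breathing-rate window length, seconds.
#' @return A list of class `sleepglove_config`.
#' @export
sleepglove_config <- function(heart = detection_thresholds(),
                              respiration = respiration_config(),
                              sdb = sdb_config(),
                              stages = list(movement_threshold = 25,
                                            accel_fs = 50,
                                            sd_estimator = "sample"),
                              respiration_window_s = 64) {
  structure(list(heart = heart, respiration = respiration, sdb = sdb,
                 stages = stages,
                 respiration_window_s = respiration_window_s),
            class = "sleepglove_config")
}

#' Read a YAML run configuration
#'
#' Top-level keys `heart`, `respiration`, `sdb`, `stages` and
#' `respiration_window_s`; each subsection overrides the matching defaults.
#'
#' @param path Path to a YAML file.
#' @return A `sleepglove_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is needed to read config files", call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  merge_into <- function(fn, over) do.call(fn, over %||% list())
  `%||%` <- function(a, b) if (is.null(a)) b else a
  # [[ with exact names: $respiration would partially match respiration_window_s
  cfg <- sleepglove_config(
    heart = merge_into(detection_thresholds, y[["heart"]]),
    respiration = merge_into(respiration_config, y[["respiration"]]),
    sdb = merge_into(sdb_config, y[["sdb"]])
  )
  if (!is.null(y[["stages"]])) {
    cfg$stages <- utils::modifyList(cfg$stages, y[["stages"]])
  }
  if (!is.null(y[["respiration_window_s"]])) {
    cfg$respiration_window_s <- y[["respiration_window_s"]]
  }
  cfg
}
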