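#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the cross-validation report of a subtype classifier
#'
#' One row per fold with its hold-out accuracy.
#'
#' @param x An `sdb_svm` from [train_classifier()].
#' @param ... Unused.
#' @return A tibble `fold`, `accuracy`.
#' @export
tidy.sdb_svm <- function(x, ...) {
  tibble(fold = seq_along(x$cv$fold_acc), accuracy = x$cv$fold_acc)
}

#' One-row summary of a subtype classifier
#'
#' The columns mirror the platform's classification report: true-positive
#' rate, false-positive rate, accuracy and ROC AUC from the pooled
#' cross-validated predictions.
#'
#' @param x An `sdb_svm`.
#' @param ... Unused.
#' @return A one-row tibble: `task`, `TPr`, `FPr`, `Acc`, `AUC`, `n`,
#'   `folds`, `kernel_scale`.
#' @export
glance.sdb_svm <- function(x, ...) {
  tibble(task = paste(x$classes, collapse = "-"),
         TPr = x$cv$TPr, FPr = x$cv$FPr, Acc = x$cv$Acc, AUC = x$cv$AUC,
         n = x$cv$n, folds = x$cv$folds,
         kernel_scale = x$config$kernel_scale)
}

#' Tidy an analyzed night into the per-minute table
#'
#' @param x A `sleepglove_night` from [run_night()].
#' @param ... Unused.
#' @return The per-minute `SleepEvents` tibble.
#' @export
tidy.sleepglove_night <- function(x, ...) x$sleep_events

#' One-row whole-night summary
#'
#' @param x A `sleepglove_night`.
#' @param ... Unused.
#' @return The `NightSleepSummary` tibble (one row).
#' @export
glance.sleepglove_night <- function(x, ...) x$night_summary
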