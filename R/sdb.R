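#' Sleep-disordered-breathing analysis parameters
#'
#' A DAP (decrease in amplitude fluctuation) event is a stretch where the PPG
#' pulse-amplitude envelope falls below `1 - depth_threshold` times its
#' running baseline for at least `min_dur_s`; nearby events merge. A DAP is
#' apneic/hypopneic when an SpO2 desaturation onset falls in a 20 s window
#' left-centered on (i.e., opening at) the DAP onset. The desaturation
#' criterion -- at least `desat_drop` percentage points below the preceding
#' 120 s median baseline -- follows scoring-manual practice; the source
#' system leaves its magnitude to the detector reference.
#'
#' @param depth_threshold Fractional envelope drop that opens an event.
#' @param min_dur_s Minimum event duration, seconds.
#' @param merge_gap_s Events closer than this merge.
#' @param baseline_win_s Centered running-median span for the envelope
#'   baseline.
#' @param desat_drop SpO2 drop criterion, percentage points.
#' @param desat_baseline_s Preceding-median span for the SpO2 baseline.
#' @param couple_window_s Desaturation search window after a DAP onset.
#' @param couple_rule `"left"` (window starts at the DAP onset, default) or
#'   `"centered"` (window centred on it).
#' @param kernel_scale Gaussian kernel scale of the subtype classifier.
#' @param cv_folds Cross-validation folds.
#' @return A list of class `sdb_config`.
#' @export
sdb_config <- function(depth_threshold = 0.3, min_dur_s = 10, merge_gap_s = 5,
                       baseline_win_s = 150, desat_drop = 3,
                       desat_baseline_s = 120, couple_window_s = 20,
                       couple_rule = c("left", "centered"),
                       kernel_scale = 0.56, cv_folds = 10) {
  structure(list(depth_threshold = depth_threshold, min_dur_s = min_dur_s,
                 merge_gap_s = merge_gap_s, baseline_win_s = baseline_win_s,
                 desat_drop = desat_drop, desat_baseline_s = desat_baseline_s,
                 couple_window_s = couple_window_s,
                 couple_rule = match.arg(couple_rule),
                 kernel_scale = kernel_scale, cv_folds = cv_folds),
            class = "sdb_config")
}

#' Pulse-amplitude envelope and its running baseline
#'
#' Per-pulse peak-to-trough amplitudes interpolated to a uniform 4 Hz grid;
#' the baseline is a centered running median over `baseline_win_s`. Stretches
#' with pulse gaps longer than 5 s are flagged invalid.
#'
#' @param ppg Numeric PPG samples.
#' @param pulses A [detect_pulses()] result.
#' @param fs PPG sampling rate, Hz.
#' @param config An [sdb_config()].
#' @return A tibble `time_s`, `envelope`, `baseline`, `valid`.
#' @export
amplitude_envelope <- function(ppg, pulses, fs = 100, config = sdb_config()) {
  pt <- pulses$pulse_times
  if (length(pt) < 2) stop("need at least 2 pulses", call. = FALSE)
  idx <- round(pt * fs) + 1
  amp <- vapply(seq_along(idx), function(k) {
    lo <- if (k == 1) max(1, idx[k] - fs) else idx[k - 1]
    seg <- ppg[lo:idx[k]]
    if (all(is.na(seg)) || is.na(ppg[idx[k]])) return(NA_real_)
    ppg[idx[k]] - min(seg, na.rm = TRUE)
  }, numeric(1))

  grid_hz <- 4
  t_grid <- seq(min(pt), max(pt), by = 1 / grid_hz)
  ok <- is.finite(amp)
  env <- approx(pt[ok], amp[ok], xout = t_grid, rule = 2)$y
  # grid points further than 5 s from any pulse are untrustworthy
  nearest <- approx(pt[ok], pt[ok], xout = t_grid, method = "constant",
                    rule = 2)$y
  nxt <- approx(pt[ok], pt[ok], xout = t_grid, method = "constant",
                rule = 2, f = 1)$y
  valid <- (t_grid - nearest) <= 5 & (nxt - t_grid) <= 5
  k <- as.integer(config$baseline_win_s * grid_hz)
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, length(env) - (length(env) %% 2 == 0))
  baseline <- if (length(env) > 2 && k >= 3) {
    as.numeric(stats::runmed(env, k, endrule = "median"))
  } else {
    rep(median(env), length(env))
  }
  tibble(time_s = t_grid, envelope = env, baseline = baseline, valid = valid)
}

#' Detect DAP events on the amplitude envelope
#'
#' Maximal runs where the envelope is below `(1 - depth_threshold) *
#' baseline` for at least `min_dur_s`, after merging runs separated by less
#' than `merge_gap_s`. Depth is `1 - min(envelope)/baseline` over the event.
#'
#' @param env A tibble from [amplitude_envelope()].
#' @param config An [sdb_config()].
#' @return A tibble of events: `onset_s`, `duration_s`, `depth`.
#' @export
detect_dap <- function(env, config = sdb_config()) {
  below <- env$valid & env$envelope < (1 - config$depth_threshold) * env$baseline
  empty <- tibble(onset_s = numeric(), duration_s = numeric(), depth = numeric())
  if (!any(below)) return(empty)
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  dt <- env$time_s[2] - env$time_s[1]
  # merge runs separated by a short gap
  if (nrow(runs) > 1) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      gap_s <- (runs$start[i] - merged$end[nrow(merged)] - 1) * dt
      if (gap_s < config$merge_gap_s) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- dplyr::bind_rows(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  out <- purrr::pmap_dfr(runs, function(start, end) {
    dur <- (end - start + 1) * dt
    seg <- start:end
    tibble(
      onset_s = env$time_s[start],
      duration_s = dur,
      depth = 1 - min(env$envelope[seg]) / median(env$baseline[seg])
    )
  })
  dplyr::filter(out, .data$duration_s >= config$min_dur_s)
}

#' Detect SpO2 desaturation events
#'
#' The baseline at each second is the median over the preceding
#' `desat_baseline_s`; an event is a maximal run where the saturation sits at
#' least `desat_drop` points below baseline. Artifact readings (`NA`, the
#' decoded sentinel) are excluded.
#'
#' @param spo2 Tibble with `time_s` and `percent` (1 Hz), or a plain numeric
#'   vector taken as 1 Hz from time 0.
#' @param config An [sdb_config()].
#' @return A tibble `onset_s`, `nadir_s`, `drop_percent`, `duration_s`.
#' @export
detect_desaturation <- function(spo2, config = sdb_config()) {
  if (is.numeric(spo2)) {
    spo2 <- tibble(time_s = seq_along(spo2) - 1, percent = spo2)
  }
  empty <- tibble(onset_s = numeric(), nadir_s = numeric(),
                  drop_percent = numeric(), duration_s = numeric())
  v <- spo2$percent
  if (all(is.na(v))) {
    warning("SpO2 channel is all artifact", call. = FALSE)
    return(empty)
  }
  n <- length(v)
  w <- as.integer(config$desat_baseline_s)
  base <- vapply(seq_len(n), function(i) {
    seg <- v[max(1, i - w):i]
    median(seg, na.rm = TRUE)
  }, numeric(1))
  below <- !is.na(v) & (base - v) >= config$desat_drop
  if (!any(below)) return(empty)
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  purrr::map2_dfr(starts[r$values], ends[r$values], function(s, e) {
    seg <- s:e
    nad <- seg[which.min(v[seg])]
    tibble(
      onset_s = spo2$time_s[s],
      nadir_s = spo2$time_s[nad],
      drop_percent = base[nad] - v[nad],
      duration_s = spo2$time_s[e] - spo2$time_s[s] + 1
    )
  })
}

#' Couple DAP events with desaturations
#'
#' A DAP is labeled `apneic_hypopneic` when a desaturation onset falls inside
#' the coupling window (by default `[onset, onset + 20 s]`, the 20 s window
#' left-centered on the DAP); otherwise it is a `control` event. With no
#' desaturations at all, every DAP is control -- the specificity mechanism of
#' the detector.
#'
#' @param daps Tibble from [detect_dap()].
#' @param desats Tibble from [detect_desaturation()].
#' @param config An [sdb_config()].
#' @return `daps` with added columns `coupled_desat`, `label` and
#'   `desat_drop` (drop of the first coupled desaturation, `NA` for control).
#' @export
couple_dap_desat <- function(daps, desats, config = sdb_config()) {
  if (nrow(daps) == 0) {
    return(dplyr::mutate(daps, coupled_desat = logical(), label = character(),
                         desat_drop = numeric()))
  }
  win <- config$couple_window_s
  lohi <- function(onset) {
    if (config$couple_rule == "left") c(onset, onset + win)
    else c(onset - win / 2, onset + win / 2)
  }
  hit <- purrr::map(daps$onset_s, function(o) {
    b <- lohi(o)
    which(desats$onset_s >= b[1] & desats$onset_s <= b[2])
  })
  daps$coupled_desat <- lengths(hit) > 0
  daps$label <- ifelse(daps$coupled_desat, "apneic_hypopneic", "control")
  daps$desat_drop <- vapply(hit, function(h) {
    if (length(h)) desats$drop_percent[h[1]] else NA_real_
  }, numeric(1))
  daps
}

#' Per-minute apnea flags and the apnea-hypopnea index
#'
#' A minute is flagged when it overlaps an apneic/hypopneic DAP event. The
#' AHI is the apneic/hypopneic event count per hour of recording.
#'
#' @param daps Labeled events from [couple_dap_desat()].
#' @param recording_len_s Total recording length, seconds.
#' @return A list: `minutes` (tibble `minute_index`, `is_apnea`), `ahi`,
#'   `n_events`.
#' @export
minute_apnea_labels <- function(daps, recording_len_s) {
  n_min <- ceiling(recording_len_s / 60)
  flags <- rep(FALSE, n_min)
  ap <- daps[daps$label == "apneic_hypopneic", , drop = FALSE]
  if (nrow(ap) > 0) {
    for (i in seq_len(nrow(ap))) {
      m0 <- floor(ap$onset_s[i] / 60)
      m1 <- floor((ap$onset_s[i] + ap$duration_s[i]) / 60)
      flags[seq.int(m0, min(m1, n_min - 1)) + 1] <- TRUE
    }
  }
  list(
    minutes = tibble(minute_index = seq_len(n_min) - 1, is_apnea = flags),
    ahi = nrow(ap) / (recording_len_s / 3600),
    n_events = nrow(ap)
  )
}

# ---- feature extraction ----------------------------------------------------

# Band power on an irregularly usable interval series: spectrum of the
# 4 Hz-resampled interval series.
prv_spectral <- function(t_s, ipi_ms) {
  if (length(ipi_ms) < 8 || sd(ipi_ms) == 0) {
    return(list(lf = 0, hf = 0, lfhf = NA_real_, tot = 0,
                lf_peak = NA_real_, hf_peak = NA_real_))
  }
  grid <- seq(min(t_s), max(t_s), by = 0.25)
  x <- spline(t_s, ipi_ms, xout = grid, method = "natural")$y
  ps <- welch_psd(x, 4)
  bp <- function(lo, hi) sum(ps$power[ps$freq >= lo & ps$freq < hi])
  pk <- function(lo, hi) {
    sel <- ps$freq >= lo & ps$freq < hi
    if (!any(sel)) return(NA_real_)
    ps$freq[sel][which.max(ps$power[sel])]
  }
  lf <- bp(0.04, 0.15); hf <- bp(0.15, 0.4)
  list(lf = lf, hf = hf,
       lfhf = if (hf > 0) lf / hf else NA_real_,
       tot = bp(0.003, 0.4), lf_peak = pk(0.04, 0.15), hf_peak = pk(0.15, 0.4))
}

#' Feature vector for one DAP event
#'
#' 37 features from the 65 s PPG window centered on the DAP plus the SpO2
#' descent, capturing the sympathovagal arousal signature of the event: 10
#' pulse-rate-variability time-domain statistics, 12 PRV spectral quantities
#' over the LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands including the
#' sympathovagal balance LF/HF, 8 DAP morphology descriptors and 7 SpO2
#' descent statistics. The registry [sdb_feature_names()] documents the set;
#' identical input yields an identical vector. Undefined ratios (e.g. LF/HF
#' with zero HF power) carry the sentinel value -1.
#'
#' @param pulses A [detect_pulses()] result for the whole recording.
#' @param env Envelope tibble from [amplitude_envelope()].
#' @param spo2 SpO2 tibble (`time_s`, `percent`).
#' @param dap One row of the labeled DAP table.
#' @param window_s Analysis window centered on the event (65 s).
#' @return A named numeric vector of length 37, or `NULL` when the window is
#'   truncated by a recording edge.
#' @export
extract_features <- function(pulses, env, spo2, dap, window_s = 65) {
  ctr <- dap$onset_s + dap$duration_s / 2
  lo <- ctr - window_s / 2; hi <- ctr + window_s / 2
  rec_lo <- min(pulses$pulse_times); rec_hi <- max(pulses$pulse_times)
  if (lo < rec_lo || hi > rec_hi) return(NULL)

  iv <- pulses$ipi[pulses$ipi$valid & pulses$ipi$t_s >= lo &
                     pulses$ipi$t_s <= hi, ]
  if (nrow(iv) < 4) return(NULL) # too little pulse data for PRV features
  x <- iv$ipi_ms
  dx <- diff(x)
  td <- c(
    prv_mean = mean(x), prv_sdnn = sd(x),
    prv_rmssd = if (length(dx)) sqrt(mean(dx^2)) else 0,
    prv_pnn50 = if (length(dx)) mean(abs(dx) > 50) else 0,
    prv_median = median(x), prv_iqr = stats::IQR(x),
    prv_min = min(x), prv_max = max(x),
    prv_cv = sd(x) / mean(x),
    prv_sdsd = if (length(dx) > 1) sd(dx) else 0
  )
  sp <- prv_spectral(iv$t_s, x)
  # split the window at the event centre: LF/HF before vs after captures the
  # post-event sympathetic surge of obstructive events
  pre <- iv[iv$t_s < ctr, ]; post <- iv[iv$t_s >= ctr, ]
  hr_pre <- if (nrow(pre)) 60000 / mean(pre$ipi_ms) else NA_real_
  hr_post <- if (nrow(post)) 60000 / mean(post$ipi_ms) else NA_real_
  fd <- c(
    prv_lf = sp$lf, prv_hf = sp$hf,
    prv_lfhf = if (is.na(sp$lfhf)) -1 else sp$lfhf,
    prv_tot = sp$tot,
    prv_lf_norm = if (sp$lf + sp$hf > 0) sp$lf / (sp$lf + sp$hf) else -1,
    prv_hf_norm = if (sp$lf + sp$hf > 0) sp$hf / (sp$lf + sp$hf) else -1,
    prv_lf_peak = if (is.na(sp$lf_peak)) -1 else sp$lf_peak,
    prv_hf_peak = if (is.na(sp$hf_peak)) -1 else sp$hf_peak,
    prv_hr_pre = if (is.na(hr_pre)) -1 else hr_pre,
    prv_hr_post = if (is.na(hr_post)) -1 else hr_post,
    prv_hr_surge = if (is.na(hr_pre) || is.na(hr_post)) -1 else hr_post - hr_pre,
    prv_ipi_ratio = if (nrow(pre) && nrow(post))
      mean(post$ipi_ms) / mean(pre$ipi_ms) else -1
  )
  eseg <- env[env$time_s >= lo & env$time_s <= hi, ]
  rel <- eseg$envelope / pmax(eseg$baseline, 1e-9)
  nad_i <- which.min(rel)
  morph <- c(
    dap_duration = dap$duration_s, dap_depth = dap$depth,
    dap_area = sum(pmax(0, 1 - rel)) * 0.25,
    dap_min_ratio = min(rel),
    dap_time_to_nadir = eseg$time_s[nad_i] - dap$onset_s,
    dap_down_slope = if (nad_i > 1)
      (rel[nad_i] - rel[1]) / (eseg$time_s[nad_i] - eseg$time_s[1]) else 0,
    dap_up_slope = if (nad_i < length(rel))
      (rel[length(rel)] - rel[nad_i]) /
        (eseg$time_s[length(rel)] - eseg$time_s[nad_i]) else 0,
    dap_baseline = median(eseg$baseline)
  )
  sseg <- spo2[spo2$time_s >= lo & spo2$time_s <= hi &
                 !is.na(spo2$percent), , drop = FALSE]
  if (nrow(sseg) >= 5) {
    v <- sseg$percent
    nad <- which.min(v)
    base0 <- median(v[seq_len(max(1, floor(nrow(sseg) / 4)))])
    ox <- c(
      spo2_baseline = base0, spo2_min = min(v),
      spo2_drop = base0 - min(v), spo2_mean = mean(v), spo2_sd = sd(v),
      spo2_down_slope = if (nad > 1) (v[nad] - v[1]) /
        (sseg$time_s[nad] - sseg$time_s[1]) else 0,
      spo2_time_to_nadir = sseg$time_s[nad] - dap$onset_s
    )
  } else {
    ox <- c(spo2_baseline = -1, spo2_min = -1, spo2_drop = -1, spo2_mean = -1,
            spo2_sd = -1, spo2_down_slope = -1, spo2_time_to_nadir = -1)
  }
  out <- c(td, fd, morph, ox)
  out[!is.finite(out)] <- -1
  out
}

#' @rdname extract_features
#' @export
sdb_feature_names <- function() {
  c("prv_mean", "prv_sdnn", "prv_rmssd", "prv_pnn50", "prv_median", "prv_iqr",
    "prv_min", "prv_max", "prv_cv", "prv_sdsd",
    "prv_lf", "prv_hf", "prv_lfhf", "prv_tot", "prv_lf_norm", "prv_hf_norm",
    "prv_lf_peak", "prv_hf_peak", "prv_hr_pre", "prv_hr_post", "prv_hr_surge",
    "prv_ipi_ratio",
    "dap_duration", "dap_depth", "dap_area", "dap_min_ratio",
    "dap_time_to_nadir", "dap_down_slope", "dap_up_slope", "dap_baseline",
    "spo2_baseline", "spo2_min", "spo2_drop", "spo2_mean", "spo2_sd",
    "spo2_down_slope", "spo2_time_to_nadir")
}

#' Feature table for all classifiable events
#'
#' Runs [extract_features()] over a labeled DAP table; events whose 65 s
#' window is truncated by a recording edge are excluded.
#'
#' @inheritParams extract_features
#' @param daps Labeled DAP tibble (needs `onset_s`, `duration_s`, `depth`;
#'   a `subtype` column, if present, is carried through).
#' @return A tibble: one row per usable event, 37 feature columns plus
#'   `onset_s` and any `subtype`.
#' @export
sdb_feature_table <- function(pulses, env, spo2, daps, window_s = 65) {
  rows <- purrr::map(seq_len(nrow(daps)), function(i) {
    f <- extract_features(pulses, env, spo2, daps[i, ], window_s)
    if (is.null(f)) return(NULL)
    out <- as_tibble(as.list(f))
    out$onset_s <- daps$onset_s[i]
    if ("subtype" %in% names(daps)) out$subtype <- daps$subtype[i]
    out
  })
  dplyr::bind_rows(rows)
}

# ---- classification --------------------------------------------------------

balance_classes <- function(df, label_col, seed) {
  set.seed(seed)
  n_min <- min(table(df[[label_col]]))
  df |>
    dplyr::group_by(.data[[label_col]]) |>
    dplyr::slice_sample(n = n_min) |>
    dplyr::ungroup()
}

#' Train the Gaussian-kernel SVM subtype classifier
#'
#' One support-vector machine with Gaussian kernel
#' `K(x, y) = exp(-||x - y||^2 / scale^2)` at scale 0.56 (libsvm
#' `gamma = 1/scale^2`), features standardized, classes balanced by
#' downsampling every class to the minority count, evaluated by k-fold
#' cross-validation. Before training, dimensionality is reduced by ranking
#' the features on the absolute two-sample t statistic between the classes
#' and keeping the `n_features` strongest -- a fine-scale Gaussian kernel is
#' only usable after such a selection, since squared distances grow linearly
#' with the number of standardized features. The device protocol runs three
#' pairwise tasks: control vs obstructive/central, CA vs CH, OA vs OH.
#'
#' @param features Tibble with the 37 feature columns and a label column.
#' @param label_col Name of the label column.
#' @param classes Length-2 character vector selecting the pairwise task;
#'   `NULL` uses all labels present.
#' @param config An [sdb_config()].
#' @param seed Integer seed (balancing and fold assignment).
#' @param n_features Number of features retained by the selection step.
#' @return An object of class `sdb_svm`: the fitted model, the selected
#'   features, the standardization parameters, and a CV report (`TPr`,
#'   `FPr`, `Acc`, `AUC`, per-fold accuracies).
#' @export
train_classifier <- function(features, label_col = "subtype", classes = NULL,
                             config = sdb_config(), seed = 1,
                             n_features = 10) {
  stopifnot(label_col %in% names(features))
  if (!is.null(classes)) {
    features <- features[features[[label_col]] %in% classes, , drop = FALSE]
  }
  labs <- sort(unique(features[[label_col]]))
  if (length(labs) != 2) stop("need exactly two classes", call. = FALSE)
  tab <- table(features[[label_col]])
  if (min(tab) < 20) {
    warning(sprintf("fewer than 20 events in class %s; task skipped",
                    names(tab)[which.min(tab)]), call. = FALSE)
    return(NULL)
  }
  df <- balance_classes(features, label_col, seed)
  X <- as.matrix(df[, sdb_feature_names()])
  y <- factor(df[[label_col]], levels = labs)
  tstat <- apply(X, 2, function(col) {
    s <- stats::aggregate(col, list(y), function(v) c(m = mean(v), v = var(v),
                                                      n = length(v)))$x
    se <- sqrt(s[1, "v"] / s[1, "n"] + s[2, "v"] / s[2, "n"])
    if (!is.finite(se) || se == 0) 0 else abs(s[1, "m"] - s[2, "m"]) / se
  })
  selected <- names(sort(tstat, decreasing = TRUE))[
    seq_len(min(n_features, ncol(X)))]
  X <- X[, selected, drop = FALSE]
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  gamma <- 1 / config$kernel_scale^2

  set.seed(seed + 1)
  k <- config$cv_folds
  # stratified fold assignment: each fold carries the class balance
  fold <- integer(nrow(Xs))
  for (cl in labs) {
    sel <- which(y == cl)
    fold[sel] <- sample(rep(seq_len(k), length.out = length(sel)))
  }
  pred <- factor(rep(NA_character_, nrow(Xs)), levels = labs)
  dec <- numeric(nrow(Xs))
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                    gamma = gamma, scale = FALSE)
    p <- stats::predict(m, Xs[!tr, , drop = FALSE], decision.values = TRUE)
    pred[!tr] <- p
    dv <- attr(p, "decision.values")[, 1]
    # orient the decision value toward the positive (first) class
    if (!startsWith(colnames(attr(p, "decision.values"))[1], labs[1])) dv <- -dv
    dec[!tr] <- dv
  }
  pos <- labs[1]
  tp <- sum(pred == pos & y == pos); fn <- sum(pred != pos & y == pos)
  fp <- sum(pred == pos & y != pos); tn <- sum(pred != pos & y != pos)
  auc <- tryCatch(
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = dec,
                                   levels = rev(labs), quiet = TRUE))),
    error = function(e) NA_real_
  )
  fold_acc <- vapply(seq_len(k), function(f) mean(pred[fold == f] == y[fold == f]),
                     numeric(1))
  model <- e1071::svm(Xs, y, kernel = "radial", gamma = gamma, scale = FALSE)
  structure(list(
    model = model, selected = selected, mu = mu, sigma = sg, classes = labs,
    positive = pos, config = config,
    cv = list(TPr = tp / (tp + fn), FPr = fp / (fp + tn),
              Acc = mean(pred == y), AUC = auc, fold_acc = fold_acc,
              n = nrow(Xs), folds = k)
  ), class = "sdb_svm")
}

#' @export
print.sdb_svm <- function(x, ...) {
  cat(sprintf(
    "<sdb_svm> %s vs %s | Gaussian kernel scale %.2f | %d-fold CV: Acc %.3f, TPr %.3f, FPr %.3f, AUC %.3f (n = %d)\n",
    x$classes[1], x$classes[2], x$config$kernel_scale, x$cv$folds,
    x$cv$Acc, x$cv$TPr, x$cv$FPr, x$cv$AUC, x$cv$n))
  invisible(x)
}

#' Classify events with a trained subtype model
#'
#' @param model An `sdb_svm` from [train_classifier()].
#' @param features Tibble with the 37 feature columns.
#' @return Factor of predicted subtypes.
#' @export
classify_events <- function(model, features) {
  X <- as.matrix(features[, model$selected])
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sigma, "/")
  stats::predict(model$model, Xs)
}

#' Run the three pairwise subtype tasks
#'
#' Control vs apneic/hypopneic events use the coupling label; the subtype
#' tasks need a `subtype` column (CA/CH/OA/OH). Tasks whose classes are
#' missing or too small are skipped with a warning.
#'
#' @param features Labeled feature table.
#' @param config An [sdb_config()].
#' @param seed Integer seed.
#' @return A named list of `sdb_svm` objects (possibly with `NULL` entries):
#'   `C_O` (central vs obstructive apnea), `CA_CH`, `OA_OH`.
#' @export
pairwise_subtype_models <- function(features, config = sdb_config(), seed = 1) {
  run <- function(a, b) {
    have <- features$subtype %in% c(a, b)
    if (length(unique(features$subtype[have])) < 2) {
      warning(sprintf("classes %s/%s not both present; task skipped", a, b),
              call. = FALSE)
      return(NULL)
    }
    train_classifier(features[have, ], "subtype", c(a, b), config, seed)
  }
  list(C_O = run("CA", "OA"), CA_CH = run("CA", "CH"), OA_OH = run("OA", "OH"))
}
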