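sdb_night <- function(duration_h = 0.5, events = NULL, seed = 41) {
  sc <- night_scenario(duration_h = duration_h, events = events, seed = seed)
  syn <- generate_night(sc)
  ppg <- as.numeric(syn$stream$ppg)
  p <- detect_pulses(zscore_normalize(ppg))
  list(syn = syn, ppg = ppg, pulses = p,
       env = amplitude_envelope(ppg, p),
       spo2 = tibble::tibble(time_s = syn$stream$spo2$sample_idx / 100,
                             percent = syn$stream$spo2$value))
}

test_that("the amplitude envelope tracks pulse amplitude and ignores DC offset", {
  x <- sdb_night(duration_h = 10 / 60)
  ratio <- x$env$envelope / x$env$baseline
  expect_equal(unname(quantile(ratio, 0.5)), 1, tolerance = 0.05)
  env2 <- amplitude_envelope(x$ppg + 3000, x$pulses)
  expect_equal(env2$envelope, x$env$envelope, tolerance = 1e-9)
})

test_that("an injected 50% amplitude drop dips the envelope to half baseline", {
  ev <- data.frame(type = "control_dap", onset_s = 240, duration_s = 15,
                   depth = 0.5)
  x <- sdb_night(duration_h = 10 / 60, events = ev)
  inside <- x$env$time_s > 245 & x$env$time_s < 252
  expect_equal(median(x$env$envelope[inside] / x$env$baseline[inside]), 0.5,
               tolerance = 0.1)
})

test_that("DAP detection finds injected events, none on a clean night", {
  ev <- data.frame(type = "control_dap", onset_s = c(120, 300, 480, 660, 840),
                   duration_s = 15, depth = 0.5)
  x <- sdb_night(duration_h = 16 / 60, events = ev)
  daps <- detect_dap(x$env)
  expect_equal(nrow(daps), 5)
  expect_equal(daps$onset_s, ev$onset_s, tolerance = 3 / 120)
  expect_equal(daps$depth, rep(0.5, 5), tolerance = 0.2)
  clean <- sdb_night(duration_h = 16 / 60)
  expect_equal(nrow(detect_dap(clean$env)), 0)
  # constant envelope: no events
  env0 <- tibble::tibble(time_s = seq(0, 600, 0.25), envelope = 1,
                         baseline = 1, valid = TRUE)
  expect_equal(nrow(detect_dap(env0)), 0)
})

test_that("DAP count is monotone non-increasing in the depth threshold", {
  ev <- data.frame(type = "control_dap", onset_s = c(120, 300, 480),
                   duration_s = 15, depth = c(0.35, 0.55, 0.75))
  x <- sdb_night(duration_h = 11 / 60, events = ev)
  # thresholds within the detector's operating range: below ~0.25 the
  # respiratory amplitude modulation itself crosses the threshold every
  # breath and gap merging dominates the run structure
  counts <- vapply(c(0.3, 0.45, 0.6, 0.75),
                   function(th) nrow(detect_dap(x$env, sdb_config(depth_threshold = th))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 3)
})

test_that("desaturation detection applies the 3-point drop criterion", {
  base <- rep(97, 300)
  dip <- base; dip[150:159] <- 93
  ev <- detect_desaturation(dip)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$drop_percent, 4)
  expect_equal(ev$onset_s, 149) # 1 Hz series starting at t = 0
  expect_equal(nrow(detect_desaturation(base)), 0)
  shallow <- base; shallow[150:159] <- 95
  expect_equal(nrow(detect_desaturation(shallow)), 0)
  expect_warning(none <- detect_desaturation(rep(NA_real_, 60)), "artifact")
  expect_equal(nrow(none), 0)
})

test_that("DAP/desaturation coupling uses the 20 s left-centered window", {
  daps <- tibble::tibble(onset_s = 100, duration_s = 15, depth = 0.5)
  mk_desat <- function(t) tibble::tibble(onset_s = t, nadir_s = t + 5,
                                         drop_percent = 4, duration_s = 10)
  expect_equal(couple_dap_desat(daps, mk_desat(110))$label, "apneic_hypopneic")
  expect_equal(couple_dap_desat(daps, mk_desat(130))$label, "control")
  expect_equal(couple_dap_desat(daps, mk_desat(95))$label, "control")
  none <- couple_dap_desat(daps, mk_desat(110)[0, ])
  expect_equal(none$label, "control")
  # centered variant accepts a desaturation just before the DAP
  cfg <- sdb_config(couple_rule = "centered")
  expect_equal(couple_dap_desat(daps, mk_desat(95), cfg)$label,
               "apneic_hypopneic")
})

test_that("minute flags cover overlapped minutes and AHI counts events", {
  daps <- tibble::tibble(onset_s = 655, duration_s = 15, depth = 0.5,
                         label = "apneic_hypopneic")
  lab <- minute_apnea_labels(daps, recording_len_s = 1200)
  expect_identical(which(lab$minutes$is_apnea) - 1L, c(10L, 11L))
  expect_equal(lab$ahi, 1 / (1200 / 3600))
  empty <- minute_apnea_labels(daps[0, ], 1200)
  expect_false(any(empty$minutes$is_apnea))
  expect_equal(empty$ahi, 0)
})

test_that("feature vectors are deterministic, complete and scale as documented", {
  ev <- data.frame(type = c("OA", "CA"), onset_s = c(300, 600),
                   duration_s = 20)
  x <- sdb_night(duration_h = 20 / 60, events = ev)
  daps <- couple_dap_desat(detect_dap(x$env), detect_desaturation(x$spo2))
  f1 <- extract_features(x$pulses, x$env, x$spo2, daps[1, ])
  expect_length(f1, 37)
  expect_named(f1, sdb_feature_names())
  expect_true(all(is.finite(f1)))
  expect_identical(extract_features(x$pulses, x$env, x$spo2, daps[1, ]), f1)
  # PRV and SpO2 features depend on pulse times and SpO2 only: scaling the
  # PPG (hence the envelope) moves only the documented morphology features
  env2 <- x$env
  env2$envelope <- env2$envelope * 2
  env2$baseline <- env2$baseline * 2
  f2 <- extract_features(x$pulses, env2, x$spo2, daps[1, ])
  unchanged <- setdiff(sdb_feature_names(), c("dap_baseline"))
  expect_equal(f2[unchanged], f1[unchanged], tolerance = 1e-9)
  expect_equal(f2[["dap_baseline"]], 2 * f1[["dap_baseline"]], tolerance = 1e-9)
  # window truncated by the recording edge: event excluded
  edge <- daps[1, ]; edge$onset_s <- 5
  expect_null(extract_features(x$pulses, x$env, x$spo2, edge))
  tab <- sdb_feature_table(x$pulses, x$env, x$spo2, daps)
  expect_equal(nrow(tab), nrow(daps))
})

test_that("constant-interval windows zero the variability features", {
  pt <- seq(0, 200, by = 1)
  pulses <- structure(list(
    pulse_times = pt,
    ipi = tibble::tibble(t_s = pt[-length(pt)], ipi_ms = rep(1000, 200),
                         valid = TRUE),
    fs = 100), class = "pulse_series")
  env <- tibble::tibble(time_s = seq(0, 200, 0.25), envelope = 1, baseline = 1,
                        valid = TRUE)
  spo2 <- tibble::tibble(time_s = 0:200, percent = 97)
  dap <- tibble::tibble(onset_s = 95, duration_s = 10, depth = 0.5)
  f <- extract_features(pulses, env, spo2, dap)
  expect_equal(f[["prv_sdnn"]], 0)
  expect_equal(f[["prv_rmssd"]], 0)
  expect_equal(f[["prv_pnn50"]], 0)
  expect_equal(f[["prv_lfhf"]], -1) # undefined ratio carries the sentinel
})

test_that("the Gaussian SVM separates constructed classes and not shuffled ones", {
  set.seed(6)
  n <- 120
  mk <- function(lab, shift) {
    X <- matrix(rnorm(n / 2 * 37), n / 2, 37,
                dimnames = list(NULL, sdb_feature_names()))
    X[, 1:5] <- X[, 1:5] + shift # 3 s.d. separation in 5 informative features
    out <- tibble::as_tibble(X)
    out$subtype <- lab
    out
  }
  feats <- dplyr::bind_rows(mk("CA", 0), mk("OA", 3))
  # the construction has exactly 5 informative dimensions; selecting them is
  # the point of the feature-selection step
  m <- train_classifier(feats, "subtype", seed = 2, n_features = 5)
  expect_gte(m$cv$Acc, 0.9)
  expect_gte(m$cv$AUC, 0.9)
  # doubling every feature's scale: standardization makes predictions identical
  feats2 <- feats
  feats2[sdb_feature_names()] <- feats2[sdb_feature_names()] * 2
  m2 <- train_classifier(feats2, "subtype", seed = 2, n_features = 5)
  expect_identical(m2$cv, m$cv)
  expect_identical(classify_events(m, feats), classify_events(m2, feats2))
  # shuffled labels: chance
  set.seed(7)
  feats$subtype <- sample(feats$subtype)
  m3 <- train_classifier(feats, "subtype", seed = 2)
  expect_equal(m3$cv$Acc, 0.5, tolerance = 0.3)
  # deterministic under a fixed seed
  expect_identical(glance(train_classifier(feats, "subtype", seed = 2)),
                   glance(m3))
  # tiny class: skipped with a warning
  small <- feats[c(1:30, 61:70), ]
  expect_warning(skip <- train_classifier(small, "subtype", seed = 1),
                 "fewer than 20")
  expect_null(skip)
})

test_that("tidiers expose the CV report in broom shapes", {
  set.seed(8)
  X <- matrix(rnorm(80 * 37), 80, 37, dimnames = list(NULL, sdb_feature_names()))
  X[41:80, 2] <- X[41:80, 2] + 4
  feats <- tibble::as_tibble(X)
  feats$subtype <- rep(c("CA", "OA"), each = 40)
  m <- train_classifier(feats, "subtype", seed = 3)
  td <- tidy(m)
  expect_named(td, c("fold", "accuracy"))
  expect_equal(nrow(td), 10)
  gl <- glance(m)
  expect_named(gl, c("task", "TPr", "FPr", "Acc", "AUC", "n", "folds",
                     "kernel_scale"))
  expect_equal(gl$kernel_scale, 0.56)
})
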