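test_that("z-score normalization centers, scales and is affine invariant", {
  expect_equal(zscore_normalize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(500, 40, 7)
  z <- zscore_normalize(x)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_equal(zscore_normalize(3.2 * x + 11), z, tolerance = 1e-9)
  expect_error(zscore_normalize(rep(5, 10)), "constant")
  expect_error(zscore_normalize(1), "at least 2")
})

test_that("pulse detection finds beats and rejects the dicrotic notch", {
  x <- toy_pulse_train(n_beats = 120, ipi_s = 1, dicrotic = 0.4)
  p <- detect_pulses(zscore_normalize(x))
  expect_equal(length(p$pulse_times), 120, tolerance = 0.01)
  expect_equal(mean(p$ipi$ipi_ms), 1000, tolerance = 0.01)
  # removing the notch changes nothing: it was never detected
  x0 <- toy_pulse_train(n_beats = 120, ipi_s = 1, dicrotic = 0)
  p0 <- detect_pulses(zscore_normalize(x0))
  expect_equal(length(p0$pulse_times), length(p$pulse_times))
  # amplitude scaling after z-scoring cannot change the count
  p2 <- detect_pulses(zscore_normalize(100 * x + 4))
  expect_equal(length(p2$pulse_times), length(p$pulse_times))
  # flat signal: no pulses
  flat <- detect_pulses(rep(0, 1000))
  expect_equal(length(flat$pulse_times), 0)
})

test_that("intervals bridging invalid samples are excluded", {
  x <- zscore_normalize(toy_pulse_train(n_beats = 60))
  x[3000:3100] <- NA
  p <- detect_pulses(x)
  gap <- p$ipi$t_s < 31 & (p$ipi$t_s + p$ipi$ipi_ms / 1000) > 30
  expect_true(all(!p$ipi$valid[gap]))
  expect_true(mean(p$ipi$valid) > 0.9)
})

test_that("ectopic cleaning masks deviants and is monotone in tolerance", {
  r <- clean_ectopic(c(1000, 1000, 400, 1000, 1000))
  expect_identical(which(r$ectopic), 3L)
  expect_true(r$ipi_clean_ms[3] > 900) # interpolated for HR averaging
  expect_identical(r$ipi_ms[3], 400)   # raw kept
  same <- clean_ectopic(rep(800, 10))
  expect_false(any(same$ectopic))
  expect_equal(attr(same, "mask_fraction"), 0)
  set.seed(3)
  x <- 1000 + rnorm(200, 0, 120)
  fracs <- vapply(c(0.5, 0.3, 0.15, 0.05),
                  function(tol) attr(clean_ectopic(x, tol), "mask_fraction"),
                  numeric(1))
  expect_true(all(diff(fracs) >= 0)) # tighter tolerance masks no less
})

test_that("brady/tachy minute rules follow the 1200/500 ms interval thresholds", {
  th <- detection_thresholds()
  expect_equal(60000 / th$brady_ibi_ms, 50)  # HR < 50 bpm
  expect_equal(60000 / th$tachy_ibi_ms, 120) # HR > 120 bpm
  expect_identical(label_brady_tachy(rep(1300, 40)),
                   list(is_brady = TRUE, is_tachy = FALSE))
  expect_identical(label_brady_tachy(rep(450, 40)),
                   list(is_brady = FALSE, is_tachy = TRUE))
  expect_identical(label_brady_tachy(rep(1000, 40)),
                   list(is_brady = FALSE, is_tachy = FALSE))
  # boundary: exactly at threshold is not an episode (strict)
  expect_false(label_brady_tachy(rep(1200, 40))$is_brady)
  expect_false(label_brady_tachy(rep(500, 40))$is_tachy)
  # single-interval episode rule
  th_any <- detection_thresholds(episode_rule = "any")
  mixed <- c(rep(1000, 50), 1250)
  expect_false(label_brady_tachy(mixed, th)$is_brady)
  expect_true(label_brady_tachy(mixed, th_any)$is_brady)
})

test_that("AF/PVC detection applies the 50 ms deviation-from-mean rule", {
  # mean 816.7; 900 exceeds 866.7 -> AF only
  expect_identical(detect_af_pvc(c(800, 800, 800, 900, 800, 800)),
                   list(is_af = TRUE, is_pvc = FALSE))
  # mean 783.3; 700 is below 733.3 -> PVC only
  expect_identical(detect_af_pvc(c(800, 800, 800, 700, 800, 800)),
                   list(is_af = FALSE, is_pvc = TRUE))
  expect_identical(detect_af_pvc(rep(950, 30)),
                   list(is_af = FALSE, is_pvc = FALSE))
  # interval exactly mean + 50: strict rule, no detection
  x <- c(rep(1000, 5), 1060) # mean 1010, deviation exactly 50
  expect_false(detect_af_pvc(x)$is_af)
  expect_true(detect_af_pvc(c(rep(1000, 5), 1061))$is_af)
  # too few intervals
  expect_true(is.na(detect_af_pvc(c(800, 900, 800))$is_af))
})

test_that("AF/PVC flags are invariant under adding a constant to every interval", {
  set.seed(4)
  for (i in 1:20) {
    x <- 900 + rnorm(30, 0, 40)
    shift <- runif(1, -300, 300)
    expect_identical(detect_af_pvc(x + shift), detect_af_pvc(x))
  }
})

test_that("minute labels recover generated bradycardic and tachycardic minutes", {
  kinds <- rep(c(NA, "brady", NA, "tachy"), 3)
  arr <- data.frame(minute = which(!is.na(kinds)) - 1,
                    kind = kinds[!is.na(kinds)])
  sc <- night_scenario(duration_h = length(kinds) / 60, arrhythmia = arr,
                       seed = 21)
  syn <- generate_night(sc)
  p <- detect_pulses(zscore_normalize(as.numeric(syn$stream$ppg)))
  lab <- minute_cardiac_labels(p, n_minutes = length(kinds))
  expect_identical(lab$is_brady, syn$truth$minutes$is_brady)
  expect_identical(lab$is_tachy, syn$truth$minutes$is_tachy)
  expect_false(any(lab$is_brady & lab$is_tachy, na.rm = TRUE))
  # HR readout on clean minutes
  clean <- is.na(kinds)
  expect_equal(lab$mean_hr_bpm[clean],
               syn$truth$minutes$hr_bpm[clean], tolerance = 0.02)
})
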