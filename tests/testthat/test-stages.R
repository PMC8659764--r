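# brute-force reference for the staging rule, evaluated minute by minute
oracle_stages <- function(n, sample_sd = TRUE) {
  mN <- mean(n)
  sN <- sd(n)
  if (!sample_sd) sN <- sN * sqrt((length(n) - 1) / length(n))
  out <- character(length(n))
  for (j in seq_along(n)) {
    out[j] <- if (n[j] > mN + 3 * sN) "AW"
    else if (n[j] > mN + sN) "LS"
    else "DS"
  }
  out
}

test_that("the movement derivative sums absolute axis differences per second", {
  a <- data.frame(x = c(0, 0.1), y = c(0, 0.1), z = c(0, 0.1))
  expect_equal(movement_derivative(a, 0.02), 15)
  same <- data.frame(x = c(1, 1), y = c(2, 2), z = c(3, 3))
  expect_equal(movement_derivative(same, 0.02), 0)
  # invariant under axis permutation and sign flips
  set.seed(9)
  b <- data.frame(x = rnorm(50), y = rnorm(50), z = rnorm(50))
  d0 <- movement_derivative(b)
  expect_equal(movement_derivative(data.frame(x = b$z, y = -b$x, z = b$y)), d0)
})

test_that("movement counting registers rising edges, not samples above threshold", {
  fs <- 50
  a <- data.frame(x = rep(0, fs * 120), y = 0, z = 0)
  # one sustained 1 s excursion and two short ones in minute 0
  a$x[100:150] <- 2
  a$x[800:805] <- 2
  a$x[2000:2002] <- 2
  cnt <- movement_counts(a, fs = fs, threshold = 25)
  expect_equal(nrow(cnt), 2)
  # each excursion has one rising and one falling edge of the derivative,
  # both crossing upward once
  expect_equal(cnt$n_movements[1], 6)
  expect_equal(cnt$n_movements[2], 0)
  # noise alone never counts at the default threshold
  set.seed(10)
  quiet <- data.frame(x = rnorm(fs * 60, sd = 0.01),
                      y = rnorm(fs * 60, sd = 0.01),
                      z = 1 + rnorm(fs * 60, sd = 0.01))
  expect_equal(movement_counts(quiet, fs = fs)$n_movements, 0)
})

test_that("stage classification matches the brute-force rule on worked examples", {
  # 10-minute night, one 100-count outlier: sample s.d. keeps it out of AW
  n1 <- c(rep(0, 9), 100)
  s1 <- classify_stages(n1)
  expect_identical(as.character(s1$stage), oracle_stages(n1))
  expect_identical(as.character(s1$stage[10]), "LS")
  # 100-minute night: the same outlier now clears the 3-sigma bar
  n2 <- c(rep(0, 99), 100)
  s2 <- classify_stages(n2)
  expect_identical(as.character(s2$stage), oracle_stages(n2))
  expect_identical(as.character(s2$stage[100]), "AW")
  # all-zero counts: zero variance, everything Deep Sleep
  expect_true(all(classify_stages(rep(0, 30))$stage == "DS"))
})

test_that("stage classification matches the oracle on random count vectors", {
  set.seed(11)
  for (i in 1:25) {
    n <- rpois(sample(10:200, 1), lambda = sample(c(0.5, 2, 10), 1))
    expect_identical(as.character(classify_stages(n)$stage), oracle_stages(n))
    expect_identical(
      as.character(classify_stages(n, "population")$stage),
      oracle_stages(n, sample_sd = FALSE)
    )
  }
})

test_that("labels are invariant under positive scaling of all counts", {
  set.seed(12)
  for (c_ in c(0.5, 2, 17)) {
    n <- rpois(120, 3)
    expect_identical(classify_stages(n * c_)$stage, classify_stages(n)$stage)
  }
})

test_that("with sample s.d., a single outlier cannot reach AW when n <= 10", {
  # threshold arithmetic: the outlier's z-score is bounded by (n-1)/sqrt(n)
  for (n_len in c(5, 8, 10)) {
    counts <- c(rep(0, n_len - 1), 1000)
    expect_false(any(classify_stages(counts)$stage == "AW"))
  }
  counts <- c(rep(0, 10), 1000) # n = 11: bound exceeded, AW reachable
  expect_identical(as.character(classify_stages(counts)$stage[11]), "AW")
})

test_that("stage durations sum to the recording length and wake-ups count runs", {
  set.seed(13)
  n <- rpois(90, 2); n[c(10, 11, 50)] <- 60
  st <- classify_stages(n)
  ssum <- stage_summary(st)
  expect_equal(ssum$LightSleepDuration + ssum$DeepSleepDuration +
                 ssum$AwakeDuration, 90)
  expect_equal(ssum$SleepDuration, 90)
  r <- rle(as.character(st$stage))
  expect_equal(ssum$WakeUpsCounter, sum(r$values == "AW"))
})
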