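# fixtures built in code: random token streams for the codec and small
# synthetic nights for the analysis modules

random_stream <- function(n = 2000, seed = NULL, p_aux = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  # random walk with occasional large jumps so DD, SF and AV all occur
  steps <- sample(-120:120, n - 1, replace = TRUE)
  jumps <- sample(c(rep(0, 50), c(-1, 1) * 3000, 12345), n - 1, replace = TRUE)
  ppg <- cumsum(c(131072, steps + jumps))
  ppg <- as.integer(pmin(pmax(ppg, 0), 262143))
  spo2_idx <- sort(sample(0:(n - 1), max(1, round(n * p_aux))))
  mov_idx <- sort(sample(0:(n - 1), max(1, round(n * p_aux / 4))))
  sample_stream(
    ppg,
    spo2 = data.frame(sample_idx = spo2_idx,
                      percent = sample(80:100, length(spo2_idx), TRUE)),
    movements = data.frame(sample_idx = mov_idx,
                           count = sample(0:50, length(mov_idx), TRUE))
  )
}

streams_equal <- function(a, b) {
  identical(a$ppg, b$ppg) &&
    identical(a$spo2$sample_idx, b$spo2$sample_idx) &&
    all(a$spo2$value == b$spo2$value) &&
    identical(a$movements$sample_idx, b$movements$sample_idx) &&
    all(a$movements$value == b$movements$value)
}

# pulse train built from first principles (independent of the synth module):
# gaussian systolic peak per beat, optional dicrotic bump
toy_pulse_train <- function(n_beats = 60, ipi_s = 1, fs = 100,
                            dicrotic = 0.4, noise_sd = 0.005, seed = 99) {
  set.seed(seed)
  dur <- n_beats * ipi_s
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  onset <- (ceiling(t / ipi_s) - 1) * ipi_s
  u <- (t - onset) / ipi_s
  x <- exp(-((u - 0.3) / 0.08)^2 / 2)
  if (dicrotic > 0) x <- x + dicrotic * exp(-((u - 0.6) / 0.1)^2 / 2)
  x + stats::rnorm(length(t), sd = noise_sd)
}
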