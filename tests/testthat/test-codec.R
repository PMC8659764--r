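# reference factorization oracle: exhaustive search over the scale set for
# the smallest exact divisor with an 8-bit quotient
oracle_delta_tokens <- function(prev, cur) {
  d <- cur - prev
  if (d >= -128 && d <= 127) return(list(kind = "DD", value = d))
  for (s in c(2, 4, 8, 16, 32, 64, 128, 256)) {
    if (d %% s == 0 && abs(d / s) <= 127) {
      return(list(kind = c("SF", "DD"), value = c(s, d / s)))
    }
  }
  list(kind = "AV", value = cur)
}

test_that("delta encoding picks DD, the smallest exact scale factor, or AV", {
  expect_equal(encode_delta(1000, 1005),
               tibble::tibble(kind = "DD", value = 5L))
  expect_equal(encode_delta(777, 777)$value, 0L)
  ex <- encode_delta(0, 512)
  expect_equal(ex$kind, c("SF", "DD"))
  expect_equal(ex$value, c(8L, 64L))
  expect_equal(prod(ex$value), 512)
  set.seed(1)
  for (d in c(sample(-60000:60000, 60), 254, -256, 127, -128, 128, 129,
              32640, 32641)) {
    got <- encode_delta(100000, 100000 + d)
    want <- oracle_delta_tokens(100000, 100000 + d)
    expect_equal(got$kind, want$kind, info = paste("delta", d))
    expect_equal(got$value, as.integer(want$value), info = paste("delta", d))
    # lossless contract: tokens reproduce the sample exactly
    rec <- if (identical(got$kind, "AV")) got$value
    else if (identical(got$kind, "DD")) 100000 + got$value
    else 100000 + got$value[1] * got$value[2]
    expect_identical(as.integer(rec), as.integer(100000 + d))
  }
})

test_that("SpO2 offset coding clamps to the 6-bit range with artifact sentinel", {
  expect_identical(encode_spo2(100), 63L)
  expect_identical(encode_spo2(37), 0L)
  expect_identical(encode_spo2(97), 60L)
  expect_identical(encode_spo2(20), 0L) # negative difference -> artifact 0
  expect_warning(over <- encode_spo2(105), "clamped")
  expect_identical(over, 63L)
  expect_identical(decode_spo2(encode_spo2(97)), 97L)
  expect_true(is.na(decode_spo2(encode_spo2(37)))) # sentinel decodes to NA
})

test_that("xor checksum folds to 8 bits and detects single-byte corruption", {
  expect_identical(xor_checksum(raw(0)), 0L)
  expect_identical(xor_checksum(as.raw(c(0x01, 0x02, 0x03))), 0L)
  set.seed(2)
  b <- as.raw(sample(0:255, 100, TRUE))
  expect_identical(xor_checksum(c(b, b)), 0L)
  for (i in sample(length(b), 5)) {
    b2 <- b
    b2[i] <- as.raw(bitwXor(as.integer(b2[i]), sample(1:255, 1)))
    expect_false(xor_checksum(b2) == xor_checksum(b))
  }
})

test_that("one second of constant PPG packs as AV + 99 zero deltas in one frame", {
  s <- sample_stream(rep(1000L, 100))
  fr <- encode_recording(s)
  expect_equal(nrow(fr), 1)
  blk <- fr$block[[1]]
  expect_equal(length(blk), 4096)
  # row 1: counter 0, then useful bits = one 21-bit AV + 99 9-bit DDs
  expect_equal(sum(as.integer(blk[1:4]) * 256^(0:3)), 0)
  useful <- as.integer(blk[5]) + 256L * as.integer(blk[6])
  expect_equal(useful, 21 + 99 * 9)
  expect_true(streams_equal(decode_file(fr), s))
})

test_that("serialized blocks have the 25 x 157 byte geometry", {
  fr <- encode_recording(random_stream(30000, seed = 3))
  expect_gt(nrow(fr), 1)
  for (i in seq_len(nrow(fr))) {
    blk <- fr$block[[i]]
    expect_equal(length(blk), 4096)
    # bytes beyond the 25 rows are padding
    expect_true(all(blk[(25 * 157 + 1):4096] == as.raw(0)))
    # per-row useful-bit counts within payload capacity
    off <- 0
    for (r in 1:25) {
      hdr <- if (r == 1) 4 else 0
      ub <- as.integer(blk[off + hdr + 1]) + 256L * as.integer(blk[off + hdr + 2])
      expect_lte(ub, (if (r == 1) 151 else 155) * 8)
      off <- off + 157
    }
  }
})

test_that("encode/decode round-trips randomized clean streams exactly", {
  for (seed in 1:40) {
    s <- random_stream(n = sample(500:5000, 1), seed = seed)
    expect_true(streams_equal(decode_file(encode_recording(s)), s),
                info = paste("seed", seed))
  }
})

test_that("decoding is invariant under frame reordering and keeps first duplicate", {
  s <- random_stream(25000, seed = 7)
  fr <- encode_recording(s)
  d0 <- decode_file(fr)
  set.seed(8)
  d1 <- decode_file(fr[sample(nrow(fr)), ])
  expect_identical(d1$ppg, d0$ppg)
  expect_identical(d1$spo2, d0$spo2)
  dup <- dplyr::bind_rows(fr, fr[2, ])
  expect_warning(d2 <- decode_file(dup), "duplicate")
  expect_identical(d2$ppg, d0$ppg)
})

test_that("a corrupted block is dropped, its gap recorded, the rest intact", {
  s <- random_stream(25000, seed = 9)
  fr <- encode_recording(s)
  i <- 4
  blk <- fr$block[[i]]
  blk[800] <- as.raw(bitwXor(as.integer(blk[800]), 64L))
  fr$block[[i]] <- blk
  d <- decode_file(fr)
  expect_equal(nrow(d$gaps), 1)
  expect_equal(d$gaps$reason, "missing_block")
  lost <- seq.int(d$gaps$from_sample + 1, d$gaps$to_sample + 1)
  expect_true(all(is.na(d$ppg[lost])))
  expect_false(any(d$valid[lost]))
  expect_identical(d$ppg[-lost], s$ppg[-lost])
})

test_that("artifact samples become garbage tokens and invalidate their segment", {
  s <- random_stream(12000, seed = 10)
  ppg <- s$ppg
  ppg[3000:3004] <- NA # out-of-range artifacts
  s2 <- sample_stream(ppg, spo2 = data.frame(sample_idx = s$spo2$sample_idx,
                                             percent = s$spo2$value),
                      movements = data.frame(sample_idx = s$movements$sample_idx,
                                             count = s$movements$value))
  d <- decode_file(encode_recording(s2))
  expect_true(all(is.na(d$ppg[3000:3004])))
  expect_identical(d$ppg[-(3000:3004)], ppg[-(3000:3004)])
  # counter still advanced through the garbage
  expect_equal(length(d$ppg), length(ppg))
  # the enclosing segment is flagged invalid
  expect_false(any(d$valid[3000:3004]))
  expect_equal(d$gaps$reason, "garbage_segment")
  expect_lt(mean(!d$valid), 0.5)
})

test_that("bin files round-trip through disk with the length-prefixed container", {
  s <- random_stream(8000, seed = 11)
  fr <- encode_recording(s)
  f <- withr::local_tempfile(fileext = ".bin")
  write_bin(fr, f)
  fr2 <- read_bin(f)
  expect_equal(nrow(fr2), nrow(fr))
  expect_identical(fr2$header, fr$header)
  expect_true(streams_equal(decode_file(fr2), s))
  expect_match(bin_filename(s), "^user_\\d{8}T\\d{6}Z\\.bin$")
})

test_that("stream/table conversion preserves all three channels", {
  s <- random_stream(4000, seed = 12)
  tab <- stream_to_table(s)
  expect_named(tab, c("time_s", "ppg", "spo2", "movements"))
  expect_equal(nrow(tab), 4000)
  s2 <- table_to_stream(tab)
  expect_true(streams_equal(s2, s))
})
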