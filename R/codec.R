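#' Construct a time-aligned sample stream
#'
#' A `sample_stream` is the in-memory form of one overnight recording: a PPG
#' channel sampled at 100 Hz, a 1 Hz SpO2 channel and a per-epoch movement
#' count channel, all indexed by the running PPG sample counter. It is both
#' what the block codec encodes and what every analysis module consumes.
#'
#' Auxiliary channels are bound to PPG sample indices: an SpO2 value or a
#' movement count is stamped at the most recent PPG sample preceding (or
#' coinciding with) its production time, which preserves the 1 Hz SpO2
#' cadence exactly.
#'
#' @param ppg Integer vector of PPG samples at `fs` Hz. Values must lie in
#'   the 18-bit device range `[0, 262143]`; `NA` marks an artifact sample
#'   (encoded as garbage, value lost, counter preserved).
#' @param spo2 Tibble/data frame with columns `sample_idx` (0-based PPG
#'   sample index) and `percent` (integer SpO2 reading), or `NULL`.
#' @param movements Tibble/data frame with columns `sample_idx` and `count`
#'   (unsigned 16-bit per-epoch movement count), or `NULL`.
#' @param fs PPG sampling frequency in Hz (device nominal 100).
#' @param start_time Recording start, a `POSIXct` (used for report dates and
#'   the `.bin` filename convention).
#' @param user_id,device_id Identifier strings.
#'
#' @return An object of class `sample_stream`: a list with the validated
#'   channels plus sampling metadata.
#' @export
sample_stream <- function(ppg, spo2 = NULL, movements = NULL, fs = 100,
                          start_time = as.POSIXct("2021-01-01 22:00:00", tz = "UTC"),
                          user_id = "user", device_id = "upnea-0") {
  ppg <- as.integer(round(ppg))
  if (length(ppg) == 0) stop("empty PPG channel", call. = FALSE)
  bad <- !is.na(ppg) & (ppg < 0L | ppg > 262143L)
  if (any(bad)) {
    # outside the 18-bit device range: artifact by definition
    ppg[bad] <- NA_integer_
  }
  norm_aux <- function(x, value_col, max_val) {
    if (is.null(x) || nrow(as.data.frame(x)) == 0) {
      return(tibble(sample_idx = integer(), value = integer()))
    }
    x <- as.data.frame(x)
    out <- tibble(
      sample_idx = as.integer(x$sample_idx),
      value = pmin(pmax(as.integer(round(x[[value_col]])), 0L), max_val)
    )
    if (any(out$sample_idx < 0L | out$sample_idx >= length(ppg))) {
      stop("auxiliary sample_idx outside the PPG channel", call. = FALSE)
    }
    dplyr::arrange(out, .data$sample_idx)
  }
  structure(
    list(
      ppg = ppg,
      spo2 = norm_aux(spo2, "percent", 255L),
      movements = norm_aux(movements, "count", 65535L),
      fs = fs,
      start_time = start_time,
      user_id = user_id,
      device_id = device_id
    ),
    class = "sample_stream"
  )
}

#' @export
print.sample_stream <- function(x, ...) {
  cat(sprintf(
    "<sample_stream> %.1f min of PPG @ %g Hz (%d samples, %d artifact), %d SpO2 values, %d movement epochs\n",
    length(x$ppg) / x$fs / 60, x$fs, length(x$ppg), sum(is.na(x$ppg)),
    nrow(x$spo2), nrow(x$movements)
  ))
  invisible(x)
}

#' XOR checksum over a byte sequence
#'
#' Folds the XOR operator over all bytes, reduced to 8 bits; the transport
#' header carries this value so a receiver can detect corrupted blocks. The
#' empty sequence checksums to 0 (the XOR identity).
#'
#' @param bytes A raw vector.
#' @return A single integer in `[0, 255]`.
#' @export
#' @examples
#' xor_checksum(as.raw(c(0x01, 0x02, 0x03))) # 0
xor_checksum <- function(bytes) {
  stopifnot(is.raw(bytes))
  if (length(bytes) == 0) return(0L)
  Reduce(bitwXor, as.integer(bytes))
}

#' Delta-encode one PPG sample as codec tokens
#'
#' Token-level view of the compression rule for a single sample: the delta
#' against the previous sample is stored as an 8-bit signed delta difference
#' (DD) when it fits; when it does not, the smallest scale factor (SF) in
#' `{2, 4, 8, 16, 32, 64, 128, 256}` that divides the delta exactly with an
#' 8-bit quotient is used, so the codec stays lossless; when no exact
#' factoring exists, the sample is re-encoded as an 18-bit absolute value
#' (AV). Garbage (GB) is never produced here: it is reserved for artifact
#' samples and emitted by the stream encoder.
#'
#' @param prev_ppg Last successfully encoded PPG value.
#' @param cur_ppg Current PPG value, within the 18-bit range.
#' @return A tibble of tokens with columns `kind` (`"DD"`, `"SF"`, `"AV"`)
#'   and `value` (the 8-bit delta, the scale *value* for SF rows, or the
#'   absolute sample).
#' @export
#' @examples
#' encode_delta(1000, 1005) # one DD token, value 5
#' encode_delta(0, 512)     # SF 8 then DD 64: 8 * 64 = 512
encode_delta <- function(prev_ppg, cur_ppg) {
  stopifnot(cur_ppg >= 0, cur_ppg <= 262143)
  d <- cur_ppg - prev_ppg
  if (d >= -128 && d <= 127) {
    return(tibble(kind = "DD", value = as.integer(d)))
  }
  for (code in 0:7) {
    s <- 2^(code + 1)
    if (d %% s == 0 && abs(d / s) <= 127) {
      return(tibble(kind = c("SF", "DD"), value = as.integer(c(s, d / s))))
    }
  }
  tibble(kind = "AV", value = as.integer(cur_ppg))
}

#' Offset-encode an SpO2 reading into its 6-bit code
#'
#' The device stores saturation as `percent - 37`, clamped to the 6-bit range
#' `[0, 63]`; a non-positive difference is stored as 0, the artifact
#' sentinel. Readings above 100 % cannot be represented and are clamped to 63
#' with a warning.
#'
#' @param spo2_percent Integer saturation reading(s), percent.
#' @return Integer code(s) in `[0, 63]`.
#' @export
#' @examples
#' encode_spo2(100) # 63
#' encode_spo2(97)  # 60
#' encode_spo2(37)  # 0 (artifact sentinel)
encode_spo2 <- function(spo2_percent) {
  code <- as.integer(round(spo2_percent)) - 37L
  code[is.na(code)] <- 0L # unreadable input stored as the artifact sentinel
  over <- !is.na(code) & code > 63L
  if (any(over)) {
    warning("SpO2 reading above 100% clamped to code 63", call. = FALSE)
    code[over] <- 63L
  }
  pmax(code, 0L)
}

#' Decode a 6-bit SpO2 code back to percent
#'
#' Code 0 is the artifact sentinel and decodes to `NA`.
#'
#' @param code Integer code(s) in `[0, 63]`.
#' @return Integer percent values in `[38, 100]`, `NA` for artifacts.
#' @export
decode_spo2 <- function(code) {
  out <- as.integer(code) + 37L
  out[code == 0L] <- NA_integer_
  out
}

#' Encode a sample stream into transport frames
#'
#' Packs the stream into 4096-byte blocks (25 rows of 157 bytes; see
#' `FORMAT.md`), each preceded by a JSON header carrying the device ID and an
#' 8-bit XOR checksum of the block bytes. Every block starts with its running
#' PPG sample counter and an absolute-value token; artifact samples are
#' written as garbage tokens followed by an absolute-value resync, the only
#' sanctioned information loss. Decoding the frames reproduces every
#' non-artifact sample exactly.
#'
#' @param stream A [sample_stream()].
#' @param device_id Device identifier for the frame headers; defaults to the
#'   stream's.
#' @return A tibble of class `transport_frames` with columns `counter`
#'   (starting PPG sample counter), `header` (JSON string) and `block`
#'   (list-column of 4096-byte raw vectors).
#' @export
encode_recording <- function(stream, device_id = stream$device_id) {
  stopifnot(inherits(stream, "sample_stream"))
  spo2_code <- encode_spo2(stream$spo2$value)
  enc <- cpp_encode_stream(
    stream$ppg,
    stream$spo2$sample_idx, spo2_code,
    stream$movements$sample_idx, stream$movements$value
  )
  headers <- vapply(enc$blocks, function(b) {
    jsonlite::toJSON(
      list(device_id = device_id, checksum = xor_checksum(b)),
      auto_unbox = TRUE
    )
  }, character(1))
  structure(
    tibble(
      counter = as.numeric(enc$counters),
      header = headers,
      block = enc$blocks
    ),
    class = c("transport_frames", "tbl_df", "tbl", "data.frame")
  )
}

#' Decode transport frames back into a sample stream
#'
#' Verifies each frame's XOR checksum (failing frames are dropped and the
#' gap recorded), orders blocks chronologically by their sample counters --
#' the on-disk arrangement follows the device's flash layout, not time --
#' de-duplicates counters (first frame wins) and reconstructs the three
#' channels. Any block containing a garbage token has its whole signal
#' segment flagged invalid for downstream analysis, mirroring the server's
#' discard rule.
#'
#' @param frames A `transport_frames` tibble from [encode_recording()] or
#'   [read_bin()].
#' @param fs,start_time,user_id Stream metadata (not carried by the wire
#'   format).
#' @return A [sample_stream()] with two extra fields: `valid`, a logical mask
#'   per PPG sample (`FALSE` over rejected/garbage blocks and unfilled gaps),
#'   and `gaps`, a tibble of dropped or invalid block extents with a reason.
#' @export
decode_file <- function(frames, fs = 100,
                        start_time = as.POSIXct("2021-01-01 22:00:00", tz = "UTC"),
                        user_id = "user") {
  stopifnot(nrow(frames) > 0)
  ok <- vapply(seq_len(nrow(frames)), function(i) {
    hdr <- jsonlite::fromJSON(frames$header[i])
    identical(as.integer(hdr$checksum), xor_checksum(frames$block[[i]]))
  }, logical(1))

  decoded <- lapply(frames$block[ok], cpp_decode_block)
  counters <- vapply(decoded, `[[`, numeric(1), "counter")
  ord <- order(counters)
  decoded <- decoded[ord]
  counters <- counters[ord]
  dup <- duplicated(counters)
  if (any(dup)) {
    warning(sprintf("%d duplicate block counter(s); keeping first", sum(dup)),
            call. = FALSE)
    decoded <- decoded[!dup]
    counters <- counters[!dup]
  }
  malformed <- vapply(decoded, `[[`, logical(1), "malformed")
  decoded <- decoded[!malformed]
  counters <- counters[!malformed]
  if (length(decoded) == 0) stop("no decodable blocks", call. = FALSE)

  n_total <- max(vapply(decoded, function(d) d$counter + length(d$ppg), numeric(1)))
  ppg <- rep(NA_integer_, n_total)
  valid <- rep(FALSE, n_total)
  spo2_idx <- integer(); spo2_code <- integer()
  move_idx <- integer(); move_val <- integer()
  gaps <- list()

  for (d in decoded) {
    rng <- seq.int(d$counter + 1, d$counter + length(d$ppg))
    ppg[rng] <- d$ppg
    if (d$has_gb) {
      gaps[[length(gaps) + 1]] <- tibble(
        from_sample = d$counter, to_sample = d$counter + length(d$ppg) - 1,
        reason = "garbage_segment"
      )
    } else {
      valid[rng] <- TRUE
    }
    spo2_idx <- c(spo2_idx, d$spo2_idx); spo2_code <- c(spo2_code, d$spo2_code)
    move_idx <- c(move_idx, d$move_idx); move_val <- c(move_val, d$move_val)
  }

  # unfilled stretches = checksum-rejected (or never-received) blocks
  hole <- is.na(ppg) & !valid
  if (any(hole)) {
    r <- rle(hole)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      covered <- any(vapply(decoded, function(d) {
        starts[k] - 1 >= d$counter && starts[k] - 1 < d$counter + length(d$ppg)
      }, logical(1)))
      if (!covered) {
        gaps[[length(gaps) + 1]] <- tibble(
          from_sample = starts[k] - 1, to_sample = ends[k] - 1,
          reason = "missing_block"
        )
      }
    }
  }

  out <- sample_stream(
    ppg = ppg,
    spo2 = tibble(sample_idx = spo2_idx, percent = decode_spo2(spo2_code)),
    movements = tibble(sample_idx = move_idx, count = move_val),
    fs = fs, start_time = start_time, user_id = user_id,
    device_id = jsonlite::fromJSON(frames$header[which(ok)[1]])$device_id
  )
  out$valid <- valid
  out$gaps <- if (length(gaps)) dplyr::bind_rows(gaps) else
    tibble(from_sample = numeric(), to_sample = numeric(), reason = character())
  out
}

#' Write transport frames to a `.bin` file
#'
#' On-disk container: for each frame, a 2-byte LSB-first length prefix, the
#' UTF-8 JSON header, then the 4096-byte block. The conventional filename is
#' `<userID>_<ISO8601 start time>.bin`; [bin_filename()] builds it.
#'
#' @param frames A `transport_frames` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bin <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(frames))) {
    hdr <- charToRaw(frames$header[i])
    writeBin(length(hdr), con, size = 2, endian = "little")
    writeBin(hdr, con)
    writeBin(frames$block[[i]], con)
  }
  invisible(path)
}

#' @rdname write_bin
#' @param stream A [sample_stream()] (used for its user ID and start time).
#' @export
bin_filename <- function(stream) {
  sprintf("%s_%s.bin", stream$user_id,
          format(stream$start_time, "%Y%m%dT%H%M%SZ", tz = "UTC"))
}

#' Read a `.bin` file into transport frames
#'
#' @param path Path to a file written by [write_bin()].
#' @return A `transport_frames` tibble; see [encode_recording()].
#' @export
read_bin <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  headers <- character(); blocks <- list(); counters <- numeric()
  while (pos + 1L <= length(bytes)) {
    len <- as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
    pos <- pos + 2L
    if (pos + len + 4096L - 1L > length(bytes)) {
      warning("truncated trailing frame ignored", call. = FALSE)
      break
    }
    headers <- c(headers, rawToChar(bytes[pos:(pos + len - 1L)]))
    pos <- pos + len
    blk <- bytes[pos:(pos + 4095L)]
    pos <- pos + 4096L
    blocks[[length(blocks) + 1L]] <- blk
    counters <- c(counters, sum(as.numeric(blk[1:4]) * 256^(0:3)))
  }
  structure(
    tibble(counter = counters, header = headers, block = blocks),
    class = c("transport_frames", "tbl_df", "tbl", "data.frame")
  )
}

#' Tabulate a decoded stream as a tidy signal table
#'
#' Unpacks a [sample_stream()] into the CSV dialect used by the command-line
#' tools: one row per PPG sample with empty cells where no auxiliary sample
#' falls.
#'
#' @param stream A [sample_stream()].
#' @return A tibble with columns `time_s`, `ppg`, `spo2`, `movements`.
#' @export
stream_to_table <- function(stream) {
  n <- length(stream$ppg)
  spo2 <- rep(NA_integer_, n)
  spo2[stream$spo2$sample_idx + 1L] <- if ("percent" %in% names(stream$spo2))
    stream$spo2$percent else stream$spo2$value
  mov <- rep(NA_integer_, n)
  mov[stream$movements$sample_idx + 1L] <- if ("count" %in% names(stream$movements))
    stream$movements$count else stream$movements$value
  tibble(
    time_s = (seq_len(n) - 1) / stream$fs,
    ppg = stream$ppg,
    spo2 = spo2,
    movements = mov
  )
}

#' @rdname stream_to_table
#' @param tab A data frame with the `stream_to_table()` columns.
#' @param ... Passed on to [sample_stream()].
#' @export
table_to_stream <- function(tab, ...) {
  fs <- if (nrow(tab) > 1) round(1 / median(diff(tab$time_s))) else 100
  has_spo2 <- !is.na(tab$spo2)
  has_mov <- !is.na(tab$movements)
  sample_stream(
    ppg = tab$ppg,
    spo2 = tibble(sample_idx = which(has_spo2) - 1L, percent = tab$spo2[has_spo2]),
    movements = tibble(sample_idx = which(has_mov) - 1L, count = tab$movements[has_mov]),
    fs = fs, ...
  )
}
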