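# Minimal PCM WAV reader/writer (RIFF little-endian, integer PCM).
# 8-bit unsigned, 16- and 24-bit signed supported on read; 16-bit on write.

read_wav_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) abort("Not a RIFF/WAV file.")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    abort("Not a WAVE file.")
  }
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        n_channels = readBin(con, "integer", 1, 2, endian = "little",
                             signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little",
                              signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little",
                       signed = FALSE))
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) abort("Malformed WAV: missing fmt/data chunk.")
  if (fmt$audio_format != 1) {
    abort(sprintf("Unsupported WAV encoding: format tag %d (only integer PCM is supported).",
                  fmt$audio_format))
  }
  if (!fmt$bits %in% c(8, 16, 24)) {
    abort(sprintf("Unsupported PCM bit depth: %d (8/16/24 supported).", fmt$bits))
  }
  samp <- switch(as.character(fmt$bits),
    "8" = (as.numeric(data) - 128) / 127,
    "16" = readBin(data, "integer", length(data) / 2, 2, signed = TRUE,
                   endian = "little") / 32767,
    "24" = {
      n <- length(data) / 3
      b <- matrix(as.numeric(data), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v[v >= 2^23] <- v[v >= 2^23] - 2^24
      v / (2^23 - 1)
    })
  mat <- matrix(samp, ncol = fmt$n_channels, byrow = TRUE)
  list(samples = mat, sample_rate = fmt$sample_rate, bits = fmt$bits)
}

#' Read a (paired) flight-tone recording from a PCM WAV file
#'
#' Reads an integer-PCM WAV file (8/16/24-bit, mono or two-channel) and
#' returns one `audio_rec` per channel, sharing a common time base.
#' Paired recordings keep each mosquito on its own channel.
#'
#' @param path Path to a WAV file.
#' @param subjects Optional list (length = number of channels) of subject
#'   metadata lists attached to the returned channels.
#' @param expect_channels If not `NULL`, error unless the file has
#'   exactly this many channels (e.g. `2` for a live-pair recording).
#' @return A list of `audio_rec` tibbles (`time_s`, `amplitude`), one per
#'   channel.
#' @export
read_pair_wav <- function(path, subjects = NULL, expect_channels = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  w <- read_wav_raw(path)
  nch <- ncol(w$samples)
  if (!is.null(expect_channels) && nch != expect_channels) {
    abort(sprintf("Expected %d channel(s) but %s has %d.",
                  expect_channels, basename(path), nch))
  }
  t <- (seq_len(nrow(w$samples)) - 1) / w$sample_rate
  lapply(seq_len(nch), function(ch) {
    new_series(tibble(time_s = t, amplitude = w$samples[, ch]),
               "audio_rec", w$sample_rate,
               subject = if (!is.null(subjects)) subjects[[ch]] else
                 list(id = paste0("ch", ch)))
  })
}

#' Write audio to a 16-bit PCM WAV file
#'
#' @param channels A single `audio_rec` or a list of them (equal length);
#'   each becomes one channel.
#' @param path Output path.
#' @param normalize Scale so the global peak maps to full range
#'   (default `TRUE`); otherwise amplitudes are clipped to `[-1, 1]`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(channels, path, normalize = TRUE) {
  if (is.data.frame(channels)) channels <- list(channels)
  fs <- sample_rate(channels[[1]])
  n <- nrow(channels[[1]])
  if (!all(vapply(channels, nrow, 1L) == n)) {
    abort("All channels must have the same number of samples.")
  }
  mat <- vapply(channels, function(ch) ch$amplitude, numeric(n))
  mat <- matrix(mat, nrow = n)
  peak <- max(abs(mat), 1e-12)
  if (normalize && peak > 0) mat <- mat / peak
  mat <- pmin(pmax(mat, -1), 1)
  ints <- as.integer(round(t(mat) * 32767)) # interleaved
  nch <- ncol(mat)
  data_size <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(round(fs)), con, size = 4, endian = "little")
  writeBin(as.integer(round(fs) * nch * 2), con, size = 4, endian = "little")
  writeBin(as.integer(nch * 2), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}
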