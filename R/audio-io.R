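# WAV reading/writing over base readBin/writeBin (RIFF PCM and IEEE float),
# plus segmentation into the one-minute analysis windows.

#' Construct an audio segment
#'
#' An audio segment is the unit of acoustic analysis: a mono, peak-bounded
#' waveform with its sampling rate. Samples are stored as doubles in
#' \eqn{[-1, 1]} regardless of the bit depth of the source file.
#'
#' @param samples Numeric vector of amplitudes, all finite.
#' @param rate_hz Sampling rate in Hz (default 44100, the pipeline rate).
#' @return An object of class `audio_segment` with fields `samples`,
#'   `rate_hz` and `n_samples`.
#' @export
audio_segment <- function(samples, rate_hz = 44100) {
  if (!is.numeric(samples) || length(samples) == 0L)
    abort_chick("audio segment has zero samples", "empty_audio_error")
  if (!all(is.finite(samples)))
    abort_chick("audio segment contains non-finite samples", "format_error")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    abort_chick("rate_hz must be a single positive number", "format_error")
  structure(list(samples = as.numeric(samples), rate_hz = as.numeric(rate_hz),
                 n_samples = length(samples)),
            class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment: %d samples @ %g Hz (%.2f s)>\n",
              x$n_samples, x$rate_hz, x$n_samples / x$rate_hz))
  invisible(x)
}

#' Read a WAV file as a mono audio segment
#'
#' Accepts RIFF/WAVE files holding integer PCM (8/16/24/32 bit) or 32-bit
#' IEEE float samples. Multi-channel input is averaged to mono; integer
#' samples are rescaled to \eqn{[-1, 1]} by the full-scale value of the bit
#' depth.
#'
#' @param path Path to an existing WAV file.
#' @return An [audio_segment].
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    abort_chick(sprintf("no such file: %s", path), "format_error")
  con <- file(path, "rb")
  on.exit(close(con))

  read_tag <- function() rawToChar(readBin(con, "raw", 4L))
  read_u32 <- function() {
    b <- readBin(con, "raw", 4L)
    if (length(b) < 4L) abort_chick("truncated WAV header", "format_error")
    sum(as.numeric(b) * 256^(0:3))
  }
  read_u16 <- function() {
    b <- readBin(con, "raw", 2L)
    if (length(b) < 2L) abort_chick("truncated WAV header", "format_error")
    sum(as.numeric(b) * 256^(0:1))
  }

  if (!identical(read_tag(), "RIFF"))
    abort_chick(sprintf("%s: not a RIFF file", path), "format_error")
  read_u32()  # chunk size, unused
  if (!identical(read_tag(), "WAVE"))
    abort_chick(sprintf("%s: not a WAVE file", path), "format_error")

  fmt <- NULL
  data_raw <- NULL
  repeat {
    tag <- read_tag()
    if (nchar(tag) < 4L) break
    size <- read_u32()
    if (identical(tag, "fmt ")) {
      fmt <- list(code = read_u16(), channels = read_u16(),
                  rate = read_u32())
      read_u32(); read_u16()  # byte rate, block align
      fmt$bits <- read_u16()
      extra <- size - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(tag, "data")) {
      data_raw <- readBin(con, "raw", size)
      break
    } else {
      # skip unknown chunk (word-aligned)
      readBin(con, "raw", size + size %% 2)
    }
  }
  if (is.null(fmt))
    abort_chick(sprintf("%s: missing fmt chunk", path), "format_error")
  if (is.null(data_raw) || length(data_raw) == 0L)
    abort_chick(sprintf("%s: no audio samples", path), "empty_audio_error")

  code <- fmt$code
  if (code == 0xFFFE) code <- 1L  # WAVE_FORMAT_EXTENSIBLE: assume PCM payload
  bytes <- fmt$bits / 8
  n_total <- floor(length(data_raw) / (bytes * fmt$channels)) * fmt$channels
  if (n_total == 0L)
    abort_chick(sprintf("%s: no audio samples", path), "empty_audio_error")

  if (code == 1L) {
    x <- switch(as.character(fmt$bits),
      "8"  = (as.numeric(data_raw[seq_len(n_total)]) - 128) / 128,
      "16" = {
        v <- readBin(data_raw, "integer", n = n_total, size = 2L,
                     signed = TRUE, endian = "little")
        v / 32768
      },
      "24" = {
        b <- as.numeric(data_raw[seq_len(n_total * 3)])
        i <- seq(1L, length(b), by = 3L)
        v <- b[i] + 256 * b[i + 1L] + 65536 * b[i + 2L]
        v <- ifelse(v >= 2^23, v - 2^24, v)
        v / 2^23
      },
      "32" = {
        v <- readBin(data_raw, "integer", n = n_total, size = 4L,
                     endian = "little")
        v / 2^31
      },
      abort_chick(sprintf("%s: unsupported PCM bit depth %d", path, fmt$bits),
                  "format_error"))
  } else if (code == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", n = n_total, size = 4L,
                 endian = "little")
  } else {
    abort_chick(sprintf("%s: unsupported encoding (format code %d, %d bit)",
                        path, fmt$code, fmt$bits), "format_error")
  }

  if (fmt$channels > 1L) {
    x <- matrix(x, nrow = fmt$channels)
    x <- colMeans(x)
  }
  if (!all(is.finite(x)))
    abort_chick(sprintf("%s: corrupt sample data", path), "format_error")
  audio_segment(x, fmt$rate)
}

#' Write an audio segment (or channel matrix) to a PCM16 WAV file
#'
#' @param x An [audio_segment], a numeric vector, or a matrix with one
#'   column per channel.
#' @param path Output path.
#' @param rate_hz Sampling rate, ignored when `x` is an `audio_segment`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, rate_hz = 44100) {
  if (inherits(x, "audio_segment")) {
    rate_hz <- x$rate_hz
    x <- x$samples
  }
  m <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  channels <- ncol(m)
  v <- as.vector(t(m))                     # interleave channels
  v <- pmax(pmin(v, 1), -1)
  # full-scale 32768 to mirror the reader; clamp the one unrepresentable value
  pcm <- as.integer(pmax(pmin(round(v * 32768), 32767), -32768))

  con <- file(path, "wb")
  on.exit(close(con))
  u32 <- function(n) writeBin(as.integer(n), con, size = 4L, endian = "little")
  u16 <- function(n) writeBin(as.integer(n), con, size = 2L, endian = "little")
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL); u32(36L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); u32(16L)
  u16(1L); u16(channels); u32(rate_hz)
  u32(rate_hz * channels * 2L); u16(channels * 2L); u16(16L)
  writeChar("data", con, eos = NULL); u32(data_bytes)
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Split a segment into consecutive one-minute windows
#'
#' Consecutive, non-overlapping 60 s windows. A trailing remainder shorter
#' than 60 s is discarded with a warning rather than zero-padded, since
#' padding would bias spectral statistics toward silence.
#'
#' @param seg An [audio_segment].
#' @return List of `audio_segment`s, each exactly `60 * rate_hz` samples.
#' @export
minute_windows <- function(seg) {
  stopifnot(inherits(seg, "audio_segment"))
  win <- as.integer(60 * seg$rate_hz)
  n_full <- seg$n_samples %/% win
  rem <- seg$n_samples - n_full * win
  if (rem > 0)
    warn_chick(sprintf("discarding trailing %.2f s (< 60 s window)",
                       rem / seg$rate_hz), "partial_window_warning")
  if (n_full == 0L) return(list())
  lapply(seq_len(n_full), function(i) {
    audio_segment(seg$samples[((i - 1L) * win + 1L):(i * win)], seg$rate_hz)
  })
}

#' Parse recording metadata from a file name or sidecar table
#'
#' File naming convention: `<flock>_<day>_<minute>.wav`. Day of placement
#' must be 1-4 for in-scope data.
#'
#' @param file_id File name (with or without `.wav` extension).
#' @return A one-row data.frame: file_id, flock_id, day, minute_index.
#' @export
parse_recording_meta <- function(file_id) {
  base <- sub("\\.wav$", "", basename(file_id), ignore.case = TRUE)
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (length(parts) < 3L)
    abort_chick(sprintf("cannot parse metadata from '%s' (want <flock>_<day>_<minute>)",
                        file_id), "format_error")
  day <- suppressWarnings(as.integer(parts[length(parts) - 1L]))
  minute <- suppressWarnings(as.integer(parts[length(parts)]))
  if (is.na(day) || is.na(minute) || !(day %in% 1:4) || minute < 0)
    abort_chick(sprintf("invalid day/minute in '%s' (day must be 1-4)", file_id),
                "format_error")
  data.frame(file_id = base,
             flock_id = paste(parts[seq_len(length(parts) - 2L)], collapse = "_"),
             day = day, minute_index = minute,
             stringsAsFactors = FALSE)
}
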