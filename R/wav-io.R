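#' Minimal RIFF/WAVE reader
#'
#' Reads a PCM (16- or 24-bit integer) or IEEE float (32-bit) WAV file and
#' returns the first channel as a numeric vector normalized to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric, first channel), `sample_rate` (Hz),
#'   `n_channels`, and `bits_per_sample`.
#' @keywords internal
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      fmt_bytes <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format    = readBin(fmt_bytes[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels      = readBin(fmt_bytes[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate     = readBin(fmt_bytes[5:8], "integer", 1, size = 4, endian = "little"),
        bits_per_sample = readBin(fmt_bytes[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      seek(con, sz + sz %% 2L, origin = "current")  # chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw) || length(data_raw) == 0)
    stop("empty or malformed WAV file: ", path, call. = FALSE)

  bits <- fmt$bits_per_sample
  x <- switch(
    as.character(bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2L, size = 2,
                   endian = "little") / 32768,
    "24" = {
      n <- length(data_raw) / 3L
      b <- matrix(as.integer(data_raw), nrow = 3L)
      v <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = {
      if (fmt$audio_format == 3L) {
        readBin(data_raw, "double", length(data_raw) / 4L, size = 4, endian = "little")
      } else {
        readBin(data_raw, "integer", length(data_raw) / 4L, size = 4,
                endian = "little") / 2147483648
      }
    },
    stop("unsupported WAV bit depth: ", bits, call. = FALSE)
  )

  nch <- fmt$n_channels
  if (nch > 1L) {
    warning("multi-channel WAV: using first channel only", call. = FALSE)
    x <- x[seq(1L, length(x) - nch + 1L, by = nch)]
  }
  list(samples = x, sample_rate = fmt$sample_rate,
       n_channels = nch, bits_per_sample = bits)
}

#' Minimal RIFF/WAVE writer (16-bit PCM, mono)
#'
#' @param samples Numeric vector in \[-1, 1\]; values outside are clipped.
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @keywords internal
write_wav <- function(samples, path, sample_rate) {
  x <- pmin(pmax(samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")               # PCM
  writeBin(1L, con, size = 2, endian = "little")               # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")               # block align
  writeBin(16L, con, size = 2, endian = "little")              # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
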