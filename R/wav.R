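#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the stimulus audio the envelope
#' characterization consumes: linear PCM, 16- or 32-bit signed integer,
#' single channel. Samples are returned normalized to `[-1, 1]`.
#'
#' @param path file path.
#' @return list with `samples` (numeric vector in `[-1, 1]`) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little"),
        n_channels = readBin(con, "integer", 1, size = 2, endian = "little"),
        sample_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align = readBin(con, "integer", 1, size = 2, endian = "little"),
        bits = readBin(con, "integer", 1, size = 2, endian = "little"))
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("missing fmt/data chunk in ", path, call. = FALSE)
  if (fmt$audio_format != 1) stop("only linear PCM supported", call. = FALSE)
  if (fmt$n_channels != 1) stop("only mono supported", call. = FALSE)
  if (!fmt$bits %in% c(16L, 32L))
    stop("only 16/32-bit PCM supported", call. = FALSE)
  bytes <- fmt$bits %/% 8L
  samples <- readBin(data_raw, "integer", n = length(data_raw) %/% bytes,
                     size = bytes, signed = TRUE, endian = "little")
  list(samples = samples / 2^(fmt$bits - 1), sample_rate = fmt$sample_rate)
}

#' Write a mono PCM WAV file
#'
#' Companion writer to [read_wav()] (16-bit PCM). Samples outside `[-1, 1]`
#' are clipped.
#'
#' @param samples numeric vector in `[-1, 1]`.
#' @param sample_rate Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  x <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
  data_size <- length(x) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}
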