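#' Read a RIFF WAV file
#'
#' Supports uncompressed PCM (8/16/24/32-bit integer) and IEEE float
#' (32-bit) WAV. Stereo files are channel-averaged to mono. Samples are
#' returned on the [-1, 1] scale.
#'
#' @param path WAV file.
#' @return List with `samples` (numeric vector) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("audio file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_format(sprintf("%s is not a RIFF file", path))
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_format(sprintf("%s is not a WAVE file", path))
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      u16 <- function(off) sum(as.integer(fmt_raw[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.integer(fmt_raw[off + 1:4]) * 256^(0:3))
      fmt <- list(format = u16(0), channels = u16(2), rate = u32(4),
                  bits = u16(14))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop_format("malformed WAV: data before fmt chunk")
      if (!fmt$format %in% c(1L, 3L)) {
        stop_format(sprintf("unsupported (compressed) WAV format code %d",
                            fmt$format))
      }
      bytes <- fmt$bits / 8
      n <- size %/% bytes
      if (fmt$format == 3L) {
        samples <- readBin(con, "double", n, size = 4, endian = "little")
      } else if (fmt$bits == 8L) {
        samples <- (readBin(con, "integer", n, 1, signed = FALSE) - 128) / 128
      } else if (fmt$bits == 24L) {
        raw <- readBin(con, "raw", size)
        m <- matrix(as.integer(raw[seq_len(n * 3)]), nrow = 3)
        v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
        v <- ifelse(v >= 2^23, v - 2^24, v)
        samples <- v / 2^23
      } else {
        samples <- readBin(con, "integer", n, size = bytes,
                           endian = "little") / 2^(fmt$bits - 1)
      }
      if (length(samples) < n) {
        stop_format(sprintf("truncated WAV data in %s", path))
      }
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
  }
  if (is.null(fmt) || is.null(samples)) {
    stop_format(sprintf("truncated or malformed WAV file: %s", path))
  }
  if (fmt$channels > 1L) {
    nf <- length(samples) %/% fmt$channels
    samples <- rowMeans(matrix(samples[seq_len(nf * fmt$channels)],
                               ncol = fmt$channels, byrow = TRUE))
  }
  list(samples = as.numeric(samples), sample_rate = fmt$rate)
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' @param wave List with `samples` in [-1, 1] and `sample_rate`.
#' @param path Output path.
#' @export
write_wav <- function(wave, path) {
  samples <- pmin(pmax(wave$samples, -1), 1)
  pcm <- as.integer(round(samples * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(wave$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(wave$sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
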