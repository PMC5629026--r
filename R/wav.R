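#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for talker stimuli: supports PCM 8/16/24/32-bit
#' integer and 32/64-bit IEEE float samples. Multi-channel files are mixed
#' down to mono by averaging. Samples are returned as doubles in
#' `[-1, 1]`.
#'
#' @param path path to a `.wav` file.
#' @param resample_to optional target sampling rate in Hz; if given and it
#'   differs from the file's rate, the signal is resampled (polyphase
#'   resampling via the `signal` package).
#' @return numeric vector of samples; the source rate is attached as
#'   attribute `sample_rate_hz`.
#' @export
read_wav_mono <- function(path, resample_to = NULL) {
  if (!file.exists(path))
    stop("unreadable input: WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("unreadable input: not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("unreadable input: not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE,
                               endian = "little"),
        n_channels = readBin(body[3:4], "integer", 1, 2, signed = FALSE,
                             endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, signed = FALSE,
                       endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("unreadable input: missing fmt/data chunk in ", path)
  if (fmt$audio_format == 65534L) fmt$audio_format <- 1L  # WAVE_FORMAT_EXTENSIBLE

  x <- switch(as.character(fmt$audio_format),
    "1" = switch(as.character(fmt$bits),
      "8"  = (as.double(readBin(data_raw, "integer", length(data_raw), 1,
                                signed = FALSE)) - 128) / 128,
      "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                     signed = TRUE, endian = "little") / 32768,
      "24" = {
        n <- length(data_raw) / 3
        b <- matrix(as.integer(data_raw), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      },
      "32" = readBin(data_raw, "integer", length(data_raw) / 4, 4,
                     signed = TRUE, endian = "little") / 2147483648,
      stop("unsupported PCM bit depth: ", fmt$bits)),
    "3" = readBin(data_raw, "double", length(data_raw) / (fmt$bits / 8),
                  fmt$bits / 8, endian = "little"),
    stop("unsupported WAV audio format code: ", fmt$audio_format))

  if (fmt$n_channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  rate <- fmt$sample_rate
  if (!is.null(resample_to) && resample_to != rate) {
    if (!requireNamespace("signal", quietly = TRUE))
      stop("the 'signal' package is required to resample WAV input")
    g <- gcd_int(as.integer(round(resample_to)), as.integer(rate))
    x <- signal::resample(x, round(resample_to) / g, rate / g)
    rate <- resample_to
  }
  attr(x, "sample_rate_hz") <- rate
  x
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Write a stereo WAV file
#'
#' Writes 16-bit PCM. Samples outside `[-1, 1]` are clipped.
#'
#' @param samples 2 x N numeric matrix (rows = left, right) or a numeric
#'   vector for mono.
#' @param path output file path.
#' @param sample_rate_hz sampling rate to record in the header.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate_hz = 48000) {
  if (is.matrix(samples)) {
    stopifnot(nrow(samples) %in% c(1, 2))
    inter <- as.vector(samples)               # column-major = interleaved
    n_ch <- nrow(samples)
  } else {
    inter <- as.numeric(samples)
    n_ch <- 1L
  }
  pcm <- as.integer(round(pmax(-1, pmin(1, inter)) * 32767))
  byte_rate <- as.integer(sample_rate_hz * n_ch * 2)
  data_sz <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")          # PCM
  writeBin(as.integer(n_ch), con, 2, endian = "little")
  writeBin(as.integer(sample_rate_hz), con, 4, endian = "little")
  writeBin(byte_rate, con, 4, endian = "little")
  writeBin(as.integer(n_ch * 2), con, 2, endian = "little")  # block align
  writeBin(16L, con, 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
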