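#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader supporting the containers this package writes and
#' the common clinical-recorder exports: uncompressed PCM (8/16/24/32 bit) and
#' IEEE float (32/64 bit), mono or multichannel. Chunks other than `fmt ` and
#' `data` are skipped.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric matrix, one column per channel,
#'   amplitudes in `[-1, 1]`) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("audio file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file (cannot decode): ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file (cannot decode): ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels   = readBin(body[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(body[5:8], "integer", 1, size = 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))  # chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("corrupt WAV (missing fmt/data chunk), cannot decode: ", path)
  }
  # WAVE_FORMAT_EXTENSIBLE (0xFFFE) carries the real format in its extension;
  # the bit depth field is still authoritative for the PCM layouts we accept.
  x <- switch(
    as.character(fmt$audio_format),
    "1" = , "65534" = .decode_pcm(data_raw, fmt$bits),
    "3" = .decode_float(data_raw, fmt$bits),
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ") in ", path)
  )
  n <- length(x) %/% fmt$n_channels
  samples <- matrix(x[seq_len(n * fmt$n_channels)], ncol = fmt$n_channels, byrow = TRUE)
  if (any(!is.finite(samples))) stop("corrupt WAV (non-finite samples): ", path)
  list(samples = samples, sample_rate = fmt$sample_rate)
}

.decode_pcm <- function(raw, bits) {
  if (bits == 8L) {
    v <- as.integer(raw)                       # unsigned, midpoint 128
    return((v - 128) / 128)
  }
  if (bits == 16L) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2, endian = "little")
    return(v / 32768)
  }
  if (bits == 24L) {
    n <- length(raw) %/% 3L
    b <- matrix(as.integer(raw[seq_len(n * 3L)]), nrow = 3L)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    return(v / 8388608)
  }
  if (bits == 32L) {
    v <- readBin(raw, "integer", n = length(raw) %/% 4L, size = 4, endian = "little")
    return(v / 2147483648)
  }
  stop("unsupported PCM bit depth: ", bits)
}

.decode_float <- function(raw, bits) {
  size <- bits %/% 8L
  if (!size %in% c(4L, 8L)) stop("unsupported float bit depth: ", bits)
  readBin(raw, "double", n = length(raw) %/% size, size = size, endian = "little")
}

#' Write a mono or multichannel WAV file (16-bit PCM)
#'
#' Amplitudes are clipped to `[-1, 1]` before quantization.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(is.matrix(samples), sample_rate > 0)
  x <- pmin(1, pmax(-1, t(samples)))           # interleave channels
  q <- as.integer(round(as.vector(x) * 32767))
  n_channels <- ncol(samples)
  byte_rate <- sample_rate * n_channels * 2L
  data_size <- length(q) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(as.integer(n_channels), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4, endian = "little")
  writeBin(as.integer(n_channels * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}
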