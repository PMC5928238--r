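#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for PCM 16-bit and IEEE float 32-bit files.
#' Samples are returned in floating point at full scale +/- 1.0
#' regardless of the source bit depth. Multi-channel files are downmixed
#' to mono by averaging (with a warning). If `rate` is given and differs
#' from the file rate, the signal is resampled to it with a warning.
#'
#' @param path path to a .wav file.
#' @param rate target sampling rate in Hz, or `NULL` to keep the file's.
#' @return An [AudioSignal-class].
#' @seealso [writeWav()], [resampleTo()]
#' @export
readWav <- function(path, rate = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; raw_data <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audioFormat = sum(as.integer(body[1:2]) * c(1L, 256L)),
        channels = sum(as.integer(body[3:4]) * c(1L, 256L)),
        rate = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(body[15:16]) * c(1L, 256L)))
    } else if (identical(id, "data")) {
      raw_data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(raw_data)) break
  }
  if (is.null(fmt) || is.null(raw_data)) stop("missing fmt/data chunk: ", path)
  n <- length(raw_data)
  if (fmt$audioFormat == 1L && fmt$bits == 16L) {
    x <- readBin(raw_data, "integer", n %/% 2L, size = 2L, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$audioFormat == 3L && fmt$bits == 32L) {
    x <- readBin(raw_data, "numeric", n %/% 4L, size = 4L, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit)",
                 fmt$audioFormat, fmt$bits))
  }
  if (fmt$channels > 1L) {
    warning("downmixing ", fmt$channels, "-channel WAV to mono")
    x <- rowMeans(matrix(x, ncol = fmt$channels, byrow = TRUE))
  }
  sig <- audioSignal(x, fmt$rate)
  if (!is.null(rate) && rate != fmt$rate) {
    warning(sprintf("resampling %s from %g to %g Hz", basename(path),
                    fmt$rate, rate))
    sig <- resampleTo(sig, rate)
  }
  sig
}

#' Write a mono WAV file
#'
#' Writes an [AudioSignal-class] as RIFF/WAVE, either PCM 16-bit
#' (default; samples clipped to +/- 1.0 and quantized) or IEEE float
#' 32-bit.
#'
#' @param signal an [AudioSignal-class].
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
writeWav <- function(signal, path, bits = 16) {
  stopifnot(is(signal, "AudioSignal"), bits %in% c(16, 32))
  x <- samples(signal)
  fs <- round(sampleRate(signal))
  con <- file(path, "wb")
  on.exit(close(con))
  bytes <- bits / 8
  dataSize <- length(x) * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(as.integer(if (bits == 16) 1L else 3L), con, size = 2L,
           endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * bytes), con, size = 4L, endian = "little")
  writeBin(as.integer(bytes), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4L, endian = "little")
  if (bits == 16) {
    q <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(x, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Resample a signal to a new rate
#'
#' Rational-ratio polyphase resampling via the signal package.
#'
#' @param signal an [AudioSignal-class].
#' @param rate target sampling rate in Hz.
#' @return An [AudioSignal-class] at `rate`.
#' @export
resampleTo <- function(signal, rate) {
  stopifnot(is(signal, "AudioSignal"), rate > 0)
  fs <- sampleRate(signal)
  if (rate == fs) return(signal)
  frac <- .ratApprox(rate / fs)
  y <- signal::resample(samples(signal), frac[1L], frac[2L])
  audioSignal(as.numeric(y), rate)
}

## Small rational approximation p/q of a positive ratio.
.ratApprox <- function(x, maxq = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(maxq)) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(p / q - x)
    if (e < err - 1e-15) { best <- c(p, q); err <- e }
    if (err < 1e-12) break
  }
  as.integer(best)
}
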