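#' Zwicker critical-band (Bark scale) edge frequencies
#'
#' The standard critical-band edge table in Hz after Zwicker (Bark scale).
#' Consecutive entries delimit one critical band; the 17 bands between
#' 100 and 4400 Hz are the ones used for mosaic and noise-vocoded speech,
#' a range wide enough to keep vocoded speech nearly fully intelligible.
#'
#' @format Numeric vector of 26 edge frequencies (Hz), 0 to 15500.
#' @seealso [criticalBands()], [writeBandTable()]
#' @export
zwickerBandEdges <- c(
  0, 100, 200, 300, 400, 510, 630, 770, 920, 1080, 1270, 1480,
  1720, 2000, 2320, 2700, 3150, 3700, 4400, 5300, 6400, 7700,
  9500, 12000, 15500)

#' Build a critical-band partition from the Zwicker edge table
#'
#' Selects all Bark-scale band edges between `fLow` and `fHigh`
#' (inclusive); both limits must themselves be entries of the table so
#' that the partition is exact. The default 100-4400 Hz range spans 17
#' critical bands.
#'
#' @param fLow,fHigh lower and upper frequency limits in Hz; must coincide
#'   with entries of [zwickerBandEdges].
#' @return A [CriticalBandSpec-class].
#' @examples
#' criticalBands(100, 4400)   # 17 bands
#' criticalBands(100, 200)    # a single band
#' @export
criticalBands <- function(fLow = 100, fHigh = 4400) {
  if (fLow >= fHigh)
    stop("'fLow' must be smaller than 'fHigh'")
  for (f in c(fLow, fHigh)) {
    if (!any(abs(zwickerBandEdges - f) < 1e-9)) {
      below <- max(zwickerBandEdges[zwickerBandEdges < f], -Inf)
      above <- min(zwickerBandEdges[zwickerBandEdges > f], Inf)
      stop(sprintf(
        "%g Hz is not a critical-band edge; nearest valid edges are %g and %g Hz",
        f, below, above))
    }
  }
  edges <- zwickerBandEdges[zwickerBandEdges >= fLow - 1e-9 &
                            zwickerBandEdges <= fHigh + 1e-9]
  new("CriticalBandSpec", edges = edges)
}

#' Export the band-edge table as plain text
#'
#' Writes the critical-band partition as a tab-separated table with one
#' row per band (band index, lower and upper edge, bandwidth).
#'
#' @param spec a [CriticalBandSpec-class].
#' @param file path of the output file ("" prints to the console).
#' @return The table, invisibly, as a data.frame.
#' @export
writeBandTable <- function(spec, file = "") {
  stopifnot(is(spec, "CriticalBandSpec"))
  e <- bandEdges(spec)
  tab <- data.frame(band = seq_len(nBands(spec)),
                    low_hz = e[-length(e)], high_hz = e[-1L],
                    width_hz = diff(e))
  utils::write.table(tab, file = file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(tab)
}

## Two-sided FFT bin frequencies of a length-n signal at rate fs.
.binFreqs <- function(n, fs) {
  k <- 0:(n - 1L)
  pmin(k, n - k) * fs / n
}

## Zero-phase brick-wall band mask applied in the frequency domain.
## Keeps bins with lo <= f < hi (half-open, matching contiguous bands).
.maskBand <- function(X, f, lo, hi) {
  keep <- f >= lo & f < hi
  Y <- X
  Y[!keep] <- 0
  Y
}

#' Decompose a signal into critical bands
#'
#' Splits a waveform into the contiguous bands of a [CriticalBandSpec-class]
#' using zero-phase spectral masking: one forward FFT, then for each band
#' all frequency bins outside its half-open edge pair `[lo, hi)` are
#' zeroed and the band waveform recovered by the inverse transform.
#' Because every bin belongs to exactly one band, the bands sum to the
#' `[fLow, fHigh)` band-limited input to numerical precision and no group
#' delay desynchronizes the bands.
#'
#' @param signal an [AudioSignal-class].
#' @param spec a [CriticalBandSpec-class]; the signal rate must be at
#'   least twice its highest edge.
#' @return A [BandDecomposition-class].
#' @examples
#' sp <- criticalBands(100, 4400)
#' t <- seq(0, 0.2, by = 1 / 22050)
#' d <- bandDecompose(audioSignal(sin(2 * pi * 1000 * t), 22050), sp)
#' nBands(d)
#' @export
bandDecompose <- function(signal, spec) {
  stopifnot(is(signal, "AudioSignal"), is(spec, "CriticalBandSpec"))
  e <- bandEdges(spec)
  fs <- sampleRate(signal)
  if (fs < 2 * e[length(e)])
    stop(sprintf(
      "sampling rate %g Hz is too low for the highest band edge %g Hz",
      fs, e[length(e)]))
  x <- samples(signal)
  n <- length(x)
  X <- stats::fft(x)
  f <- .binFreqs(n, fs)
  B <- nBands(spec)
  bands <- matrix(0, nrow = n, ncol = B)
  for (b in seq_len(B)) {
    Yb <- .maskBand(X, f, e[b], e[b + 1L])
    bands[, b] <- Re(stats::fft(Yb, inverse = TRUE)) / n
  }
  new("BandDecomposition", bands = bands, spec = spec, rate = fs)
}

#' Band-limit a signal to a frequency range
#'
#' Zero-phase brick-wall band limiting, keeping spectral content within
#' `[fLow, fHigh)`; the exact sum of the bands a [bandDecompose()] with
#' the same edges would produce.
#'
#' @param signal an [AudioSignal-class].
#' @param fLow,fHigh band limits in Hz.
#' @return An [AudioSignal-class].
#' @export
bandLimit <- function(signal, fLow, fHigh) {
  stopifnot(is(signal, "AudioSignal"), fLow < fHigh)
  x <- samples(signal)
  n <- length(x)
  fs <- sampleRate(signal)
  X <- stats::fft(x)
  Y <- .maskBand(X, .binFreqs(n, fs), fLow, fHigh)
  audioSignal(Re(stats::fft(Y, inverse = TRUE)) / n, fs)
}

#' Total energy of a signal
#'
#' Sum of squared amplitudes (relative energy, no calibration constant).
#' @param signal an [AudioSignal-class] or numeric vector.
#' @return numeric scalar.
#' @export
signalEnergy <- function(signal) {
  x <- if (is(signal, "AudioSignal")) samples(signal) else as.numeric(signal)
  sum(x^2)
}
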