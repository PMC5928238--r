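## Full linear convolution via FFT; returns length(x) + length(h) - 1.
.convFull <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, nf - length(x))))
  H <- stats::fft(c(h, rep(0, nf - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / nf
}

## Discrete unit-area Gaussian kernel, truncated at +/- 4 sigma.
.gaussKernel <- function(sigma, rate) {
  L <- max(1L, ceiling(4 * sigma * rate))
  t <- (-L:L) / rate
  w <- exp(-t^2 / (2 * sigma^2))
  w / sum(w)
}

#' Sound-energy-density trajectory of a band signal
#'
#' Squares the waveform (instantaneous intensity, relative units) and
#' smooths it with a unit-area Gaussian window in time. The default
#' `sigma` of 5 ms is the moving-average width used throughout the
#' mosaic/vocoder pipeline. Signal edges are reflect-padded by 4 sigma
#' before the convolution so the density does not decay spuriously at
#' the boundaries; the output has the length of the input.
#'
#' @param band an [AudioSignal-class] (typically one critical band).
#' @param sigma Gaussian width in seconds (> 0).
#' @return An [EnergyTrajectory-class].
#' @examples
#' t <- seq(0, 0.5, by = 1 / 22050)
#' tr <- energyTrajectory(audioSignal(0.5 * sin(2 * pi * 500 * t), 22050))
#' mean(densityValues(tr))   # ~ 0.5^2 / 2
#' @export
energyTrajectory <- function(band, sigma = 0.005) {
  stopifnot(is(band, "AudioSignal"))
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number (seconds)")
  fs <- sampleRate(band)
  d <- .smoothDensity(samples(band)^2, sigma, fs)
  new("EnergyTrajectory", density = d, rate = fs, sigma = sigma)
}

## Gaussian smoothing of a nonnegative intensity vector with reflect
## padding; shared by energyTrajectory() and the resynthesis loops that
## work on raw matrices.
.smoothDensity <- function(intensity, sigma, rate) {
  w <- .gaussKernel(sigma, rate)
  L <- (length(w) - 1L) %/% 2L
  n <- length(intensity)
  padL <- intensity[pmin(pmax(seq(L + 1L, 2L, by = -1L), 1L), n)]
  padR <- intensity[pmin(pmax(seq(n - 1L, n - L, by = -1L), 1L), n)]
  y <- .convFull(c(padL, intensity, padR), w)
  d <- y[(2L * L + 1L):(2L * L + n)]
  pmax(d, 0)  # clip FFT round-off below zero
}

#' Average energy densities over fixed time segments
#'
#' Cuts each band's energy-density trajectory into half-open segments
#' `[s * T, (s + 1) * T)` starting at the first sample and averages within
#' each, producing the B x S matrix of "mosaic tiles". The final segment
#' may be shorter than the nominal duration.
#'
#' @param trajectories a list of [EnergyTrajectory-class] objects (one per
#'   band, equal length and rate), a single trajectory, or a
#'   [BandDecomposition-class] (trajectories are computed with `sigma`).
#' @param segmentMs segment duration in milliseconds (> 0).
#' @param spec optional [CriticalBandSpec-class] recorded in the result;
#'   mandatory metadata when `trajectories` is not a decomposition.
#' @param sigma Gaussian width (s) used when `trajectories` is a
#'   [BandDecomposition-class].
#' @return An [EnergyBlockMatrix-class].
#' @examples
#' tr <- new("EnergyTrajectory", density = c(1, 1, 3, 3, 5), rate = 1000,
#'           sigma = 0.005)
#' blockValues(blockAverage(tr, 2, spec = criticalBands(100, 200)))
#' @export
blockAverage <- function(trajectories, segmentMs, spec = NULL,
                         sigma = 0.005) {
  if (is(trajectories, "BandDecomposition")) {
    dec <- trajectories
    spec <- dec@spec
    fs <- dec@rate
    dens <- apply(bandSignals(dec), 2L, function(x)
      .smoothDensity(x^2, sigma, fs))
  } else {
    if (is(trajectories, "EnergyTrajectory"))
      trajectories <- list(trajectories)
    stopifnot(length(trajectories) >= 1L,
              all(vapply(trajectories, is, logical(1), "EnergyTrajectory")))
    fs <- sampleRate(trajectories[[1L]])
    lens <- vapply(trajectories, length, integer(1))
    if (length(unique(lens)) != 1L ||
        length(unique(vapply(trajectories, sampleRate, numeric(1)))) != 1L)
      stop("all trajectories must share one length and one rate")
    dens <- vapply(trajectories, densityValues, numeric(lens[1L]))
    if (is.null(spec))
      stop("'spec' is required when passing trajectories directly")
  }
  dens <- as.matrix(dens)
  n <- nrow(dens)
  if (n < 1L) stop("empty trajectory")
  if (segmentMs <= 0) stop("'segmentMs' must be > 0")
  segLen <- max(1L, round(segmentMs / 1000 * fs))
  vals <- .blockMeans(dens, segLen)
  new("EnergyBlockMatrix", values = vals, segmentMs = as.numeric(segmentMs),
      spec = spec, nSamples = as.integer(n), rate = fs)
}

## Per-sample segment index for a length-n signal (half-open windows
## [s*T, (s+1)*T), origin at the first sample).
.segmentIndex <- function(n, segLen) {
  rep(seq_len(ceiling(n / segLen)), each = segLen, length.out = n)
}

## Raw per-segment means of an n x B density matrix -> B x S matrix.
.blockMeans <- function(dens, segLen) {
  dens <- as.matrix(dens)
  grp <- .segmentIndex(nrow(dens), segLen)
  out <- t(rowsum(dens, grp, reorder = TRUE) / as.numeric(table(grp)))
  dimnames(out) <- NULL
  out
}
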