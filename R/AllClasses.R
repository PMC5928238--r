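#' @import methods
NULL

#' AudioSignal: a sampled mono waveform
#'
#' The universal currency of the DSP layer: a mono waveform in floating
#' point at full scale +/- 1.0 together with its sampling rate in Hz.
#' Amplitudes are dimensionless; all energy quantities derived from an
#' `AudioSignal` are relative (no SPL calibration).
#'
#' @slot samples numeric vector of finite amplitudes.
#' @slot rate sampling frequency in Hz (scalar, > 0).
#'
#' @seealso [audioSignal()], [samples()], [sampleRate()], [readWav()]
#' @export
setClass("AudioSignal",
  representation(samples = "numeric", rate = "numeric"))

setValidity("AudioSignal", function(object) {
  msg <- NULL
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "'rate' must be a single positive finite number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "'samples' must contain at least one sample")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Construct an AudioSignal
#'
#' @param samples numeric amplitude vector, full scale +/- 1.0.
#' @param rate sampling frequency in Hz.
#' @return An [AudioSignal-class] object.
#' @examples
#' s <- audioSignal(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 22050)), 22050)
#' duration(s)
#' @export
audioSignal <- function(samples, rate = 22050) {
  new("AudioSignal", samples = as.numeric(samples), rate = as.numeric(rate))
}

#' CriticalBandSpec: contiguous critical-band edges
#'
#' An ordered set of band-edge frequencies partitioning a frequency range
#' into contiguous bands; band `i` covers `[edges[i], edges[i + 1])`.
#' Normally built from the Zwicker Bark-scale edge table via
#' [criticalBands()].
#'
#' @slot edges strictly increasing frequency values in Hz, length B + 1
#'   for B bands.
#' @seealso [criticalBands()], [zwickerBandEdges]
#' @export
setClass("CriticalBandSpec", representation(edges = "numeric"))

setValidity("CriticalBandSpec", function(object) {
  e <- object@edges
  msg <- NULL
  if (length(e) < 2L) msg <- c(msg, "need at least two edges (one band)")
  if (anyNA(e) || any(!is.finite(e))) msg <- c(msg, "edges must be finite")
  else {
    if (any(diff(e) <= 0)) msg <- c(msg, "edges must be strictly increasing")
    if (e[1L] < 0) msg <- c(msg, "edges must be nonnegative")
  }
  if (is.null(msg)) TRUE else msg
})

#' BandDecomposition: a signal split into critical bands
#'
#' Holds the per-band waveforms of a critical-band decomposition as the
#' columns of a samples-by-bands matrix, all at the rate of the source
#' signal. Because bands are realized as disjoint zero-phase spectral
#' masks, the rowSums of `bands` reconstruct the band-limited input
#' to numerical precision.
#'
#' @slot bands numeric matrix, one column per band.
#' @slot spec the [CriticalBandSpec-class] that produced it.
#' @slot rate sampling rate in Hz.
#' @seealso [bandDecompose()], [bandSignals()]
#' @export
setClass("BandDecomposition",
  representation(bands = "matrix", spec = "CriticalBandSpec",
                 rate = "numeric"))

setValidity("BandDecomposition", function(object) {
  msg <- NULL
  if (ncol(object@bands) != nBands(object@spec))
    msg <- c(msg, "number of band columns must equal the band count of 'spec'")
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "'rate' must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' EnergyTrajectory: smoothed sound-energy density over time
#'
#' The instantaneous squared amplitude of a (band-limited) signal smoothed
#' by a unit-area Gaussian window in time; same length as the source
#' signal. Units are amplitude^2 (relative intensity).
#'
#' @slot density nonnegative density per sample.
#' @slot rate sampling rate in Hz.
#' @slot sigma Gaussian smoothing width in seconds.
#' @seealso [energyTrajectory()]
#' @export
setClass("EnergyTrajectory",
  representation(density = "numeric", rate = "numeric", sigma = "numeric"))

setValidity("EnergyTrajectory", function(object) {
  msg <- NULL
  if (any(object@density < 0)) msg <- c(msg, "density values must be >= 0")
  if (length(object@sigma) != 1L || object@sigma <= 0)
    msg <- c(msg, "'sigma' must be a single positive number")
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "'rate' must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' EnergyBlockMatrix: the mosaic tiles
#'
#' Per-band, per-segment average sound-energy densities: the B x S grid of
#' "mosaic tiles" obtained by cutting each band's energy trajectory into
#' fixed time segments and averaging within each. The final segment may be
#' shorter than the nominal duration (S = ceiling(duration / segment)).
#'
#' @slot values B x S nonnegative matrix of mean densities (amplitude^2).
#' @slot segmentMs segment duration in milliseconds.
#' @slot spec the [CriticalBandSpec-class] of the rows.
#' @slot nSamples number of samples of the source signal.
#' @slot rate sampling rate in Hz.
#' @seealso [blockAverage()], [mosaicize()]
#' @export
setClass("EnergyBlockMatrix",
  representation(values = "matrix", segmentMs = "numeric",
                 spec = "CriticalBandSpec", nSamples = "integer",
                 rate = "numeric"))

setValidity("EnergyBlockMatrix", function(object) {
  msg <- NULL
  if (any(object@values < 0)) msg <- c(msg, "block values must be >= 0")
  if (length(object@segmentMs) != 1L || object@segmentMs <= 0)
    msg <- c(msg, "'segmentMs' must be a single positive number")
  if (nrow(object@values) != nBands(object@spec))
    msg <- c(msg, "row count must equal the band count of 'spec'")
  segLen <- max(1L, round(object@segmentMs / 1000 * object@rate))
  if (ncol(object@values) != ceiling(object@nSamples / segLen))
    msg <- c(msg, "column count must be ceiling(nSamples / segment length)")
  if (is.null(msg)) TRUE else msg
})

#' RampSpec: per-segment onset/offset ramps
#'
#' Rise and fall times applied inside each temporal segment to suppress
#' spectral splatter at segment boundaries. The ramps are raised-cosine
#' (Hann half-windows) and are contained within the segment: if a
#' (final, partial) segment is shorter than rise + fall, both shrink
#' proportionally.
#'
#' @slot riseMs rise time in ms (>= 0).
#' @slot fallMs fall time in ms (>= 0).
#' @slot shape ramp family identifier; only `"hann"` is implemented.
#' @seealso [rampSpec()], [gridSmooth()], [localTimeReverse()], [mosaicize()]
#' @export
setClass("RampSpec",
  representation(riseMs = "numeric", fallMs = "numeric", shape = "character"))

setValidity("RampSpec", function(object) {
  msg <- NULL
  if (object@riseMs < 0 || object@fallMs < 0)
    msg <- c(msg, "rise and fall times must be >= 0")
  if (!identical(object@shape, "hann"))
    msg <- c(msg, "only the 'hann' (raised-cosine) ramp shape is implemented")
  if (is.null(msg)) TRUE else msg
})

#' Construct a RampSpec
#'
#' @param riseMs,fallMs rise and fall times in milliseconds. The study
#'   default is 5 ms each.
#' @param shape ramp family; `"hann"` raised-cosine half-windows.
#' @return A [RampSpec-class] object.
#' @export
rampSpec <- function(riseMs = 5, fallMs = 5, shape = "hann") {
  new("RampSpec", riseMs = as.numeric(riseMs), fallMs = as.numeric(fallMs),
      shape = shape)
}

#' FriedmanResult: Friedman two-way ANOVA by ranks
#'
#' Result container for the Friedman test on an N (subjects) x k
#' (conditions) matrix: the tie-corrected statistic, its p value
#' (exact permutation null for small designs, chi-squared otherwise)
#' and the column rank sums needed for post-hoc comparisons.
#'
#' @slot Fr Friedman statistic (tie-corrected, >= 0).
#' @slot N number of rows (subjects).
#' @slot k number of columns (conditions).
#' @slot p p value.
#' @slot pMethod `"exact"` or `"chisq"`.
#' @slot rankSums per-column sums of within-row mid-ranks.
#' @seealso [friedmanRanks()], [multipleComparisons()]
#' @export
setClass("FriedmanResult",
  representation(Fr = "numeric", N = "integer", k = "integer", p = "numeric",
                 pMethod = "character", rankSums = "numeric"))

setValidity("FriedmanResult", function(object) {
  msg <- NULL
  if (object@Fr < -1e-9) msg <- c(msg, "'Fr' must be >= 0")
  if (object@k < 2L) msg <- c(msg, "'k' must be >= 2")
  if (object@N < 2L) msg <- c(msg, "'N' must be >= 2")
  if (is.null(msg)) TRUE else msg
})

#' QCReport: quality-control summary for one stimulus
#'
#' Spectrographic QC of a generated stimulus against its source:
#' block-energy deviation (how closely the stimulus' mosaic tiles match
#' the source's), within-segment flatness of the stimulus' band densities,
#' out-of-band splatter, plus duration and RMS level, each flagged
#' against documented thresholds.
#'
#' @slot blockDevMaxDb,blockDevMeanDb max/mean per-block absolute deviation
#'   (dB) over non-silent blocks.
#' @slot flatnessDb maximum within-segment density excursion (dB).
#' @slot splatterDb out-of-band to in-band energy ratio (dB).
#' @slot durationS stimulus duration in seconds.
#' @slot rms root-mean-square amplitude.
#' @slot flags named logical vector of pass flags.
#' @slot thresholds named numeric vector of the thresholds used.
#' @seealso [qcStimulus()]
#' @export
setClass("QCReport",
  representation(blockDevMaxDb = "numeric", blockDevMeanDb = "numeric",
                 flatnessDb = "numeric", splatterDb = "numeric",
                 durationS = "numeric", rms = "numeric",
                 flags = "logical", thresholds = "numeric"))

setValidity("QCReport", function(object) {
  if (any(!is.finite(c(object@blockDevMaxDb, object@blockDevMeanDb))))
    "block deviations must be finite" else TRUE
})
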