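#' @rdname AudioSignal-class
#' @export
setMethod("samples", "AudioSignal", function(x) x@samples)

#' @rdname AudioSignal-class
#' @export
setMethod("sampleRate", "AudioSignal", function(x) x@rate)

#' @rdname AudioSignal-class
#' @export
setMethod("duration", "AudioSignal",
          function(x) length(x@samples) / x@rate)

#' @rdname AudioSignal-class
#' @export
setMethod("length", "AudioSignal", function(x) length(x@samples))

setMethod("show", "AudioSignal", function(object) {
  cat(sprintf("AudioSignal: %d samples @ %g Hz (%.3f s), RMS %.4g\n",
              length(object@samples), object@rate,
              length(object@samples) / object@rate,
              sqrt(mean(object@samples^2))))
})

#' @rdname CriticalBandSpec-class
#' @export
setMethod("bandEdges", "CriticalBandSpec", function(x) x@edges)

#' @rdname CriticalBandSpec-class
#' @export
setMethod("nBands", "CriticalBandSpec", function(x) length(x@edges) - 1L)

setMethod("show", "CriticalBandSpec", function(object) {
  e <- object@edges
  cat(sprintf("CriticalBandSpec: %d bands, %g-%g Hz\n",
              length(e) - 1L, e[1L], e[length(e)]))
  cat("  edges (Hz): ", paste(format(e, trim = TRUE), collapse = ", "),
      "\n", sep = "")
})

#' @rdname BandDecomposition-class
#' @export
setMethod("bandSignals", "BandDecomposition", function(x) x@bands)

#' @rdname BandDecomposition-class
#' @export
setMethod("nBands", "BandDecomposition", function(x) nBands(x@spec))

#' @rdname BandDecomposition-class
#' @export
setMethod("sampleRate", "BandDecomposition", function(x) x@rate)

setMethod("show", "BandDecomposition", function(object) {
  cat(sprintf("BandDecomposition: %d bands x %d samples @ %g Hz\n",
              ncol(object@bands), nrow(object@bands), object@rate))
})

#' @rdname EnergyTrajectory-class
#' @export
setMethod("densityValues", "EnergyTrajectory", function(x) x@density)

#' @rdname EnergyTrajectory-class
#' @export
setMethod("sampleRate", "EnergyTrajectory", function(x) x@rate)

#' @rdname EnergyTrajectory-class
#' @export
setMethod("length", "EnergyTrajectory", function(x) length(x@density))

setMethod("show", "EnergyTrajectory", function(object) {
  cat(sprintf(
    "EnergyTrajectory: %d samples @ %g Hz, sigma = %g ms, mean %.4g\n",
    length(object@density), object@rate, 1000 * object@sigma,
    mean(object@density)))
})

#' @rdname EnergyBlockMatrix-class
#' @export
setMethod("blockValues", "EnergyBlockMatrix", function(x) x@values)

#' @rdname EnergyBlockMatrix-class
#' @export
setMethod("nBands", "EnergyBlockMatrix", function(x) nrow(x@values))

#' Number of temporal segments of a block matrix
#' @param x an [EnergyBlockMatrix-class].
#' @return integer segment count S.
#' @export
nSegments <- function(x) {
  stopifnot(is(x, "EnergyBlockMatrix"))
  ncol(x@values)
}

setMethod("show", "EnergyBlockMatrix", function(object) {
  cat(sprintf(
    "EnergyBlockMatrix: %d bands x %d segments (%g ms), source %d samples\n",
    nrow(object@values), ncol(object@values), object@segmentMs,
    object@nSamples))
})

setMethod("show", "RampSpec", function(object) {
  cat(sprintf("RampSpec: rise %g ms, fall %g ms, shape '%s'\n",
              object@riseMs, object@fallMs, object@shape))
})

setMethod("show", "FriedmanResult", function(object) {
  cat(sprintf(
    "Friedman two-way ANOVA by ranks: N = %d, k = %d, Fr = %.4g, p %s (%s)\n",
    object@N, object@k, object@Fr,
    if (object@p < 0.001) "< 0.001" else sprintf("= %.4g", object@p),
    object@pMethod))
  cat("  rank sums:", paste(format(object@rankSums), collapse = ", "), "\n")
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:\n")
  cat(sprintf("  block deviation: max %.3f dB, mean %.3f dB\n",
              object@blockDevMaxDb, object@blockDevMeanDb))
  cat(sprintf("  flatness: %.3f dB; splatter: %.2f dB\n",
              object@flatnessDb, object@splatterDb))
  cat(sprintf("  duration %.3f s, RMS %.4g\n", object@durationS, object@rms))
  ok <- object@flags
  cat("  flags: ",
      paste(sprintf("%s=%s", names(ok), ifelse(ok, "pass", "FAIL")),
            collapse = ", "), "\n", sep = "")
})

#' Did a QC report pass all checks?
#' @param report a [QCReport-class].
#' @return logical scalar.
#' @export
qcPassed <- function(report) {
  stopifnot(is(report, "QCReport"))
  all(report@flags)
}
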