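#' @rdname AudioSignal-class
#' @param object,x an object.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname AudioSignal-class
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname AudioSignal-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname CriticalBandSpec-class
#' @param x an object.
#' @export
setGeneric("bandEdges", function(x) standardGeneric("bandEdges"))

#' @rdname CriticalBandSpec-class
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname BandDecomposition-class
#' @param x an object.
#' @export
setGeneric("bandSignals", function(x) standardGeneric("bandSignals"))

#' @rdname EnergyBlockMatrix-class
#' @param x an object.
#' @export
setGeneric("blockValues", function(x) standardGeneric("blockValues"))

#' @rdname EnergyTrajectory-class
#' @param x an object.
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))
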