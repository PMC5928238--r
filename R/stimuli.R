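## Run expr with a private RNG stream when seed is given, restoring the
## caller's .Random.seed afterwards; deterministic output for a fixed seed.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

## Hann (raised-cosine) half-window ramps for one segment of segLen
## samples, contained within the segment. Shrinks proportionally when the
## segment is shorter than rise + fall.
.segmentEnvelope <- function(segLen, riseN, fallN) {
  env <- rep(1, segLen)
  if (riseN + fallN > segLen && riseN + fallN > 0L) {
    shrink <- segLen / (riseN + fallN)
    riseN <- floor(riseN * shrink)
    fallN <- floor(fallN * shrink)
  }
  if (riseN > 0L)
    env[seq_len(riseN)] <- sin(pi / 2 * (seq_len(riseN) - 0.5) / riseN)^2
  if (fallN > 0L)
    env[segLen - fallN + seq_len(fallN)] <-
      sin(pi / 2 * (seq(fallN, 1L) - 0.5) / fallN)^2
  env
}

## Full-length per-segment ramp envelope for an n-sample signal.
.gridEnvelope <- function(n, rate, segmentMs, ramp) {
  segLen <- max(1L, round(segmentMs / 1000 * rate))
  riseN <- round(ramp@riseMs / 1000 * rate)
  fallN <- round(ramp@fallMs / 1000 * rate)
  starts <- seq(1L, n, by = segLen)
  env <- numeric(n)
  for (s in starts) {
    len <- min(segLen, n - s + 1L)
    env[s:(s + len - 1L)] <- .segmentEnvelope(len, riseN, fallN)
  }
  env
}

#' Shape a waveform with a temporal grid of onset/offset ramps
#'
#' Leaves the waveform untouched except within the per-segment rise and
#' fall regions, where the raised-cosine ramp envelope multiplies it -
#' the control condition in which original speech is given the same
#' temporal grid as the degraded stimuli (the spectrogram shows these as
#' thin vertical energy dips at segment boundaries).
#'
#' @param signal an [AudioSignal-class].
#' @param segmentMs grid window duration in ms.
#' @param ramp a [RampSpec-class]; `rampSpec(0, 0)` is the identity.
#' @return An [AudioSignal-class] of the same length.
#' @export
gridSmooth <- function(signal, segmentMs, ramp = rampSpec()) {
  stopifnot(is(signal, "AudioSignal"), is(ramp, "RampSpec"), segmentMs > 0)
  x <- samples(signal)
  env <- .gridEnvelope(length(x), sampleRate(signal), segmentMs, ramp)
  audioSignal(x * env, sampleRate(signal))
}

#' Locally time-reverse a waveform
#'
#' Cuts the signal into half-open segments `[s * T, (s + 1) * T)` and
#' reverses each segment's waveform in place (the final, possibly
#' shorter, segment is reversed within its own extent). Without ramps
#' the operation is an exact involution and an exact energy-preserving
#' permutation of the samples; with a [RampSpec-class] each segment is
#' additionally shaped with rise/fall ramps to suppress the click-like
#' spectral splatter of the abrupt segment edges.
#'
#' @param signal an [AudioSignal-class].
#' @param segmentMs segment duration in ms.
#' @param ramp a [RampSpec-class], or `NULL` for no smoothing.
#' @return An [AudioSignal-class] of the same length.
#' @examples
#' s <- audioSignal(rnorm(882), 22050)
#' r <- localTimeReverse(s, 20)
#' identical(samples(localTimeReverse(r, 20)), samples(s))  # involution
#' @export
localTimeReverse <- function(signal, segmentMs, ramp = NULL) {
  stopifnot(is(signal, "AudioSignal"), segmentMs > 0)
  x <- samples(signal)
  n <- length(x)
  fs <- sampleRate(signal)
  segLen <- max(1L, round(segmentMs / 1000 * fs))
  idx <- seq_len(n)
  grp <- .segmentIndex(n, segLen)
  rev_idx <- stats::ave(idx, grp, FUN = rev)
  y <- x[rev_idx]
  if (!is.null(ramp)) {
    stopifnot(is(ramp, "RampSpec"))
    y <- y * .gridEnvelope(n, fs, segmentMs, ramp)
  }
  audioSignal(y, fs)
}

#' Mosaicize a speech signal in time and frequency
#'
#' Converts speech into "mosaic speech": the signal is decomposed into
#' the critical bands of `spec`, each band's Gaussian-smoothed
#' sound-energy-density trajectory is averaged within fixed temporal
#' segments ([blockAverage()]), and each time-by-frequency tile is
#' replaced by a portion of band-limited noise carrying the same average
#' energy density, shaped per segment with rise/fall ramps. Each tile is
#' thus statically flat: a steady-state local spectrum, the auditory
#' analogue of a pixelated image.
#'
#' One continuous noise carrier per band is used, with a piecewise-
#' constant per-segment gain, so each tile keeps the statistics of a
#' steady band noise. Gains are refined iteratively: the finished
#' stimulus is re-decomposed and re-measured with the same trajectory +
#' block pipeline and the gains corrected until its block densities
#' match the target tiles (this absorbs the carrier's own level
#' fluctuation and the ramp/smoothing losses).
#'
#' @param signal an [AudioSignal-class].
#' @param spec a [CriticalBandSpec-class] (default 17 bands, 0.1-4.4 kHz).
#' @param segmentMs mosaic tile duration in ms (study values 20, 40, 80,
#'   160, 320).
#' @param ramp a [RampSpec-class]; default 5-ms raised-cosine rise/fall.
#' @param seed integer seed for the noise carriers; a fixed seed gives a
#'   bit-identical stimulus.
#' @param sigma Gaussian density-smoothing width in seconds (default 5 ms).
#' @param floor silence floor: target densities below it map to zero gain.
#' @param nIter per-tile gain-refinement iterations.
#' @return An [AudioSignal-class] of the same length and rate.
#' @export
mosaicize <- function(signal, spec = criticalBands(100, 4400), segmentMs,
                      ramp = rampSpec(), seed = NULL, sigma = 0.005,
                      floor = 1e-10, nIter = 5L) {
  stopifnot(is(signal, "AudioSignal"), is(spec, "CriticalBandSpec"),
            is(ramp, "RampSpec"), segmentMs > 0)
  fs <- sampleRate(signal)
  n <- length(signal)
  target <- blockValues(blockAverage(bandDecompose(signal, spec),
                                     segmentMs, sigma = sigma))
  B <- nrow(target)
  S <- ncol(target)
  segLen <- max(1L, round(segmentMs / 1000 * fs))
  grp <- .segmentIndex(n, segLen)
  env <- .gridEnvelope(n, fs, segmentMs, ramp)

  carriers <- .withSeed(seed, {
    noise <- audioSignal(stats::rnorm(n), fs)
    bandSignals(bandDecompose(noise, spec))
  })
  enveloped <- carriers * env

  silent <- target <= floor
  gains <- matrix(0, B, S)
  ## initial gains from each enveloped carrier's own tile densities
  for (b in seq_len(B)) {
    cb <- .blockMeans(.smoothDensity(enveloped[, b]^2, sigma, fs), segLen)
    gains[b, ] <- ifelse(silent[b, ] | cb <= 0, 0, sqrt(target[b, ] / cb))
  }
  build <- function(g) {
    out <- numeric(n)
    for (b in seq_len(B)) out <- out + enveloped[, b] * g[b, grp]
    out
  }
  out <- build(gains)
  ## refinement: re-measure through the full analysis pipeline
  for (i in seq_len(nIter)) {
    meas <- blockValues(blockAverage(
      bandDecompose(audioSignal(out, fs), spec), segmentMs, sigma = sigma))
    corr <- ifelse(silent | meas <= 0, 1, sqrt(target / pmax(meas, floor)))
    gains <- gains * corr
    out <- build(gains)
  }
  audioSignal(out, fs)
}

#' Noise-vocode a speech signal
#'
#' Classic channel-vocoder resynthesis on the critical-band grid: a white
#' noise as long as the signal (plus temporal margins, trimmed after
#' modulation) is decomposed into the same bands; each band noise's own
#' energy-density trajectory is measured with the same Gaussian moving
#' average as the speech target, and the noise is amplitude-modulated by
#' `sqrt(target / own)` so its density follows the speech band's density.
#' The modulated bands are summed. Pitch and temporal fine structure of
#' the original are discarded; the per-band intensity fluctuation is
#' preserved.
#'
#' Because a 100-Hz-wide band noise's own envelope fluctuates on a
#' timescale comparable to the smoothing window, a single gain division
#' cancels that fluctuation only partially; `nIter` additional
#' fixed-point corrections of each band's own density sharpen the
#' tracking. As in a classic channel vocoder, each modulated band is
#' band-pass filtered again (re-masked to its own band) so the gain
#' modulation cannot spread energy into neighboring channels.
#'
#' @inheritParams mosaicize
#' @param floor silence floor: gain division is floored at it and target
#'   densities below it map to zero.
#' @param nIter per-band gain-correction iterations after the initial
#'   density division.
#' @return An [AudioSignal-class] of the same length and rate.
#' @export
vocode <- function(signal, spec = criticalBands(100, 4400), seed = NULL,
                   sigma = 0.005, floor = 1e-10, nIter = 2L) {
  stopifnot(is(signal, "AudioSignal"), is(spec, "CriticalBandSpec"))
  fs <- sampleRate(signal)
  n <- length(signal)
  dec <- bandDecompose(signal, spec)
  target <- apply(bandSignals(dec), 2L, function(x)
    .smoothDensity(x^2, sigma, fs))

  margin <- ceiling(4 * sigma * fs)
  noiseBands <- .withSeed(seed, {
    noise <- audioSignal(stats::rnorm(n + 2L * margin), fs)
    bandSignals(bandDecompose(noise, spec))
  })
  core <- (margin + 1L):(margin + n)
  e <- bandEdges(spec)
  f <- .binFreqs(n, fs)
  remask <- function(y, b) {
    Y <- .maskBand(stats::fft(y), f, e[b], e[b + 1L])
    Re(stats::fft(Y, inverse = TRUE)) / n
  }
  out <- numeric(n)
  for (b in seq_len(ncol(noiseBands))) {
    nb <- noiseBands[core, b]
    own <- .smoothDensity(nb^2, sigma, fs)
    g <- sqrt(target[, b] / pmax(own, floor))
    g[target[, b] <= floor] <- 0
    for (i in seq_len(nIter)) {
      own <- .smoothDensity(remask(nb * g, b)^2, sigma, fs)
      g <- g * sqrt(target[, b] / pmax(own, floor))
      g[target[, b] <= floor] <- 0
    }
    out <- out + remask(nb * g, b)
  }
  audioSignal(out, fs)
}

#' Equalize sound energy per unit time across stimuli
#'
#' Rescales each stimulus so its mean squared amplitude over its full
#' duration equals `referencePower`, as done before presenting the
#' stimulus set to listeners.
#'
#' @param stimuli a list of [AudioSignal-class] objects (a single signal
#'   is accepted).
#' @param referencePower target mean square amplitude (amplitude^2).
#' @return A list of rescaled [AudioSignal-class] objects (or a single
#'   signal if a single one was given).
#' @export
equalizeEnergy <- function(stimuli, referencePower = 0.01) {
  single <- is(stimuli, "AudioSignal")
  if (single) stimuli <- list(stimuli)
  stopifnot(all(vapply(stimuli, is, logical(1), "AudioSignal")),
            referencePower > 0)
  out <- lapply(stimuli, function(s) {
    p <- mean(samples(s)^2)
    if (p <= 0) stop("cannot equalize a silent stimulus")
    audioSignal(samples(s) * sqrt(referencePower / p), sampleRate(s))
  })
  if (single) out[[1L]] else out
}

#' The stimulus-type vocabulary
#'
#' The four stimulus types of the design: grid-smoothed original speech,
#' mosaic speech, and locally time-reversed speech with
#' (`ltr_smoothed`) and without (`ltr_raw`) 5-ms rise/fall times.
#' @return character vector of the four type identifiers.
#' @export
stimulusTypes <- function() {
  c("original_gridded", "mosaic", "ltr_smoothed", "ltr_raw")
}

#' Build the condition matrix of an experiment design
#'
#' Full Cartesian product of stimulus types and temporal-grid durations
#' in stable type-major order. The full design crosses the 4 types with 5
#' durations (20, 40, 80, 160, 320 ms) into 20 conditions.
#'
#' @param types character vector of stimulus types (subset of
#'   [stimulusTypes()]), no duplicates.
#' @param durationsMs numeric vector of segment durations in ms, no
#'   duplicates.
#' @return data.frame with columns `stimType`, `segmentMs`, one row per
#'   condition.
#' @examples
#' nrow(buildConditionMatrix(stimulusTypes(), c(20, 40, 80, 160, 320)))
#' @export
buildConditionMatrix <- function(types = stimulusTypes(),
                                 durationsMs = c(20, 40, 80, 160, 320)) {
  if (length(types) < 1L || length(durationsMs) < 1L)
    stop("'types' and 'durationsMs' must be nonempty")
  if (anyDuplicated(types)) stop("duplicate stimulus types")
  if (anyDuplicated(durationsMs)) stop("duplicate durations")
  bad <- setdiff(types, stimulusTypes())
  if (length(bad))
    stop("unknown stimulus type(s): ", paste(bad, collapse = ", "))
  if (any(durationsMs <= 0)) stop("durations must be > 0")
  data.frame(
    stimType = rep(types, each = length(durationsMs)),
    segmentMs = rep(as.numeric(durationsMs), times = length(types)),
    stringsAsFactors = FALSE)
}

#' Generate one stimulus for a design condition
#'
#' Dispatches to [gridSmooth()], [mosaicize()] or [localTimeReverse()]
#' according to the stimulus type of a condition row.
#'
#' @param signal an [AudioSignal-class].
#' @param stimType one of [stimulusTypes()].
#' @param segmentMs temporal grid duration in ms.
#' @param spec a [CriticalBandSpec-class] (used by `"mosaic"`).
#' @param rampMs ramp duration in ms for the smoothed types.
#' @param seed integer noise seed (used by `"mosaic"`).
#' @return An [AudioSignal-class].
#' @export
makeStimulus <- function(signal, stimType, segmentMs,
                         spec = criticalBands(100, 4400), rampMs = 5,
                         seed = NULL) {
  stimType <- match.arg(stimType, stimulusTypes())
  ramp <- rampSpec(rampMs, rampMs)
  switch(stimType,
    original_gridded = gridSmooth(signal, segmentMs, ramp),
    mosaic = mosaicize(signal, spec, segmentMs, ramp, seed = seed),
    ltr_smoothed = localTimeReverse(signal, segmentMs, ramp),
    ltr_raw = localTimeReverse(signal, segmentMs, NULL))
}
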