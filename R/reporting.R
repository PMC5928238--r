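## Out-of-band to in-band energy ratio (dB) of a signal relative to a
## band partition's outer edges.
.splatterDb <- function(signal, spec) {
  e <- bandEdges(spec)
  x <- samples(signal)
  n <- length(x)
  X2 <- Mod(stats::fft(x))^2
  f <- .binFreqs(n, sampleRate(signal))
  inBand <- f >= e[1L] & f < e[length(e)]
  inE <- sum(X2[inBand])
  outE <- sum(X2[!inBand])
  10 * log10(max(outE, .Machine$double.xmin) / max(inE, .Machine$double.xmin))
}

## Upper-quantile within-tile coefficient of variation of per-band
## densities over live tiles, excluding ramp regions plus a smoothing
## guard. The upper tail is where non-stationary tiles show up.
.tileCv <- function(dens, liveTiles, segLen, guard, q = 0.9) {
  n <- nrow(dens)
  grp <- .segmentIndex(n, segLen)
  cvs <- numeric(0)
  for (s in seq_len(max(grp))) {
    idx <- which(grp == s)
    if (length(idx) <= 2L * guard + 8L) next
    idx <- idx[(guard + 1L):(length(idx) - guard)]
    for (b in seq_len(ncol(dens))) {
      if (!liveTiles[b, s]) next
      d <- dens[idx, b]
      m <- mean(d)
      if (m > 0) cvs <- c(cvs, stats::sd(d) / m)
    }
  }
  if (length(cvs)) unname(stats::quantile(cvs, q)) else NA_real_
}

#' Quality-control a generated stimulus against its source
#'
#' Re-measures the stimulus through the same analysis pipeline that
#' defines the mosaic (critical-band decomposition, Gaussian-smoothed
#' energy densities, per-segment block averages) and reports:
#' \describe{
#'   \item{block deviation}{max and mean absolute dB deviation of the
#'     stimulus' tiles from the source's, over source blocks above the
#'     silence floor - the calibration contract of mosaicization.}
#'   \item{flatness}{excess within-tile density fluctuation in dB:
#'     the 90th-percentile within-tile coefficient of variation of the
#'     stimulus' band densities relative to that of a stationary band
#'     noise measured identically. A mosaic tile should play as a steady-state
#'     sound, i.e. fluctuate no more than steady band noise does (excess
#'     near 0 dB); running speech fluctuates far more.}
#'   \item{splatter}{out-of-band to in-band energy ratio in dB.}
#' }
#' Each number is flagged against documented, configurable thresholds;
#' the block and flatness checks only gate stimulus types whose
#' construction promises them (type `"mosaic"`). The block flag gates on
#' the mean deviation: individual quiet blocks adjacent to loud
#' neighbors are floor-filled by ramp splatter and smoothing spill (a
#' time-frequency uncertainty effect), so the max is reported but not
#' gated on.
#'
#' @param original the source [AudioSignal-class].
#' @param stimulus the generated [AudioSignal-class] (same rate).
#' @param stimType stimulus type (one of [stimulusTypes()]); decides
#'   which flags gate the pass decision.
#' @param segmentMs temporal grid duration in ms.
#' @param spec a [CriticalBandSpec-class].
#' @param rampMs ramp duration excluded from the flatness windows.
#' @param sigma Gaussian density-smoothing width in seconds.
#' @param blockTolDb mean block-deviation threshold in dB.
#' @param flatTolDb excess-flatness threshold in dB.
#' @param splatterTolDb out-of-band splatter threshold in dB.
#' @param silenceDb blocks more than this far (dB) below the loudest
#'   source block are treated as silent and excluded from the block
#'   deviation; the default -25 dB bounds the splatter floor of 5-ms
#'   ramps on 100-Hz-wide bands.
#' @return A [QCReport-class].
#' @export
qcStimulus <- function(original, stimulus, stimType, segmentMs,
                       spec = criticalBands(100, 4400), rampMs = 5,
                       sigma = 0.005, blockTolDb = 0.5, flatTolDb = 1,
                       splatterTolDb = -20, silenceDb = -25) {
  stopifnot(is(original, "AudioSignal"), is(stimulus, "AudioSignal"))
  if (sampleRate(original) != sampleRate(stimulus))
    stop("original and stimulus sampling rates differ")
  stimType <- match.arg(stimType, stimulusTypes())
  fs <- sampleRate(stimulus)

  srcBlocks <- blockValues(blockAverage(bandDecompose(original, spec),
                                        segmentMs, sigma = sigma))
  stimDec <- bandDecompose(stimulus, spec)
  stimDens <- apply(bandSignals(stimDec), 2L, function(x)
    .smoothDensity(x^2, sigma, fs))
  stimBlocks <- blockValues(blockAverage(stimDec, segmentMs, sigma = sigma))

  live <- srcBlocks > max(srcBlocks) * 10^(silenceDb / 10)
  devs <- abs(10 * log10(pmax(stimBlocks[live], 1e-300) /
                         pmax(srcBlocks[live], 1e-300)))
  blockDevMax <- if (any(live)) max(devs) else 0
  blockDevMean <- if (any(live)) mean(devs) else 0

  ## flatness: stimulus tile CV against a stationary band-noise
  ## reference measured through the identical pipeline
  n <- length(stimulus)
  segLen <- max(1L, round(segmentMs / 1000 * fs))
  guard <- round(rampMs / 1000 * fs) + ceiling(3 * sigma * fs)
  liveStim <- stimBlocks > max(stimBlocks) * 10^(silenceDb / 10)
  cvStim <- .tileCv(stimDens, liveStim, segLen, guard)
  refNoise <- .withSeed(20050, stats::rnorm(n))
  refDens <- apply(bandSignals(bandDecompose(audioSignal(refNoise, fs),
                                             spec)), 2L,
                   function(x) .smoothDensity(x^2, sigma, fs))
  cvRef <- .tileCv(refDens, liveStim, segLen, guard)
  flat <- if (is.na(cvStim) || is.na(cvRef) || cvRef <= 0) 0
          else 10 * log10(cvStim / cvRef)

  splatter <- .splatterDb(stimulus, spec)

  flags <- c(
    blocks = !(stimType == "mosaic") || blockDevMean <= blockTolDb,
    flatness = !(stimType == "mosaic") || flat <= flatTolDb,
    splatter = stimType == "ltr_raw" || splatter <= splatterTolDb,
    finite = all(is.finite(samples(stimulus))))
  new("QCReport",
      blockDevMaxDb = blockDevMax, blockDevMeanDb = blockDevMean,
      flatnessDb = flat, splatterDb = splatter,
      durationS = duration(stimulus),
      rms = sqrt(mean(samples(stimulus)^2)),
      flags = flags,
      thresholds = c(blockTolDb = blockTolDb, flatTolDb = flatTolDb,
                     splatterTolDb = splatterTolDb, silenceDb = silenceDb))
}

#' Build a full experiment stimulus set
#'
#' Generates every condition x sentence stimulus of a design, equalizes
#' sound energy per unit time across the set, quality-controls each
#' stimulus, writes one WAV per stimulus plus a manifest CSV, and
#' returns the manifest. With the full design (4 types x 5 durations, 3
#' sentences per condition) this produces the 60 stimuli a participant
#' encounters.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{types}{stimulus types (default all four).}
#'     \item{durationsMs}{grid durations in ms (default 20-320).}
#'     \item{sentences}{list of sentences, each a list with elements
#'       `signal` ([AudioSignal-class]) and `morae`; or an integer
#'       number of synthetic sentences to generate.}
#'     \item{seed}{integer master seed.}
#'     \item{referencePower}{target mean-square amplitude (default 0.01).}
#'     \item{rampMs}{ramp duration in ms (default 5).}
#'     \item{bandRange}{c(fLow, fHigh) in Hz (default c(100, 4400)).}
#'   }
#' @param outDir output directory (created if needed).
#' @param writeWavs write the WAV files (set `FALSE` to only QC).
#' @param strict error (nonzero status for the CLI) if any stimulus
#'   hard-fails QC.
#' @return data.frame manifest: one row per stimulus with filename,
#'   condition, sentence, seed, QC numbers and pass flag. Written to
#'   `manifest.csv` in `outDir` together with `references.csv` (the
#'   mora sequences) when WAVs are written.
#' @export
runExperimentBuild <- function(config, outDir = tempfile("stimuli"),
                               writeWavs = TRUE, strict = FALSE) {
  types <- config$types %||% stimulusTypes()
  durs <- config$durationsMs %||% c(20, 40, 80, 160, 320)
  seed <- config$seed %||% 1L
  refPow <- config$referencePower %||% 0.01
  rampMs <- config$rampMs %||% 5
  band <- config$bandRange %||% c(100, 4400)
  spec <- criticalBands(band[1L], band[2L])
  sentences <- config$sentences
  if (is.null(sentences)) stop("config$sentences is required")
  if (is.numeric(sentences) && length(sentences) == 1L) {
    if (sentences < 1) stop("need at least one sentence")
    sentences <- lapply(seq_len(sentences), function(i)
      .withSeed(seed * 1000L + i,
                synthSentence(nMorae = sample(16:19, 1L))))
  }
  if (length(sentences) < 1L) stop("need at least one sentence")

  conds <- buildConditionMatrix(types, durs)
  if (writeWavs) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  rows <- list()
  stims <- list()
  k <- 0L
  for (ci in seq_len(nrow(conds))) {
    for (si in seq_along(sentences)) {
      k <- k + 1L
      sSeed <- seed + 7919L * ci + si
      stim <- makeStimulus(sentences[[si]]$signal, conds$stimType[ci],
                           conds$segmentMs[ci], spec, rampMs, seed = sSeed)
      stims[[k]] <- stim
      rows[[k]] <- data.frame(
        filename = sprintf("%s_%03dms_s%02d.wav", conds$stimType[ci],
                           conds$segmentMs[ci], si),
        stim_type = conds$stimType[ci], segment_ms = conds$segmentMs[ci],
        sentence_id = si, seed = sSeed, stringsAsFactors = FALSE)
    }
  }
  stims <- equalizeEnergy(stims, refPow)

  k <- 0L
  for (ci in seq_len(nrow(conds))) {
    for (si in seq_along(sentences)) {
      k <- k + 1L
      qc <- qcStimulus(equalizeEnergy(sentences[[si]]$signal, refPow),
                       stims[[k]], conds$stimType[ci], conds$segmentMs[ci],
                       spec, rampMs)
      rows[[k]]$duration_s <- qc@durationS
      rows[[k]]$rms <- qc@rms
      rows[[k]]$block_dev_max_db <- qc@blockDevMaxDb
      rows[[k]]$splatter_db <- qc@splatterDb
      rows[[k]]$qc_pass <- qcPassed(qc)
      if (writeWavs)
        writeWav(stims[[k]], file.path(outDir, rows[[k]]$filename))
    }
  }
  manifest <- do.call(rbind, rows)
  if (writeWavs) {
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
    refs <- data.frame(
      sentence_id = seq_along(sentences),
      reference = vapply(sentences, function(s)
        paste(s$morae, collapse = " "), character(1)))
    utils::write.csv(refs, file.path(outDir, "references.csv"),
                     row.names = FALSE)
  }
  if (strict && !all(manifest$qc_pass))
    stop("QC hard failure for: ",
         paste(manifest$filename[!manifest$qc_pass], collapse = ", "))
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plain-text results report
#'
#' Formats a threshold table and Friedman analysis in the reporting
#' style of the behavioural study: per-type group mean and SD of the
#' 50 % points, the Friedman statistic with N, k and p, and the
#' post-hoc pairwise decisions.
#'
#' @param thresholds output of [thresholdTable()].
#' @param alpha family-wise level for the multiple comparisons.
#' @param file optional path; when given the report is also written there.
#' @return The report lines, invisibly, as a character vector.
#' @export
reportThresholds <- function(thresholds, alpha = 0.05, file = NULL) {
  ok <- stats::complete.cases(thresholds)
  wide <- stats::reshape(thresholds[ok, ], idvar = "participant",
                         timevar = "stimType", direction = "wide")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  colnames(m) <- sub("^threshold50Ms\\.", "", colnames(m))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  lines <- c("50 % mora-identification points (ms) by stimulus type:")
  for (j in seq_len(ncol(m)))
    lines <- c(lines, sprintf("  %-18s mean %.1f ms, SD %.1f ms",
                              colnames(m)[j], mean(m[, j]),
                              stats::sd(m[, j])))
  if (ncol(m) >= 2L && nrow(m) >= 2L) {
    fr <- friedmanRanks(m)
    lines <- c(lines, sprintf(
      "Friedman two-way ANOVA by ranks: N = %d, k = %d, Fr = %.1f; p %s",
      fr@N, fr@k, fr@Fr,
      if (fr@p < 0.001) "< 0.001" else sprintf("= %.3f", fr@p)))
    mc <- multipleComparisons(fr, alpha)
    for (r in seq_len(nrow(mc)))
      lines <- c(lines, sprintf(
        "  %s vs %s: |rank-sum diff| = %.1f (critical %.1f) -> %s",
        colnames(m)[mc$i[r]], colnames(m)[mc$j[r]], mc$rankSumDiff[r],
        mc$critical[r],
        if (mc$significant[r]) "significant" else "not significant"))
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
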