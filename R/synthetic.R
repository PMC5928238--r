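## Romanized (Hepburn) mora inventory, one token per mora; "n" is the
## special moraic nasal. The token's final vowel selects the formant
## targets.
.moraInventory <- function() {
  cv <- as.vector(outer(c("k", "s", "t", "n", "h", "m", "r", "g", "d", "b"),
                        c("a", "i", "u", "e", "o"), paste0))
  fix <- c(si = "shi", ti = "chi", tu = "tsu", hu = "fu",
           di = "ji", du = "zu")
  cv[cv %in% names(fix)] <- fix[cv[cv %in% names(fix)]]
  c("a", "i", "u", "e", "o", cv, "n")
}

## Vowel formant targets (Hz): F1, F2, F3 for a female-like voice, all
## well below the 4.4 kHz band ceiling.
.vowelFormants <- list(
  a = c(850, 1350, 2900), i = c(320, 2500, 3200), u = c(350, 1200, 2600),
  e = c(550, 2100, 2950), o = c(500, 900, 2700),  n = c(300, 1100, 2300))

## Second-order resonator (all-pole biquad) at centre frequency f0 with
## bandwidth bw, applied recursively.
.resonate <- function(x, f0, bw, rate) {
  r <- exp(-pi * bw / rate)
  theta <- 2 * pi * f0 / rate
  a <- c(2 * r * cos(theta), -r^2)
  gain <- (1 - r^2) / 2  # keeps peak gain of order 1
  stats::filter(x * gain, a, method = "recursive")
}

#' Synthesize a speech-like sentence
#'
#' Generates a mora-structured speech-like waveform by source-filter
#' synthesis: an impulse-train glottal source at `f0` with spectral tilt,
#' shaped per mora by 3 resonant formant filters whose targets are drawn
#' from a vowel table, with raised-cosine amplitude dips between morae
#' and a brief noise burst at consonant onsets. No claim of perceptual
#' realism is made - the output emulates the band-energy dynamics of
#' speech (energy concentrated below 4.4 kHz, mora-rate amplitude
#' fluctuation) so the stimulus pipeline can be exercised without a
#' recorded-speech corpus.
#'
#' Defaults mirror the sentence statistics of the behavioural study:
#' 16-19 morae per sentence at 0.12-0.15 s per mora, total duration
#' around 2-3 s at 22.05 kHz.
#'
#' @param nMorae number of morae (>= 1).
#' @param moraDurationS duration of one mora in seconds, either a scalar
#'   or a range from which per-sentence values are drawn.
#' @param f0 fundamental frequency in Hz.
#' @param rate sampling rate in Hz.
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return A list with elements `signal` (an [AudioSignal-class]) and
#'   `morae` (character vector: the reference mora sequence).
#' @examples
#' s <- synthSentence(nMorae = 17, moraDurationS = 0.14, seed = 1)
#' duration(s$signal)   # 2.38 s
#' s$morae
#' @export
synthSentence <- function(nMorae = 17, moraDurationS = c(0.12, 0.15),
                          f0 = 220, rate = 22050, seed = NULL) {
  stopifnot(nMorae >= 1, all(moraDurationS > 0), f0 > 0, rate > 0)
  .withSeed(seed, {
    inv <- .moraInventory()
    morae <- sample(inv, nMorae, replace = TRUE)
    durs <- if (length(moraDurationS) == 2L)
      stats::runif(nMorae, moraDurationS[1L], moraDurationS[2L])
    else rep(moraDurationS[1L], length.out = nMorae)
    pieces <- vector("list", nMorae)
    for (m in seq_len(nMorae)) {
      nm <- round(durs[m] * rate)
      vowel <- substring(morae[m], nchar(morae[m]))
      if (!vowel %in% names(.vowelFormants)) vowel <- "n"
      fmt <- .vowelFormants[[vowel]]
      if (any(fmt >= rate / 2))
        stop("formant frequency at or above Nyquist")
      ## impulse-train source with slight f0 jitter and -6 dB/oct tilt
      period <- round(rate / (f0 * stats::runif(1, 0.95, 1.05)))
      src <- numeric(nm)
      src[seq(1L, nm, by = period)] <- 1
      src <- as.numeric(stats::filter(src, 0.97, method = "recursive"))
      ## consonant-like onset: short noise burst for CV morae
      if (nchar(morae[m]) == 2L) {
        nb <- min(nm, round(0.015 * rate))
        src[seq_len(nb)] <- src[seq_len(nb)] * 0.2 +
          stats::rnorm(nb, sd = 0.3)
      }
      y <- numeric(nm)
      bws <- c(90, 110, 160)
      gains <- c(1, 0.6, 0.25)
      for (j in seq_along(fmt))
        y <- y + gains[j] * as.numeric(.resonate(src, fmt[j], bws[j], rate))
      ## mora envelope: rise/fall dips between morae (~15 ms shoulders)
      sh <- max(2L, min(round(0.015 * rate), nm %/% 3L))
      env <- rep(1, nm)
      env[seq_len(sh)] <- sin(pi / 2 * (seq_len(sh) - 0.5) / sh)^2
      env[nm - sh + seq_len(sh)] <- rev(env[seq_len(sh)])
      env <- 0.15 + 0.85 * env
      pieces[[m]] <- y * env
    }
    x <- unlist(pieces)
    ## clear the sub-band rumble of the source model: zero-phase 2nd-order
    ## Butterworth high-pass at the 100-Hz lower band edge
    hp <- signal::butter(2, 100 / (rate / 2), type = "high")
    x <- signal::filtfilt(hp, x - mean(x))
    x <- x / max(abs(x)) * 0.9
    list(signal = audioSignal(x, rate), morae = morae)
  })
}

#' Simulate observer responses for an experiment design
#'
#' Generates trial records for a simulated listener whose probability of
#' reporting each reference mora correctly follows a descending logistic
#' psychometric function of segment duration,
#' \deqn{p(d) = 1 / (1 + \exp((d - \theta) / s)),}
#' with 50 % point `theta` (ms, per stimulus type) and steepness `s`
#' (ms). Misses are realized as deletions (70 %) or substitutions with a
#' random other mora (30 %), so scoring must be robust to both.
#'
#' @param conditions data.frame of conditions as from
#'   [buildConditionMatrix()] (columns `stimType`, `segmentMs`).
#' @param references list of reference mora sequences (character
#'   vectors), presented once each per condition.
#' @param thresholdMs named numeric: true 50 % point (ms) per stimulus
#'   type (unnamed scalar applies to all types).
#' @param slopeMs logistic steepness in ms (> 0).
#' @param participant participant identifier.
#' @param seed integer seed.
#' @param pDeletion probability that a missed mora is deleted rather
#'   than substituted.
#' @return data.frame with one row per condition x sentence: columns
#'   `participant`, `stimType`, `segmentMs`, `sentenceId`, `reference`,
#'   `response` (mora sequences space-delimited).
#' @export
simulateResponses <- function(conditions, references, thresholdMs,
                              slopeMs = 20, participant = "P01",
                              seed = NULL, pDeletion = 0.7) {
  stopifnot(all(c("stimType", "segmentMs") %in% names(conditions)),
            length(references) >= 1L, slopeMs > 0, all(thresholdMs > 0))
  inv <- .moraInventory()
  .withSeed(seed, {
    rows <- vector("list", nrow(conditions) * length(references))
    ri <- 0L
    for (ci in seq_len(nrow(conditions))) {
      ty <- as.character(conditions$stimType[ci])
      d <- conditions$segmentMs[ci]
      th <- if (!is.null(names(thresholdMs)) && ty %in% names(thresholdMs))
        thresholdMs[[ty]] else thresholdMs[[1L]]
      pCorrect <- 1 / (1 + exp((d - th) / slopeMs))
      for (si in seq_along(references)) {
        ref <- references[[si]]
        ok <- stats::runif(length(ref)) < pCorrect
        resp <- character(0)
        for (i in seq_along(ref)) {
          if (ok[i]) resp <- c(resp, ref[i])
          else if (stats::runif(1) >= pDeletion)
            resp <- c(resp, sample(setdiff(inv, ref[i]), 1L))
        }
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          participant = participant, stimType = ty, segmentMs = d,
          sentenceId = si, reference = paste(ref, collapse = " "),
          response = paste(resp, collapse = " "),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
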