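Package: mosaicSpeech
Title: Mosaic Speech and Companion Degraded-Speech Stimuli with
    Intelligibility Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates "mosaic speech" - speech decomposed into Bark-scale
    critical bands, with per-band sound-energy-density trajectories averaged
    over fixed time segments and resynthesized as amplitude-modulated band
    noises - together with the companion degradations used in temporal
    resolution studies of speech perception: noise-vocoded speech, locally
    time-reversed speech (with and without onset/offset ramps) and
    grid-smoothed original speech. Includes a seedable speech-like synthetic
    sentence generator (impulse-train source with formant resonators and
    mora-like amplitude structure), spectrographic quality control of
    generated stimuli, batch experiment builds with WAV output and manifests,
    and the behavioural analysis layer: mora identification scoring by
    longest common subsequence, 50 percent-correct segment-duration
    thresholds by linear interpolation, and the Friedman two-way analysis of
    variance by ranks with tie correction, exact small-sample null
    distribution and rank-sum multiple comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
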