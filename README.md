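# mosaicSpeech

Stimulus generation and intelligibility analysis for **mosaic speech** —
speech degraded on a time × frequency grid the way a pixelated image is
degraded in space — together with its companion conditions:
noise-vocoded speech, locally time-reversed speech (with and without
onset/offset ramps), and grid-smoothed original speech.

The paradigm measures the temporal resolution that speech communication
needs. Speech is decomposed into **17 Bark-scale critical bands**
covering 0.1–4.4 kHz; each band's sound-energy density (squared
amplitude smoothed by a Gaussian window, σ = 5 ms) is averaged within
fixed temporal segments *T* ∈ {20, 40, 80, 160, 320} ms; and every
time-by-frequency tile is replaced by a band-limited noise carrying the
same average energy density, shaped with 5-ms raised-cosine rise/fall
ramps:

```
tile(b, s) = mean over [sT, (s+1)T) of  G_σ * x_b²(t)
output     = Σ_b  noise_b(t) · g(b, s(t)) · ramp(t),   g chosen so the
             re-measured tiles of the output equal tile(b, s)
```

Each tile is statically flat — a steady-state local spectrum — so the
stimulus carries spectro-temporal envelope information at exactly the
grid's resolution, with no pitch and no temporal fine structure.

The analysis layer implements the behavioural statistics of such
experiments: per-trial **mora** scoring (order-preserving longest common
subsequence against the reference transcription), **50 %-correct segment
durations** by linear interpolation of the psychometric curve, and the
**Friedman two-way ANOVA by ranks** (tie-corrected, exact permutation
null for small designs) with Siegel–Castellan rank-sum multiple
comparisons.

A seedable synthetic-sentence generator (impulse-train source, formant
resonators, mora-like amplitude structure, 16–19 morae at 0.12–0.15 s
per mora) and simulated logistic observers make every stage testable
without a proprietary speech corpus.

## Worked example

```r
library(mosaicSpeech)

# a 17-mora speech-like sentence, 0.14 s per mora
sent <- synthSentence(nMorae = 17, moraDurationS = 0.14, seed = 1)
sent$signal
#> AudioSignal: 52479 samples @ 22050 Hz (2.380 s), RMS 0.2539
paste(sent$morae, collapse = " ")
#> "e ne a zu gi ge da chi mo gu mi mi re do ko ha sa"

# mosaicize on the 17-band grid at 80-ms segments and QC the result
mz <- mosaicize(sent$signal, criticalBands(100, 4400),
                segmentMs = 80, seed = 42)
qcStimulus(sent$signal, mz, "mosaic", 80)
#> QCReport:
#>   block deviation: max 6.295 dB, mean 0.241 dB
#>   flatness: 0.210 dB; splatter: -35.23 dB
#>   duration 2.380 s, RMS 0.2568
#>   flags: blocks=pass, flatness=pass, splatter=pass, finite=pass
```

The QC re-measures the stimulus through the same
decomposition/smoothing/averaging pipeline: tiles match the source to
0.24 dB on average (the 6.3 dB maximum sits in tiles 25+ dB below the
loudest, where ramp splatter from loud neighbours dominates — see the
vignette); tile fluctuation is statistically that of steady band noise
(0.21 dB excess); out-of-band splatter is 35 dB down.

```r
# 50 % point of a psychometric curve, by linear interpolation
threshold50(c(20, 40, 80, 160, 320), c(98, 91, 46, 5, 1))
#> 76.44444   # ms

# Friedman rank analysis of per-listener 50 % points across 3 types
m <- rbind(c(78, 65, 62), c(71, 66, 60), c(80, 70, 69),
           c(74, 64, 66), c(77, 68, 63))
friedmanRanks(m)
#> Friedman two-way ANOVA by ranks: N = 5, k = 3, Fr = 8.4, p = 0.008488 (exact)
#>   rank sums: 15,  9,  6
```

`runExperimentBuild()` generates a full 4-type × 5-duration × 3-sentence
stimulus set (60 equalized WAV files plus a QC manifest), and
`inst/cli/mosaicspeech.R` exposes `mosaicize` / `vocode` / `ltr` /
`gridsmooth` / `batch` / `synth-*` subcommands for shell use.

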