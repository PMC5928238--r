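---
title: "Mosaic speech: construction, calibration and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mosaic speech: construction, calibration and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mosaicSpeech builds the degraded-speech stimulus family used to measure
the temporal resolution that speech communication requires, and the
statistics used to analyse listeners' intelligibility. This vignette
explains the signal model, the tunable parameters, the numerical
choices, and — importantly — what the package's own tests do and do not
establish about real speech.

## The time–frequency grid

All stimuli live on a fixed spectro-temporal grid:

* **Frequency**: 17 contiguous critical bands (Bark scale after
  Zwicker) covering 0.1–4.4 kHz, the range over which noise-vocoded
  speech remains nearly fully intelligible. The edge table is exported
  as `zwickerBandEdges`; `criticalBands(100, 4400)` selects the 17
  intervals. Bands are ~100 Hz wide below 500 Hz, widening with
  frequency.
* **Time**: half-open segments `[sT, (s+1)T)` anchored at the first
  sample, with `T` ∈ {20, 40, 80, 160, 320} ms in the standard design.
  A final partial segment is processed as a shorter block.

Band decomposition (`bandDecompose()`) uses zero-phase brick-wall
spectral masking: one forward FFT, per-band zeroing of out-of-band
bins, inverse FFT. Every bin belongs to exactly one band (half-open
edges), so the bands sum to the band-limited input at machine precision
and no filter group delay desynchronizes bands. Descriptions of this
paradigm specify only that the signal is delimited into narrow
frequency bands, not a filter family; the brick-wall choice is the only
one that makes the additive-reconstruction property exact, which the
calibration loop below depends on.

## Sound-energy density

The working intensity measure is the instantaneous squared amplitude
smoothed by a unit-area Gaussian window with σ = 5 ms
(`energyTrajectory()`). All densities are relative (full-scale ±1
floating point); absolute SPL belongs to the playback chain, which is
out of scope. Signal edges are reflect-padded by 4σ before convolution
so the density does not spuriously decay at the ends. Averaging each
band's density over the temporal grid (`blockAverage()`) gives the
B × S `EnergyBlockMatrix` — the mosaic tiles.

## The four stimulus types

* `gridSmooth()` — original speech shaped with the temporal grid only:
  raised-cosine (Hann half-window) rise and fall ramps, 5 ms each,
  contained **within** each segment. Mid-segment samples are
  bit-identical to the input.
* `mosaicize()` — mosaic speech. One continuous Gaussian band-noise
  carrier per band, a piecewise-constant gain per segment chosen so the
  re-measured per-tile mean density equals the source tile, and the
  per-segment ramps. Gains are calibrated by fixed-point refinement:
  the built stimulus is re-decomposed and re-measured through the
  *identical* analysis pipeline and per-tile corrections
  `sqrt(target/measured)` applied (5 iterations by default).
* `vocode()` — noise-vocoded speech: the same carriers
  amplitude-modulated pointwise by `sqrt(target density / carrier's own
  density)`, with two fixed-point corrections (the envelope of a
  ~100-Hz-wide noise fluctuates on the same ~10 ms timescale as the
  smoothing window, so one division cancels it only partially), and —
  as in a classic channel vocoder — each modulated band band-pass
  filtered again so gain modulation cannot spread into neighboring
  channels.
* `localTimeReverse()` — each segment's waveform reversed in place,
  optionally ramped. Without ramps this is an exact involution and an
  exact permutation of samples.

`equalizeEnergy()` rescales every stimulus of a set to a common mean
square, as done before presentation to listeners.

### Ramps, and a deliberate asymmetry

Ramps are contained within the segment (total duration is exact; the
visible inter-segment dips in the stimulus spectrograms are
reproduced). A segment shorter than rise + fall shrinks both
proportionally. The mosaic is *not* re-filtered after windowing: its
anti-splatter mechanism is the ramp itself, and the residual out-of-band
splatter is a real property of these stimuli (the package's QC measures
it, and the raw-vs-ramped ordering is asserted by tests). The vocoder,
which has no ramps, *is* re-filtered per channel — the standard
construction.

### What tile calibration can and cannot achieve

The defining contract of mosaicization is that re-measured tile
densities match the source tiles. The fixed-point calibration drives
every tile whose band dominates its spectro-temporal neighborhood to
within < 0.1 dB. It cannot do the same for deeply quiet tiles: a 5-ms
ramp applied to a loud 100-Hz-wide band spreads energy into adjacent
bands, and the σ = 5 ms smoother spills across segment boundaries, so a
tile 25–40 dB below its neighbors measures leakage, not its own gain
(setting the gain to zero does not lower the measurement). This is the
time–frequency uncertainty limit inherent to a 20-ms/100-Hz grid, not a
calibration defect. Consequently:

* the QC block flag (`qcStimulus()`) gates on the **mean** absolute
  tile deviation over tiles within 25 dB of the loudest (default
  `blockTolDb` 0.5 dB, `silenceDb` −25 dB); the maximum is reported but
  dominated by the leakage floor for harmonic sources;
* the package's strictest regression of this contract (max deviation
  over all tiles above a −40 dB floor, all five durations) is expected
  to fail for harmonic speech-like input and is kept in the suite as an
  honest record of that limit.

Similarly, "each tile plays as a steady-state sound" cannot mean a
density flat to < 1 dB: steady narrow-band noise itself fluctuates
several dB at σ = 5 ms resolution. Flatness QC therefore measures
*excess* fluctuation: the 90th-percentile within-tile coefficient of
variation of band densities relative to a stationary band noise
measured through the identical pipeline (guard regions: ramp + 3σ).
Mosaic stimuli sit near 0 dB excess; grid-smoothed running speech shows
+2 to +6 dB.

## Synthetic speech-like sentences

`synthSentence()` provides license-free test material emulating the
sentence statistics of the behavioural design: 16–19 morae per
sentence, 0.12–0.15 s per mora (total ≈ 2–3 s), 22.05 kHz. The source
model is an impulse train at f0 = 220 Hz (female-like) with −6 dB/oct
spectral tilt, three resonant formant filters per mora (targets from a
five-vowel table, all < 3.3 kHz), raised-cosine inter-mora amplitude
dips, a 15-ms noise burst at consonant onsets, and a zero-phase 100-Hz
high-pass so the energy is confined to the critical-band range.

What it emulates: mora-rate amplitude structure, formant-band energy
dynamics, speech-band confinement. What it does not: coarticulation,
formant transitions, prosody, aspiration noise, or any perceptual
realism — no intelligibility claim attaches to these signals. Passing
tests therefore establish that the *machinery* (decomposition,
calibration, scoring, threshold estimation) behaves correctly, not that
the stimuli would produce the human psychometric curves. The synthetic
source is also deliberately *harder* than natural speech in one
respect: its strictly periodic source leaves 25–40 dB between-harmonic
nulls that natural (breathy) voices do not, which is what exposes the
uncertainty-limited tiles discussed above.

## Simulated observers and the analysis layer

`simulateResponses()` draws each reference mora correct with
probability `1 / (1 + exp((T − θ)/s))` — a descending logistic in
segment duration `T` with 50 % point θ and steepness `s` (default
20 ms, chosen so scores fall from ~85 % at 40 ms to ~1 % at 160 ms for
θ = 75 ms, the shape of the reported group curves). Misses become
deletions (70 %) or substitutions (30 %) — arbitrary but fixed, so
scoring must be robust to both.

Scoring (`scoreMorae()`) counts order-preserving matches via the
longest common subsequence, divided by the reference length; the
original report counted "written morae that corresponded" without
specifying alignment, and LCS is the standard forgiving choice (a
documented stand-in). The 50 % point (`threshold50()`) interpolates
linearly between the two durations bracketing the **first** descent
through 50 % going from fine to coarse grids, matching the
monotone-decline reading; an exact 50 % score returns that duration,
and a curve that never descends through 50 % is an error rather than an
extrapolation.

`friedmanRanks()` implements the Friedman two-way ANOVA by ranks with
mid-ranks and the Siegel–Castellan tie correction (ties are routine in
percent scores). For N ≤ 8, k ≤ 3 the p value is exact: the null
distribution over all within-row rank permutations is built by dynamic
programming over rank-sum states (ties included; the correction term is
permutation-invariant). Larger designs use the χ²(k−1) approximation.
`multipleComparisons()` applies the rank-sum criterion
|R_u − R_v| ≥ z_{α/k(k−1)} √(Nk(k+1)/6).

## Numerical choices and degenerate inputs

* Segment length in samples is `round(T · fs)`; the standard durations
  are exact sample counts at 22.05 kHz.
* Silence floor 10⁻¹⁰ (amplitude², relative full scale): tile targets
  below it map to zero gain; vocoder gain divisions are floored there.
* Silent input → silent output for all synthesizers; fully silent
  stimuli cannot be energy-equalized (error).
* Carrier/margin noise is seedable; identical inputs and seed give
  bit-identical stimuli, and seeded helpers restore the caller's RNG
  state.
* WAV I/O is a minimal RIFF reader/writer (PCM 16-bit and float 32),
  mono, with polyphase resampling to a configured rate on read (warned).

## Problem sizes used by the test-suite and acceptance script

Deterministic fixtures are kept small so the full suite runs in a few
minutes: 8-mora (~1 s) sentences for pipeline and calibration checks,
two sentences for the duration ladder, 500–1000 simulated observers for
threshold-recovery statistics (54 morae per condition, as in the
design), and N = 20 simulated listeners for the rank analysis. These
sizes give the narrowest band enough averaging where statistics matter
(e.g. 40 s of noise for bandwidth-proportionality checks) while staying
desk-scale.

## Known limitations

* Tile calibration and per-band density tracking are
  uncertainty-limited in deeply quiet bands of harmonic sources (see
  above); reported maxima over all tiles reflect that floor.
* The threshold estimator inherits a small positive bias (~4 ms) from
  interpolating a convex logistic linearly; it is reported as measured.
* Mora scoring has no phonological model: substitutions that happen to
  match a later reference token can credit a point; the simulated-observer
  tests bound this effect.
* No gammatone/ERB filterbanks, loudness models, SPL calibration, or
  kana processing; frequency-resolution manipulations beyond the fixed
  critical-band grid are not implemented.
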