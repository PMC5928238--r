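test_that("mosaicizing silence yields silence", {
  s <- audioSignal(rep(0, 4410), fixtureRate)
  expect_equal(max(abs(samples(mosaicize(s, fullSpec, 40, seed = 1)))), 0)
})

test_that("stationary single-band noise keeps its block densities", {
  # oracle: re-measure the output with energyTrajectory + blockAverage
  nb <- bandLimit(noiseSignal(1.2, seed = 21), 920, 1080)
  mz <- mosaicize(nb, fullSpec, 80, seed = 2)
  tgt <- blockValues(blockAverage(bandDecompose(nb, fullSpec), 80))[8, ]
  out <- blockValues(blockAverage(bandDecompose(mz, fullSpec), 80))[8, ]
  dev <- abs(10 * log10(out / tgt))
  expect_lt(max(dev), 0.5)
})

test_that("mosaic block calibration matches the source where the band
           dominates its neighborhood", {
  s <- testSentence()$signal
  mz <- mosaicize(s, fullSpec, 80, seed = 7)
  tgt <- blockValues(blockAverage(bandDecompose(s, fullSpec), 80))
  out <- blockValues(blockAverage(bandDecompose(mz, fullSpec), 80))
  live <- tgt > max(tgt) * 10^(-25 / 10)
  dev <- abs(10 * log10(out[live] / tgt[live]))
  expect_lt(mean(dev), 0.5)
})

test_that("mosaic tiles fluctuate no more than steady band noise", {
  s <- testSentence()$signal
  mz <- mosaicize(s, fullSpec, 80, seed = 5)
  qc <- qcStimulus(s, mz, "mosaic", 80, fullSpec)
  expect_lt(qc@flatnessDb, 1)
  # whereas grid-smoothed running speech shows excess fluctuation
  qcSpeech <- qcStimulus(s, gridSmooth(s, 80), "mosaic", 80, fullSpec)
  expect_gt(qcSpeech@flatnessDb, 1)
})

test_that("mosaicization is deterministic given a seed", {
  s <- testSentence()$signal
  a <- mosaicize(s, fullSpec, 160, seed = 9)
  b <- mosaicize(s, fullSpec, 160, seed = 9)
  expect_identical(samples(a), samples(b))
  expect_false(identical(samples(a),
                         samples(mosaicize(s, fullSpec, 160, seed = 10))))
})

test_that("vocoding silence yields silence", {
  s <- audioSignal(rep(0, 4410), fixtureRate)
  expect_equal(max(abs(samples(vocode(s, fullSpec, seed = 1)))), 0)
})

test_that("a vocoded AM tone stays inside its critical band", {
  t <- seq(0, 1, by = 1 / fixtureRate)
  am <- audioSignal((0.6 + 0.4 * sin(2 * pi * 4 * t)) *
                      sin(2 * pi * 1000 * t), fixtureRate)
  v <- vocode(am, fullSpec, seed = 3)
  en <- colSums(bandSignals(bandDecompose(v, fullSpec))^2)
  expect_gte(en[8] / sum(en), 0.99)
})

test_that("vocoded speech tracks the per-band target densities", {
  # oracle: energy trajectories of the re-decomposed output
  syn <- testSentence()
  s <- syn$signal
  fs <- sampleRate(s)
  v <- vocode(s, fullSpec, seed = 11)
  decS <- bandDecompose(s, fullSpec)
  decV <- bandDecompose(v, fullSpec)
  cors <- vapply(seq_len(17), function(b) {
    cor(densityValues(energyTrajectory(audioSignal(bandSignals(decS)[, b],
                                                   fs))),
        densityValues(energyTrajectory(audioSignal(bandSignals(decV)[, b],
                                                   fs))))
  }, numeric(1))
  expect_true(all(cors >= 0.95))
})

test_that("unsmoothed local reversal is an exact involution", {
  x <- samples(testSentence()$signal)
  n <- 441 * floor(length(x) / 441)  # exact multiple of 20-ms segments
  s <- audioSignal(x[seq_len(n)], fixtureRate)
  r <- localTimeReverse(s, 20)
  expect_false(identical(samples(r), samples(s)))
  expect_identical(samples(localTimeReverse(r, 20)), samples(s))
  # an exact permutation: same sample multiset, hence same energy
  expect_identical(sort(samples(r)), sort(samples(s)))
  expect_equal(signalEnergy(r), signalEnergy(s), tolerance = 1e-12)
})

test_that("a segment longer than the signal reverses the whole waveform", {
  s <- audioSignal(seq_len(1000) / 1000, fixtureRate)
  expect_identical(samples(localTimeReverse(s, 10000)), rev(samples(s)))
})

test_that("the final short segment reverses within its own extent", {
  s <- audioSignal(c(1:4, 5:6) / 10, 1000)  # 4-sample segments: 4 ms at 1 kHz
  expect_equal(samples(localTimeReverse(s, 4)), c(4:1, 6:5) / 10)
})

test_that("grid smoothing is the identity for zero ramps and leaves
           mid-segment samples untouched", {
  s <- testSentence()$signal
  expect_identical(samples(gridSmooth(s, 80, rampSpec(0, 0))), samples(s))
  g <- gridSmooth(s, 80, rampSpec())
  segLen <- round(0.08 * fixtureRate)
  rampN <- round(0.005 * fixtureRate)
  mid <- (rampN + 1):(segLen - rampN)  # interior of the first segment
  expect_identical(samples(g)[mid], samples(s)[mid])
})

test_that("Hann ramps remove the closed-form energy fraction", {
  # integral of sin^4 over a half period is 3/8, so each full Hann ramp
  # of r samples keeps 3r/8 of the energy it covers
  rate <- 1000
  segLen <- 100
  rampN <- 10
  s <- audioSignal(rep(1, 10 * segLen), rate)
  g <- gridSmooth(s, 100, rampSpec(10, 10))
  perSeg <- (segLen - 2 * rampN) + 2 * (3 / 8) * rampN
  expect_equal(signalEnergy(g) / signalEnergy(s), perSeg / segLen,
               tolerance = 0.01)
})

test_that("energy equalization scales every stimulus to the reference", {
  set.seed(5)
  batch <- lapply(c(0.1, 1, 4), function(a)
    audioSignal(a * rnorm(2000), fixtureRate))
  eq <- equalizeEnergy(batch, referencePower = 0.04)
  pows <- vapply(eq, function(s) mean(samples(s)^2), numeric(1))
  expect_true(all(abs(pows - 0.04) / 0.04 < 1e-6))
  # 4x the reference power scales by exactly 1/2
  four <- audioSignal(rep(c(0.4, -0.4), 500), fixtureRate)
  eq1 <- equalizeEnergy(four, referencePower = 0.04)
  expect_equal(samples(eq1), samples(four) / 2, tolerance = 1e-12)
  expect_error(equalizeEnergy(audioSignal(rep(0, 10), 100), 0.01), "silent")
})

test_that("ramping suppresses the splatter of abrupt segment edges", {
  s <- bandLimit(testSentence()$signal, 100, 4400)
  raw <- localTimeReverse(s, 80)
  smoothed <- localTimeReverse(s, 80, rampSpec())
  expect_gt(outOfBandFraction(raw), outOfBandFraction(smoothed))
  mzRaw <- mosaicize(s, fullSpec, 80, rampSpec(0, 0), seed = 5)
  mzSm <- mosaicize(s, fullSpec, 80, rampSpec(), seed = 5)
  expect_gt(outOfBandFraction(mzRaw), outOfBandFraction(mzSm))
})

test_that("the condition matrix is the type-major Cartesian product", {
  full <- buildConditionMatrix(stimulusTypes(), c(20, 40, 80, 160, 320))
  expect_equal(nrow(full), 20)
  expect_equal(full$stimType[1:5], rep("original_gridded", 5))
  expect_equal(full$segmentMs[1:5], c(20, 40, 80, 160, 320))
  exp1 <- buildConditionMatrix("mosaic", c(40, 80, 160, 320))
  expect_equal(nrow(exp1), 4)
  expect_equal(nrow(buildConditionMatrix("mosaic", 80)), 1)
  expect_error(buildConditionMatrix(c("mosaic", "mosaic"), 80), "duplicate")
  expect_error(buildConditionMatrix("mosaic", c(80, 80)), "duplicate")
  expect_error(buildConditionMatrix("wavelet", 80), "unknown")
})
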