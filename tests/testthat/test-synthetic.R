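test_that("synthetic sentences have mora-determined duration and stay in
           the speech band", {
  syn <- synthSentence(nMorae = 17, moraDurationS = 0.14, seed = 1)
  expect_equal(duration(syn$signal), 2.38, tolerance = 1e-3)
  expect_true(duration(syn$signal) >= 2.27 && duration(syn$signal) <= 2.98)
  expect_length(syn$morae, 17)
  expect_equal(sampleRate(syn$signal), 22050)
  # energy is dominated by the 0.1-4.4 kHz critical-band range
  expect_gt(1 - outOfBandFraction(syn$signal), 0.9)
})

test_that("a one-mora sentence is a single steady unit", {
  syn <- synthSentence(nMorae = 1, moraDurationS = 0.14, seed = 2)
  expect_length(syn$morae, 1)
  expect_equal(length(syn$signal), round(0.14 * 22050), tolerance = 2)
})

test_that("sentence synthesis is bit-reproducible under a seed and does
           not disturb the caller's RNG", {
  a <- synthSentence(nMorae = 5, seed = 77)
  set.seed(123)
  probe1 <- rnorm(1)
  b <- synthSentence(nMorae = 5, seed = 77)
  expect_identical(samples(a$signal), samples(b$signal))
  expect_identical(a$morae, b$morae)
  set.seed(123)
  c <- synthSentence(nMorae = 5, seed = 78)
  expect_identical(rnorm(1), probe1)  # RNG state restored around the call
  expect_false(identical(samples(a$signal), samples(c$signal)))
})

test_that("formants above Nyquist are rejected", {
  expect_error(synthSentence(nMorae = 2, rate = 5000, seed = 1), "Nyquist")
})

test_that("synthetic sentences pass through the whole stimulus pipeline", {
  s <- testSentence()$signal
  for (d in c(20, 320)) {
    expect_s4_class(mosaicize(s, fullSpec, d, seed = 1), "AudioSignal")
    expect_s4_class(localTimeReverse(s, d, rampSpec()), "AudioSignal")
    expect_s4_class(gridSmooth(s, d), "AudioSignal")
  }
  expect_s4_class(vocode(s, fullSpec, seed = 1), "AudioSignal")
})

test_that("an infallible simulated observer echoes every reference and a
           hopeless one reports nothing", {
  conds <- buildConditionMatrix("mosaic", c(20, 80, 320))
  refs <- lapply(1:2, function(i) c("ka", "n", "to", "mi"))
  perfect <- simulateResponses(conds, refs, thresholdMs = 1e9,
                               slopeMs = 20, seed = 1)
  expect_true(all(perfect$response == perfect$reference))
  expect_equal(mean(vapply(seq_len(nrow(perfect)), function(i)
    scoreMorae(perfect$reference[i], perfect$response[i]), numeric(1))),
    100)
  # an infinitely steep observer above threshold misses every mora;
  # random substitutions can still collide with a reference token, so
  # the score is near, not exactly, zero
  hopeless <- simulateResponses(conds, refs, thresholdMs = 1e-6,
                                slopeMs = 1e-9, seed = 1)
  scores <- vapply(seq_len(nrow(hopeless)), function(i)
    scoreMorae(hopeless$reference[i], hopeless$response[i]), numeric(1))
  expect_lt(mean(scores), 5)
})

test_that("simulated scores decline with segment duration", {
  conds <- buildConditionMatrix("mosaic", c(20, 40, 80, 160, 320))
  refs <- lapply(1:3, function(i) {
    set.seed(100 + i)
    sample(c("ka", "ki", "ku", "ke", "ko", "n", "sa", "ta"), 18,
           replace = TRUE)
  })
  rhos <- replicate(20, {
    tr <- simulateResponses(conds, refs, thresholdMs = 75, slopeMs = 20,
                            seed = sample.int(1e6, 1))
    sc <- identificationScores(tr)
    cor(sc$segmentMs, sc$scorePct, method = "spearman")
  })
  expect_lt(mean(rhos), 0)
  expect_gt(mean(rhos < 0), 0.9)
})

test_that("recovered 50 % points concentrate around the generating
           threshold", {
  conds <- buildConditionMatrix("mosaic", c(20, 40, 80, 160, 320))
  refs <- lapply(1:3, function(i) {
    set.seed(200 + i)
    sample(c("ka", "ki", "ku", "ke", "ko", "n", "sa", "ta"), 18,
           replace = TRUE)
  })
  set.seed(31)
  recovered <- replicate(60, {
    tr <- simulateResponses(conds, refs, thresholdMs = 75, slopeMs = 20,
                            seed = sample.int(1e6, 1))
    sc <- identificationScores(tr)
    sc <- sc[order(sc$segmentMs), ]
    threshold50(sc$segmentMs, sc$scorePct)
  })
  expect_lt(abs(mean(recovered) - 75), 8)
})
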