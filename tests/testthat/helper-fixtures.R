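# Shared fixtures, built in code. The canonical test sentence is cached
# per session because synthesis plus decomposition dominates test time.

fixtureRate <- 22050

toneSignal <- function(freq, durS = 0.5, amp = 1, rate = fixtureRate) {
  audioSignal(amp * sin(2 * pi * freq * seq(0, durS, by = 1 / rate)), rate)
}

noiseSignal <- function(durS = 1, rate = fixtureRate, seed = 404) {
  set.seed(seed)
  audioSignal(rnorm(round(durS * rate)), rate)
}

fullSpec <- criticalBands(100, 4400)

.fixtureEnv <- new.env()

testSentence <- function() {
  if (is.null(.fixtureEnv$sent))
    .fixtureEnv$sent <- synthSentence(nMorae = 8, moraDurationS = 0.13,
                                      seed = 3)
  .fixtureEnv$sent
}

# out-of-band energy fraction relative to a band partition
outOfBandFraction <- function(signal, spec = fullSpec) {
  e <- bandEdges(spec)
  tot <- signalEnergy(signal)
  inb <- signalEnergy(bandLimit(signal, e[1L], e[length(e)]))
  (tot - inb) / tot
}

# all 3! = 6 permutations of 1:3, for brute-force Friedman oracles
perm3 <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                6, 3, byrow = TRUE)
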