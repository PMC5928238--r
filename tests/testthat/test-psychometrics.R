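# brute-force longest-common-subsequence oracle for tiny token pairs:
# try every subset of a (greedy scan decides subsequence membership in b)
isSubseq <- function(keep, b) {
  j <- 1L
  for (tok in keep) {
    while (j <= length(b) && b[j] != tok) j <- j + 1L
    if (j > length(b)) return(FALSE)
    j <- j + 1L
  }
  TRUE
}

lcsOracle <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  best <- 0L
  for (m in 0:(2^length(a) - 1)) {
    keep <- a[bitwAnd(m, 2^(seq_along(a) - 1)) > 0]
    if (length(keep) > best && isSubseq(keep, b)) best <- length(keep)
  }
  best
}

test_that("mora scoring counts order-preserving matches against the
           reference", {
  kinkakuji <- c("ki", "n", "ka", "ku", "ji")  # 5 morae, "n" special
  expect_equal(scoreMorae(kinkakuji, kinkakuji), 100)
  expect_equal(scoreMorae(kinkakuji, character(0)), 0)
  expect_equal(scoreMorae("ki n ka ku ji", ""), 0)
  # one deletion and one substitution leave 3 of 5
  expect_equal(scoreMorae(kinkakuji, c("ki", "ka", "pu", "ji")), 60)
  expect_error(scoreMorae(character(0), kinkakuji), "nonempty")
})

test_that("mora scoring agrees with an exhaustive subsequence oracle", {
  inv <- c("ka", "ki", "ku", "n", "sa", "to")
  set.seed(42)
  for (i in 1:25) {
    ref <- sample(inv, sample(2:7, 1), replace = TRUE)
    resp <- sample(inv, sample(0:7, 1), replace = TRUE)
    expect_equal(scoreMorae(ref, resp),
                 100 * lcsOracle(resp, ref) / length(ref))
  }
})

test_that("mora scoring is order-sensitive and capped at 100", {
  ref <- c("ka", "ki", "ku", "ke", "ko")
  expect_lt(scoreMorae(ref, rev(ref)), 100)
  # response with many insertions cannot exceed 100
  expect_equal(scoreMorae(ref, rep(ref, 3)), 100)
})

test_that("the 50 % point interpolates the first descent through 50", {
  expect_equal(threshold50(c(20, 40, 80, 160), c(90, 80, 50, 10)), 80)
  expect_equal(threshold50(c(20, 40, 80, 160), c(100, 90, 60, 40)), 120)
  expect_error(threshold50(c(20, 40, 80, 160), c(100, 90, 80, 70)),
               "undefined")
  # non-monotone curve: the first crossing (fine-to-coarse) is used
  expect_equal(threshold50(c(20, 40, 80, 160, 320),
                           c(90, 60, 40, 55, 10)),
               40 + (60 - 50) / (60 - 40) * 40)
  expect_error(threshold50(c(40, 20), c(90, 40)), "increasing")
})

test_that("Friedman statistic matches the closed form under perfect
           concordance and vanishes under full ties", {
  m <- matrix(rep(c(10, 20, 30), each = 20), 20, 3)  # identical rankings
  fr <- friedmanRanks(m, exact = FALSE)
  expect_equal(fr@Fr, 2 * 20)  # Fr = 2N for k = 3
  expect_lt(fr@p, 0.001)
  expect_equal(friedmanRanks(matrix(5, 4, 3))@Fr, 0)
})

test_that("Friedman statistic equals the tie-corrected reference
           implementation", {
  set.seed(7)
  for (i in 1:6) {
    m <- matrix(sample(1:4, 30, replace = TRUE) + rnorm(30, sd = 0.01 * (i %% 2)),
                10, 3)
    expect_equal(friedmanRanks(m, exact = FALSE)@Fr,
                 unname(stats::friedman.test(m)$statistic))
  }
})

test_that("exact p values match enumeration over all within-row rank
           permutations", {
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(sample(1:5, 12, replace = TRUE), 4, 3)
    fr <- friedmanRanks(m)
    expect_identical(fr@pMethod, "exact")
    ranks <- t(apply(m, 1, rank))
    denom <- sum(apply(ranks, 1, function(r) {
      tt <- table(r); sum(tt^3 - tt)
    }))
    den <- 4 * 3 * 4 - denom / 2
    combos <- as.matrix(expand.grid(rep(list(1:6), 4)))
    frs <- apply(combos, 1, function(p) {
      rr <- t(vapply(1:4, function(r) ranks[r, perm3[p[r], ]], numeric(3)))
      if (den <= 0) 0 else 12 * sum((colSums(rr) - 4 * 2)^2) / den
    })
    expect_equal(fr@p, mean(frs >= fr@Fr - 1e-9), tolerance = 1e-3)
  }
})

test_that("Friedman depends only on within-row ranks", {
  set.seed(9)
  m <- matrix(rnorm(36), 12, 3)
  transformed <- t(apply(m, 1, function(r) exp(3 * r) - min(r)))
  expect_equal(friedmanRanks(m, exact = FALSE)@Fr,
               friedmanRanks(transformed, exact = FALSE)@Fr)
})

test_that("rank-sum multiple comparisons flag concordant extremes and
           spare identical columns", {
  frEq <- friedmanRanks(matrix(c(1, 1, 1), 6, 3, byrow = TRUE) +
                          rnorm(18, sd = 1e-12), exact = FALSE)
  # essentially identical rank sums: nothing significant
  mcEq <- multipleComparisons(frEq, 0.05)
  expect_false(any(mcEq$significant))

  fr <- friedmanRanks(matrix(rep(c(1, 2, 3), each = 20), 20, 3),
                      exact = FALSE)
  mc <- multipleComparisons(fr, 0.05)
  extreme <- mc[mc$i == 1 & mc$j == 3, ]
  expect_true(extreme$significant)
  expect_equal(extreme$rankSumDiff, 2 * 20)  # rank sums N vs 3N
  expect_error(multipleComparisons(fr, 1.5), "alpha")
})

test_that("a k = 2 comparison is consistent with the sign-test direction", {
  m <- cbind(1:10, 1:10 + 1)  # column 2 always larger
  fr <- friedmanRanks(m, exact = FALSE)
  mc <- multipleComparisons(fr, 0.05)
  expect_equal(nrow(mc), 1)
  expect_equal(fr@rankSums, c(10, 20))
  expect_true(mc$significant)
})

test_that("score pooling and threshold tables reproduce per-condition
           curves", {
  trials <- data.frame(
    participant = "P01", stimType = "mosaic",
    segmentMs = rep(c(20, 80, 320), each = 2), sentenceId = rep(1:2, 3),
    reference = "ka ki ku", response = c("ka ki ku", "ka ki ku",
                                         "ka ki ku", "ka",
                                         "", ""),
    stringsAsFactors = FALSE)
  sc <- identificationScores(trials)
  expect_equal(sc$scorePct[sc$segmentMs == 20], 100)
  expect_equal(sc$scorePct[sc$segmentMs == 80], 100 * 4 / 6)
  expect_equal(sc$scorePct[sc$segmentMs == 320], 0)
  expect_equal(unique(sc$nMorae), 6)
  th <- thresholdTable(sc)
  expect_equal(th$threshold50Ms,
               80 + (100 * 4 / 6 - 50) / (100 * 4 / 6 - 0) * (320 - 80))
})
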