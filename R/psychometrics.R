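## Length of the longest common subsequence of two token vectors.
.lcsLength <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    match_i <- a[i] == b
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (match_i[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

## Tokenize a space-delimited mora string; vectors pass through.
.moraTokens <- function(x) {
  if (length(x) == 1L && is.character(x) && grepl(" ", x))
    x <- strsplit(trimws(x), "\\s+")[[1L]]
  as.character(x[nzchar(x)])
}

#' Score mora identification for one trial
#'
#' Percentage of reference morae correctly reported: 100 times the length
#' of the order-preserving longest common subsequence of response and
#' reference, divided by the reference length. LCS matching is forgiving
#' of deletions, insertions and substitutions while remaining sensitive
#' to order, mirroring the counting of written morae that correspond to
#' the morae pronounced.
#'
#' @param reference,response mora sequences: character vectors of tokens
#'   in a documented romanization (one token per mora, "n" its own
#'   special mora), or single space-delimited strings.
#' @return percent correct in \[0, 100\].
#' @examples
#' scoreMorae(c("ki", "n", "ka", "ku", "ji"), c("ki", "n", "ka", "ku", "ji"))
#' scoreMorae("ki n ka ku ji", "ki ka pu ji")   # one deletion, one substitution
#' @export
scoreMorae <- function(reference, response) {
  ref <- .moraTokens(reference)
  if (length(ref) == 0L) stop("'reference' must be a nonempty mora sequence")
  resp <- .moraTokens(response)
  100 * .lcsLength(resp, ref) / length(ref)
}

#' 50 %-correct segment duration by linear interpolation
#'
#' Finds the segment duration at which a descending psychometric curve
#' crosses 50 % correct, interpolating linearly between the two adjacent
#' durations bracketing the first descent through 50 % (going from fine
#' to coarse durations). An exact 50 % score returns that duration.
#'
#' @param durationsMs strictly increasing segment durations (ms).
#' @param scoresPct percent-correct scores in \[0, 100\], one per duration.
#' @return the 50 % point in ms.
#' @examples
#' threshold50(c(20, 40, 80, 160), c(100, 90, 60, 40))  # 120
#' @export
threshold50 <- function(durationsMs, scoresPct) {
  stopifnot(length(durationsMs) == length(scoresPct),
            length(durationsMs) >= 2L)
  if (any(diff(durationsMs) <= 0))
    stop("'durationsMs' must be strictly increasing")
  if (any(scoresPct < 0 | scoresPct > 100))
    stop("scores must lie in [0, 100]")
  for (i in seq_len(length(scoresPct) - 1L)) {
    if (scoresPct[i] == 50) return(durationsMs[i])
    if (scoresPct[i] > 50 && scoresPct[i + 1L] < 50) {
      return(durationsMs[i] +
             (scoresPct[i] - 50) / (scoresPct[i] - scoresPct[i + 1L]) *
             (durationsMs[i + 1L] - durationsMs[i]))
    }
  }
  if (scoresPct[length(scoresPct)] == 50)
    return(durationsMs[length(durationsMs)])
  stop("threshold undefined: the curve never descends through 50 %")
}

## Exact null distribution of the tie-corrected Friedman statistic by
## dynamic programming over independent within-row rank permutations.
## Supports k in {2, 3}. Returns P(Fr >= observed).
.friedmanExactP <- function(ranks, FrObs) {
  N <- nrow(ranks); k <- ncol(ranks)
  stopifnot(k %in% c(2L, 3L))
  ## doubled ranks are integers (mid-ranks are multiples of 1/2)
  r2 <- round(2 * ranks)
  perms <- .permutations(k)
  if (k == 2L) {
    ## state: doubled rank sum of column 1
    dist <- c(`0` = 1)
    for (i in seq_len(N)) {
      nxt <- new.env()
      for (key in names(dist)) {
        p0 <- dist[[key]]
        for (pi in seq_len(nrow(perms))) {
          s <- as.integer(key) + r2[i, perms[pi, 1L]]
          kk <- as.character(s)
          nxt[[kk]] <- (if (is.null(nxt[[kk]])) 0 else nxt[[kk]]) +
            p0 / nrow(perms)
        }
      }
      dist <- unlist(as.list(nxt))
    }
    states <- cbind(as.integer(names(dist)))
  } else {
    dist <- c(`0,0` = 1)
    for (i in seq_len(N)) {
      nxt <- new.env()
      for (key in names(dist)) {
        p0 <- dist[[key]]
        base <- as.integer(strsplit(key, ",")[[1L]])
        for (pi in seq_len(nrow(perms))) {
          s1 <- base[1L] + r2[i, perms[pi, 1L]]
          s2 <- base[2L] + r2[i, perms[pi, 2L]]
          kk <- paste(s1, s2, sep = ",")
          nxt[[kk]] <- (if (is.null(nxt[[kk]])) 0 else nxt[[kk]]) +
            p0 / nrow(perms)
        }
      }
      dist <- unlist(as.list(nxt))
    }
    states <- do.call(rbind, lapply(strsplit(names(dist), ","), as.integer))
  }
  total2 <- sum(r2) # doubled grand total, fixed across permutations
  R <- matrix(0, nrow(states), k)
  R[, seq_len(k - 1L)] <- states / 2
  R[, k] <- total2 / 2 - rowSums(states) / 2
  denom <- .friedmanDenominator(ranks)
  if (denom <= 0) return(1)
  FrAll <- (12 * rowSums((R - N * (k + 1) / 2)^2)) / denom
  sum(dist[FrAll >= FrObs - 1e-9])
}

## All permutations of 1..k (small k).
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- NULL
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                            sub[, seq(pos, k - 1L)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  storage.mode(out) <- "integer"
  out
}

## Tie-corrected denominator N*k*(k+1) - sum(t^3 - t)/(k - 1), shared by
## the statistic and the exact-null computation.
.friedmanDenominator <- function(ranks) {
  N <- nrow(ranks); k <- ncol(ranks)
  ties <- apply(ranks, 1L, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  N * k * (k + 1) - sum(ties) / (k - 1)
}

#' Friedman two-way analysis of variance by ranks
#'
#' Ranks each row (subject) across the k columns (conditions) with
#' mid-ranks for ties and computes the tie-corrected Friedman statistic
#' \deqn{F_r = \frac{12 \sum_j (R_j - N(k+1)/2)^2}
#'                  {N k (k+1) - \sum (t^3 - t)/(k-1)}}
#' where \eqn{R_j} are column rank sums and the tie term sums over tie
#' groups within rows. The p value comes from an exact permutation null
#' (all within-row rank permutations, computed by dynamic programming)
#' for N <= 8 and k <= 3, and from the chi-squared approximation with
#' k - 1 degrees of freedom otherwise.
#'
#' @param matrix numeric N x k matrix, N subjects (rows) by k conditions
#'   (columns), no missing cells; N >= 2, k >= 2.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact null;
#'   `NULL` (default) selects it automatically for N <= 8, k <= 3.
#' @return A [FriedmanResult-class].
#' @examples
#' m <- rbind(c(75, 66, 64), c(80, 70, 60), c(72, 65, 66), c(78, 69, 62))
#' friedmanRanks(m)
#' @export
friedmanRanks <- function(matrix, exact = NULL) {
  m <- as.matrix(matrix)
  if (anyNA(m)) stop("missing cells are not allowed")
  N <- nrow(m); k <- ncol(m)
  if (N < 2L || k < 2L) stop("need at least 2 rows and 2 columns")
  ranks <- t(apply(m, 1L, rank))
  Rj <- colSums(ranks)
  denom <- .friedmanDenominator(ranks)
  ## fully tied rows make the correction term degenerate: no evidence
  Fr <- if (denom <= 0) 0 else 12 * sum((Rj - N * (k + 1) / 2)^2) / denom
  useExact <- if (is.null(exact)) (N <= 8L && k <= 3L) else isTRUE(exact)
  if (useExact && k <= 3L) {
    p <- .friedmanExactP(ranks, Fr)
    method <- "exact"
  } else {
    p <- stats::pchisq(Fr, df = k - 1L, lower.tail = FALSE)
    method <- "chisq"
  }
  new("FriedmanResult", Fr = Fr, N = as.integer(N), k = as.integer(k),
      p = p, pMethod = method, rankSums = as.numeric(Rj))
}

#' Post-hoc multiple comparisons after a Friedman test
#'
#' All-pairs rank-sum comparisons with the normal-approximation
#' criterion: columns u and v differ at family level `alpha` iff
#' \deqn{|R_u - R_v| \ge z_{\alpha / (k (k - 1))} \sqrt{N k (k+1) / 6}.}
#'
#' @param result a [FriedmanResult-class] (provides N, k and rank sums).
#' @param alpha family-wise significance level in (0, 1).
#' @return data.frame with one row per pair: columns `i`, `j`,
#'   `rankSumDiff`, `critical`, `significant`.
#' @export
multipleComparisons <- function(result, alpha = 0.05) {
  stopifnot(is(result, "FriedmanResult"))
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must be in (0, 1)")
  k <- result@k; N <- result@N
  z <- stats::qnorm(1 - alpha / (k * (k - 1)))
  crit <- z * sqrt(N * k * (k + 1) / 6)
  pairs <- utils::combn(k, 2L)
  diffs <- abs(result@rankSums[pairs[1L, ]] - result@rankSums[pairs[2L, ]])
  data.frame(i = pairs[1L, ], j = pairs[2L, ], rankSumDiff = diffs,
             critical = crit, significant = diffs >= crit)
}

#' Pool trial records into identification scores
#'
#' Aggregates a trial table (one row per participant x condition x
#' sentence, with space-delimited `reference` and `response` mora
#' strings) into percent-correct mora identification per participant x
#' stimulus type x segment duration, pooling the morae of all sentences
#' of a condition.
#'
#' @param trials data.frame with columns `participant`, `stimType`,
#'   `segmentMs`, `reference`, `response`.
#' @return data.frame with columns `participant`, `stimType`,
#'   `segmentMs`, `scorePct`, `nMorae`.
#' @export
identificationScores <- function(trials) {
  need <- c("participant", "stimType", "segmentMs", "reference", "response")
  if (!all(need %in% names(trials)))
    stop("trials must have columns ", paste(need, collapse = ", "))
  key <- interaction(trials$participant, trials$stimType, trials$segmentMs,
                     drop = TRUE)
  parts <- split(trials, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    nref <- 0L; ncorr <- 0
    for (i in seq_len(nrow(d))) {
      ref <- .moraTokens(d$reference[i])
      ncorr <- ncorr + .lcsLength(.moraTokens(d$response[i]), ref)
      nref <- nref + length(ref)
    }
    data.frame(participant = d$participant[1L], stimType = d$stimType[1L],
               segmentMs = d$segmentMs[1L],
               scorePct = 100 * ncorr / nref, nMorae = nref,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$participant, out$stimType, out$segmentMs), ]
}

#' Per-participant 50 % points from a score table
#'
#' Applies [threshold50()] to each participant x stimulus type of an
#' [identificationScores()] table.
#'
#' @param scores output of [identificationScores()].
#' @return data.frame with columns `participant`, `stimType`,
#'   `threshold50Ms` (NA where the curve never crosses 50 %).
#' @export
thresholdTable <- function(scores) {
  key <- interaction(scores$participant, scores$stimType, drop = TRUE)
  out <- do.call(rbind, lapply(split(scores, key), function(d) {
    d <- d[order(d$segmentMs), ]
    th <- tryCatch(threshold50(d$segmentMs, d$scorePct),
                   error = function(e) NA_real_)
    data.frame(participant = d$participant[1L], stimType = d$stimType[1L],
               threshold50Ms = th, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$participant, out$stimType), ]
}
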