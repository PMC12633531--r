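# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (and stats::fisher.test) so that every compared
# value is computed twice by different routes.

# exhaustive penalized-least-squares segmentation: enumerate all 2^(n-1)
# segmentations via boundary bitmasks
pcfExhaustive <- function(values, gamma) {
  n <- length(values)
  best <- Inf
  bestSegs <- NULL
  for (mask in 0:(2^(max(n - 1, 0)) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(seq_len(max(n - 1, 0)) - 1)) > 0)
    starts <- c(1, cuts + 1)
    ends <- c(cuts, n)
    cost <- gamma * length(starts)
    for (k in seq_along(starts)) {
      seg <- values[starts[k]:ends[k]]
      cost <- cost + sum((seg - mean(seg))^2)
    }
    if (cost < best - 1e-12) {
      best <- cost
      bestSegs <- data.frame(start = starts, end = ends)
    }
  }
  list(cost = best, segments = bestSegs)
}

pcfCost <- function(values, segments, gamma) {
  cost <- gamma * nrow(segments)
  for (k in seq_len(nrow(segments))) {
    seg <- values[segments$start[k]:segments$end[k]]
    cost <- cost + sum((seg - mean(seg))^2)
  }
  cost
}

# hypergeometric tail summations for a 2x2 table
# [[a, b], [c, d]]: margins m1 = a + b (row 1), k = a + c (col 1)
fisherOracleGreater <- function(a, b, c, d) {
  lo <- a
  hi <- min(a + b, a + c)
  sum(stats::dhyper(lo:hi, a + b, c + d, a + c))
}

fisherOracleLess <- function(a, b, c, d) {
  sum(stats::dhyper(0:a, a + b, c + d, a + c))
}

fisherOracleTwoSided <- function(a, b, c, d) {
  k <- a + c
  supp <- max(0, k - (c + d)):min(a + b, k)
  probs <- stats::dhyper(supp, a + b, c + d, k)
  pObs <- stats::dhyper(a, a + b, c + d, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# overlapping-match regex count (motif scan oracle)
regexCount <- function(seqs, pattern) {
  sum(vapply(seqs, function(s)
    length(gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1]]) -
      as.integer(gregexpr(paste0("(?=", pattern, ")"), s,
                          perl = TRUE)[[1]][1] == -1),
    numeric(1)))
}

# product-limit estimator computed by hand
kmOracle <- function(time, status) {
  ut <- sort(unique(time[status == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    atRisk <- sum(time >= ut[i])
    died <- sum(time == ut[i] & status == 1)
    s <- s * (1 - died / atRisk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}
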