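# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately avoid the package's own code paths.

# Pearson r via explicit double loop over the covariance definition.
bruteForcePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Two-group log-rank chi-square by walking the 2x2 table at every distinct
# event time: hypergeometric mean and variance of group-A events.
bruteForceLogrank <- function(tA, eA, tB, eB) {
  times <- c(tA, tB)
  events <- as.logical(c(eA, eB))
  inA <- rep(c(TRUE, FALSE), c(length(tA), length(tB)))
  eventTimes <- sort(unique(times[events]))
  O <- 0; E <- 0; V <- 0
  for (t in eventTimes) {
    atRisk <- times >= t
    n <- sum(atRisk)
    nA <- sum(atRisk & inA)
    d <- sum(events & times == t)
    dA <- sum(events & times == t & inA)
    O <- O + dA
    E <- E + d * nA / n
    if (n > 1)
      V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Exact two-sided rank-sum p-value by full enumeration with midranks,
# written independently of the package (different combinatorial path).
enumerateWilcoxonP <- function(x, y) {
  pooled <- c(x, y)
  rk <- rank(pooled)
  n1 <- length(x)
  w <- sum(rk[seq_len(n1)])
  idx <- utils::combn(length(pooled), n1, simplify = FALSE)
  sums <- vapply(idx, function(i) sum(rk[i]), numeric(1))
  pLo <- sum(sums <= w + 1e-9) / length(sums)
  pHi <- sum(sums >= w - 1e-9) / length(sums)
  min(1, 2 * min(pLo, pHi))
}

# Empirical (no-censoring) survival function at the distinct event times.
empiricalSurvival <- function(times, evalAt) {
  vapply(evalAt, function(t) mean(times > t), numeric(1))
}
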