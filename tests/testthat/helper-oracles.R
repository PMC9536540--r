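# Independent oracles used to validate the package implementations.

# Naive exhaustive-scan kNN: per-query loop, explicit distance computation,
# explicit tie rules (distance ties -> lower row index; vote ties -> tied
# class with the nearest representative).
naiveKnnOracle <- function(trainX, trainY, query, k) {
  trainY <- as.factor(trainY)
  d <- numeric(nrow(trainX))
  for (i in seq_len(nrow(trainX))) {
    d[i] <- sqrt(sum((trainX[i, ] - query)^2))
  }
  ord <- order(d, seq_along(d))
  nb <- trainY[ord[1:k]]
  counts <- sapply(levels(trainY), function(cl) sum(nb == cl))
  best <- names(counts)[counts == max(counts)]
  if (length(best) > 1L) {
    nearestRank <- sapply(best, function(cl) min(which(nb == cl)))
    best <- best[order(nearestRank)][1L]
  }
  factor(best, levels = levels(trainY))
}

# Exact Wilcoxon signed-rank null: enumerate all 2^n sign assignments of the
# (tie-averaged) ranks of |d| and compute the two-tailed p for the observed
# positive rank sum. Uses the mid-p convention (the probability mass exactly
# at the observed statistic counts half), the standard reference when judging
# a continuity-uncorrected normal approximation against a discrete exact
# distribution.
exactWilcoxonP <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d), ties.method = "average")
  wObs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wAll <- as.vector(signs %*% rk)
  mu <- n * (n + 1) / 4
  dev <- abs(wAll - mu)
  devObs <- abs(wObs - mu)
  mean(dev > devObs + 1e-9) + 0.5 * mean(abs(dev - devObs) <= 1e-9)
}

# Small well-separated two-cloud dataset builder.
makeCloudData <- function(n = 40, noiseD = 4, sep = 10, seed = 1) {
  set.seed(seed)
  lab <- rep(c(0, 1), each = n / 2)
  sig <- matrix(rnorm(n * 2), n, 2) + sep * (2 * lab - 1)
  noise <- matrix(rnorm(n * noiseD), n, noiseD)
  FSDataset(cbind(sig, noise), lab, name = "clouds",
            informative = c(1L, 2L))
}
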