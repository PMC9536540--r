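## Experimental harness: repeated independent runs, aggregate statistics,
## Friedman mean ranks and Wilcoxon signed-rank comparisons across
## algorithms, and the search-space-size utility.

#' Repeated feature-selection runs
#'
#' Executes `nRuns` independent [selectFeatures()] runs, run `r` seeded with
#' `baseSeed + r` (r = 1..nRuns), and aggregates the mean and standard
#' deviation of the best fitness, the mean hold-out metrics, the average
#' selected-feature count and the mean wall time. All per-run results,
#' including full convergence histories, are preserved. The SD over a single
#' run is 0 by convention.
#'
#' @param dataset an [FSDataset-class].
#' @param control an [FSControl-class]; its `seed` slot is overridden per
#'   run.
#' @param nRuns number of independent runs (the reference protocol uses 20).
#' @param baseSeed base seed.
#' @return A [BenchmarkSummary-class].
#' @export
runBenchmark <- function(dataset, control = fsControl(), nRuns = 20L,
                         baseSeed = 0L) {
  if (nRuns < 1L) stop("'nRuns' must be >= 1")
  seeds <- as.integer(baseSeed) + seq_len(nRuns)
  runs <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    ctrl <- control
    ctrl@seed <- seeds[r]
    runs[[r]] <- tryCatch(
      selectFeatures(dataset, ctrl),
      error = function(e) stop("run ", r, " (seed ", seeds[r], ") failed: ",
                               conditionMessage(e))
    )
  }
  fits <- vapply(runs, function(x) x@cvError, numeric(1))
  vm <- vapply(runs, function(x) x@validation, numeric(3))
  new("BenchmarkSummary",
    runs = runs,
    meanFitness = mean(fits),
    sdFitness = if (nRuns == 1L) 0 else stats::sd(fits),
    meanAccuracy = mean(vm["accuracy", ]),
    meanPrecision = mean(vm["precision", ]),
    meanFMeasure = mean(vm["fMeasure", ]),
    meanNSelected = mean(vapply(runs, function(x) x@nSelected, integer(1))),
    meanElapsed = mean(vapply(runs, function(x) x@elapsed, numeric(1))),
    seeds = seeds,
    datasetName = dataset@name
  )
}

#' Friedman mean ranks
#'
#' Within each dataset row the present scores are ranked ascending (lower
#' score = better = rank 1, ties receive average ranks); each algorithm's
#' mean rank averages over the rows where it is present. Rows with fewer
#' than two present entries are skipped with a warning.
#'
#' @param scoreTable numeric matrix or data.frame, rows = datasets,
#'   columns = algorithms, `NA` = missing.
#' @return Named numeric vector of mean ranks, one per algorithm.
#' @examples
#' friedmanMeanRanks(rbind(c(0.1, 0.2, 0.3),
#'                         c(0.3, 0.1, 0.2),
#'                         c(0.2, 0.3, 0.1))) # all 2
#' @export
friedmanMeanRanks <- function(scoreTable) {
  scoreTable <- as.matrix(scoreTable)
  if (ncol(scoreTable) < 2L) stop("at least 2 algorithms are required")
  algos <- colnames(scoreTable)
  if (is.null(algos)) algos <- paste0("algo", seq_len(ncol(scoreTable)))
  rankSum <- numeric(ncol(scoreTable))
  rankN <- integer(ncol(scoreTable))
  usable <- 0L
  for (r in seq_len(nrow(scoreTable))) {
    row <- scoreTable[r, ]
    present <- which(!is.na(row))
    if (length(present) < 2L) {
      warning("row ", r, " has fewer than 2 present entries; skipped")
      next
    }
    usable <- usable + 1L
    rk <- rank(row[present], ties.method = "average")
    rankSum[present] <- rankSum[present] + rk
    rankN[present] <- rankN[present] + 1L
  }
  if (usable == 0L) stop("no usable rows in the score table")
  out <- rankSum / pmax(rankN, 1L)
  out[rankN == 0L] <- NA_real_
  stats::setNames(out, algos)
}

#' Wilcoxon signed-rank test (paired, asymptotic)
#'
#' Paired comparison of two algorithms' per-dataset scores. Zero differences
#' are dropped and reported as ties; the absolute values of the remaining
#' differences are ranked with average ranks; the negative and positive rank
#' sums, the normal-approximation Z (tie-corrected variance, no continuity
#' correction) and the two-tailed p value are reported.
#'
#' @param x,y equal-length paired score vectors.
#' @return List with `nNegative`, `nPositive`, `nTies`, `negativeRankSum`,
#'   `positiveRankSum`, `meanNegativeRank`, `meanPositiveRank`, `z`,
#'   `pValue`.
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3, 4, 5, 6), c(0, 1, 2, 3, 4, 5))
#' @export
wilcoxonSignedRank <- function(x, y) {
  if (length(x) != length(y) || length(x) == 0L) {
    stop("'x' and 'y' must be non-empty and of equal length")
  }
  d <- x - y
  ties <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("all paired differences are zero; no test possible (all ties)")
  }
  rk <- rank(abs(d), ties.method = "average")
  wPos <- sum(rk[d > 0])
  wNeg <- sum(rk[d < 0])
  mu <- n * (n + 1) / 4
  # variance with tie correction on the ranks of |d|
  tieTab <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tieTab^3 - tieTab) / 48
  z <- (wPos - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(
    nNegative = sum(d < 0), nPositive = sum(d > 0), nTies = as.integer(ties),
    negativeRankSum = wNeg, positiveRankSum = wPos,
    meanNegativeRank = if (any(d < 0)) wNeg / sum(d < 0) else NA_real_,
    meanPositiveRank = if (any(d > 0)) wPos / sum(d > 0) else NA_real_,
    z = z, pValue = min(p, 1)
  )
}

#' Size of the feature-subset search space
#'
#' The number of possible feature subsets, `2^nFeatures`. The numeric form
#' is exact in double precision for `nFeatures <= 1023` (a power of two);
#' `exact = TRUE` additionally returns the full decimal expansion as a
#' string, computed by schoolbook doubling.
#'
#' @param nFeatures number of features (>= 1).
#' @param exact also return the exact decimal digits.
#' @return The numeric value `2^nFeatures`; with `exact = TRUE`, a list with
#'   elements `value` (numeric) and `digits` (character).
#' @examples
#' searchSpaceSize(10) # 1024
#' signif(searchSpaceSize(1000), 7)
#' @export
searchSpaceSize <- function(nFeatures, exact = FALSE) {
  nFeatures <- as.integer(nFeatures)
  if (is.na(nFeatures) || nFeatures < 1L) {
    stop("'nFeatures' must be a positive integer")
  }
  value <- 2^nFeatures
  if (!exact) return(value)
  digits <- c(1L)  # little-endian decimal digits
  for (i in seq_len(nFeatures)) {
    digits <- digits * 2L
    carry <- 0L
    for (j in seq_along(digits)) {
      digits[j] <- digits[j] + carry
      carry <- digits[j] %/% 10L
      digits[j] <- digits[j] %% 10L
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  list(value = value, digits = paste(rev(digits), collapse = ""))
}
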