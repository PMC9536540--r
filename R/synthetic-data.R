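## Synthetic high-dimensional classification data: Gaussian class-conditional
## informative features, redundant linear combinations, and pure-noise
## features, emulating the sample-starved microarray regime (tens of
## instances, thousands of features, a small informative core).

#' Generate a synthetic high-dimensional dataset
#'
#' Labels are balanced across classes up to rounding. Informative features
#' are Gaussian with unit SD and class-specific means: the class centroids
#' sit at the vertices of a regular simplex scaled so that every pair of
#' centroids is `classShift` apart in the simplex coordinates, and the
#' simplex coordinates are tiled across the informative features (for two
#' classes this puts the per-feature class means `classShift/sqrt(2)` apart).
#' Redundant features are random linear combinations of the informative ones
#' plus Gaussian noise of SD `redundancyNoise`; all remaining features are
#' i.i.d. standard Gaussian, independent of the labels. The feature order is
#' randomly permuted and the ground-truth informative indices are recorded in
#' the result. The whole construction is a deterministic function of `seed`.
#'
#' @param nInstances number of instances.
#' @param nFeatures total number of features.
#' @param nInformative number of label-carrying features.
#' @param nRedundant number of features linearly derived from informative
#'   ones.
#' @param nClasses number of classes (>= 2).
#' @param classShift between-class centroid separation, in noise-SD units.
#' @param redundancyNoise SD of the noise added to redundant features.
#' @param seed integer seed; NA uses the ambient RNG state.
#' @param name dataset name.
#' @return An [FSDataset-class] with the `informative` slot filled.
#' @examples
#' d <- makeSyntheticData(60, 1000, nInformative = 10, seed = 1)
#' table(d@labels)
#' length(d@informative)
#' @export
makeSyntheticData <- function(nInstances, nFeatures, nInformative = 10L,
                              nRedundant = 0L, nClasses = 2L, classShift = 3,
                              redundancyNoise = 0.1, seed = NA_integer_,
                              name = "synthetic") {
  nInstances <- as.integer(nInstances); nFeatures <- as.integer(nFeatures)
  nInformative <- as.integer(nInformative); nRedundant <- as.integer(nRedundant)
  nClasses <- as.integer(nClasses)
  if (nInformative + nRedundant > nFeatures) {
    stop("nInformative + nRedundant must not exceed nFeatures")
  }
  if (nClasses < 2L) stop("at least 2 classes are required")
  if (nInstances < 2L * nClasses) {
    stop("nInstances must be at least 2 * nClasses")
  }
  if (classShift < 0) stop("classShift must be non-negative")
  if (nInformative < 1L) stop("at least 1 informative feature is required")
  withSeed(seed, {
    labels <- factor(rep_len(seq_len(nClasses) - 1L, nInstances))
    # regular simplex: rows of centered identity have pairwise distance
    # sqrt(2); scale so centroid pairs are classShift apart
    simplex <- (diag(nClasses) - 1 / nClasses) * classShift / sqrt(2)
    centroids <- simplex[, rep_len(seq_len(nClasses), nInformative),
                         drop = FALSE]
    inf <- matrix(stats::rnorm(nInstances * nInformative),
                  nInstances, nInformative)
    inf <- inf + centroids[as.integer(labels), , drop = FALSE]
    blocks <- list(inf)
    if (nRedundant > 0L) {
      w <- matrix(stats::rnorm(nInformative * nRedundant),
                  nInformative, nRedundant)
      w <- sweep(w, 2L, sqrt(colSums(w^2)), "/")
      red <- inf %*% w +
        matrix(stats::rnorm(nInstances * nRedundant), nInstances) *
          redundancyNoise
      blocks <- c(blocks, list(red))
    }
    nNoise <- nFeatures - nInformative - nRedundant
    if (nNoise > 0L) {
      blocks <- c(blocks, list(matrix(stats::rnorm(nInstances * nNoise),
                                      nInstances, nNoise)))
    }
    x <- do.call(cbind, blocks)
    perm <- sample.int(nFeatures)
    x <- x[, perm, drop = FALSE]
    informative <- which(perm <= nInformative)  # new positions of the core
    FSDataset(x, labels,
      featureIds = paste0("f", seq_len(nFeatures) - 1L),
      name = name, informative = informative
    )
  })
}

#' Fixed toy dataset for exact regression tests
#'
#' An 8-instance, 6-feature, 2-class dataset hard-coded in the package:
#' features 1 and 2 separate the classes at roughly +/-5 with small jitter,
#' features 3--6 are zero-mean noise. Useful for exact, enumerable checks
#' (e.g. leave-one-out kNN).
#'
#' @return An [FSDataset-class] named `"toy"`, with `informative = c(1, 2)`.
#' @examples
#' dim(toyFixture())
#' @export
toyFixture <- function() {
  x <- matrix(c(
    #   f0      f1      f2      f3      f4      f5
     5.21,   4.83,   0.31,  -0.62,   0.45,  -1.10,
     4.77,   5.36,  -0.88,   0.14,  -0.37,   0.52,
     5.48,   4.65,   0.72,   0.95,  -1.21,  -0.08,
     4.92,   5.10,  -0.15,  -1.03,   0.66,   0.89,
    -5.12,  -4.95,   0.58,   0.27,  -0.74,   0.33,
    -4.69,  -5.27,  -0.41,  -0.85,   1.02,  -0.56,
    -5.33,  -4.58,   0.19,   0.71,   0.08,   1.15,
    -4.86,  -5.04,  -0.97,  -0.22,  -0.49,  -0.91
  ), nrow = 8, byrow = TRUE)
  FSDataset(x, rep(c(1L, 0L), each = 4L),
    featureIds = paste0("f", 0:5), name = "toy", informative = c(1L, 2L)
  )
}
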