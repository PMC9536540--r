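#' @import methods
NULL

#' High-dimensional classification dataset
#'
#' Container for an instances-by-features numeric matrix with a categorical
#' class label per instance, the shape typical of microarray gene-expression
#' benchmarks (tens of samples, thousands of features, 2--20 classes).
#'
#' @slot features numeric matrix, instances in rows, features in columns.
#' @slot labels factor of length `nrow(features)`.
#' @slot featureIds character vector of feature identifiers.
#' @slot name single character, dataset name.
#' @slot informative integer vector of ground-truth informative feature
#'   indices (1-based); empty when unknown (real data).
#'
#' @seealso [FSDataset()], [makeSyntheticData()], [readDataset()]
#' @exportClass FSDataset
setClass("FSDataset",
  representation(
    features = "matrix",
    labels = "factor",
    featureIds = "character",
    name = "character",
    informative = "integer"
  )
)

setValidity("FSDataset", function(object) {
  msg <- character()
  x <- object@features
  if (!is.numeric(x)) msg <- c(msg, "'features' must be a numeric matrix")
  if (anyNA(x)) msg <- c(msg, "'features' contains missing values")
  if (length(object@labels) != nrow(x)) {
    msg <- c(msg, "length(labels) must equal nrow(features)")
  }
  if (anyNA(object@labels)) msg <- c(msg, "'labels' contains missing values")
  if (nlevels(droplevels(object@labels)) < 2L) {
    msg <- c(msg, "at least 2 distinct classes are required")
  }
  if (length(object@featureIds) != ncol(x)) {
    msg <- c(msg, "length(featureIds) must equal ncol(features)")
  }
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be a single string")
  if (length(object@informative) &&
      (min(object@informative) < 1L || max(object@informative) > ncol(x))) {
    msg <- c(msg, "'informative' indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an FSDataset
#'
#' @param features numeric matrix (instances x features) or data.frame of
#'   numeric columns.
#' @param labels vector coercible to factor, one label per instance.
#' @param featureIds optional feature identifiers; defaults to the matrix
#'   column names, or `f0 ... f(D-1)` when absent.
#' @param name dataset name.
#' @param informative optional integer vector of ground-truth informative
#'   feature indices.
#' @return An [FSDataset-class] object.
#' @examples
#' d <- FSDataset(matrix(rnorm(40), 10, 4), rep(c("a", "b"), 5))
#' dim(d)
#' @export
FSDataset <- function(features, labels, featureIds = NULL, name = "dataset",
                      informative = integer()) {
  if (is.data.frame(features)) features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (any(table(droplevels(as.factor(labels))) < 2L)) {
    stop("every class must have at least 2 instances")
  }
  if (is.null(featureIds)) {
    featureIds <- colnames(features)
    if (is.null(featureIds)) {
      featureIds <- paste0("f", seq_len(ncol(features)) - 1L)
    }
  }
  new("FSDataset",
    features = features, labels = droplevels(as.factor(labels)),
    featureIds = as.character(featureIds), name = as.character(name)[1L],
    informative = as.integer(informative)
  )
}

#' Dwarf mongoose optimizer settings
#'
#' All knobs of the continuous dwarf mongoose optimizer: population size,
#' babysitter count, iteration budget, the alpha's vocalization coefficient
#' (peep), the babysitter exchange threshold L, box bounds and seed.
#'
#' @slot nAgents total population size n.
#' @slot nBabysitters number of babysitters bs (sidelined agents).
#' @slot maxIter iteration budget.
#' @slot peep step-size multiplier of the alpha's foraging call.
#' @slot exchangeL babysitter exchange threshold L; `NA` means AUTO,
#'   resolved to `round(0.6 * D * bs)` (at least 1) at run time.
#' @slot lowerBound,upperBound box bounds, scalar or per-dimension.
#' @slot seed integer seed; `NA` means "use the current RNG state".
#' @slot alphaMode `"inverse"` (default; lower error = higher alpha
#'   probability) or `"literal"` (fitness-proportional as printed, which under
#'   minimization favours worse agents -- kept for fidelity).
#' @exportClass DMOControl
setClass("DMOControl",
  representation(
    nAgents = "integer",
    nBabysitters = "integer",
    maxIter = "integer",
    peep = "numeric",
    exchangeL = "integer",
    lowerBound = "numeric",
    upperBound = "numeric",
    seed = "integer",
    alphaMode = "character"
  )
)

setValidity("DMOControl", function(object) {
  msg <- character()
  if (object@nAgents < 1L) msg <- c(msg, "nAgents must be >= 1")
  if (object@nBabysitters < 0L) msg <- c(msg, "nBabysitters must be >= 0")
  if (object@nAgents <= object@nBabysitters) {
    msg <- c(msg, "nAgents must exceed nBabysitters")
  }
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (!is.finite(object@peep) || object@peep < 0) {
    msg <- c(msg, "peep must be finite and non-negative")
  }
  if (!is.na(object@exchangeL) && object@exchangeL < 1L) {
    msg <- c(msg, "exchangeL must be >= 1 (or NA for AUTO)")
  }
  if (length(object@lowerBound) != length(object@upperBound)) {
    msg <- c(msg, "bounds must have equal length")
  }
  if (!all(is.finite(object@lowerBound)) || !all(is.finite(object@upperBound))) {
    msg <- c(msg, "bounds must be finite")
  } else if (!all(object@lowerBound < object@upperBound)) {
    msg <- c(msg, "lowerBound must be < upperBound in every dimension")
  }
  if (!object@alphaMode %in% c("inverse", "literal")) {
    msg <- c(msg, "alphaMode must be 'inverse' or 'literal'")
  }
  if (length(msg)) msg else TRUE
})

#' @param nAgents,nBabysitters,maxIter,peep,exchangeL,lowerBound,upperBound,seed,alphaMode
#'   see the class slots.
#' @return A [DMOControl-class] object.
#' @examples
#' dmoControl(nAgents = 10, maxIter = 100)
#' @rdname DMOControl-class
#' @export
dmoControl <- function(nAgents = 10L, nBabysitters = 3L, maxIter = 100L,
                       peep = 2.0, exchangeL = NA_integer_,
                       lowerBound = 0, upperBound = 1,
                       seed = NA_integer_, alphaMode = c("inverse", "literal")) {
  new("DMOControl",
    nAgents = as.integer(nAgents), nBabysitters = as.integer(nBabysitters),
    maxIter = as.integer(maxIter), peep = as.numeric(peep),
    exchangeL = as.integer(exchangeL),
    lowerBound = as.numeric(lowerBound), upperBound = as.numeric(upperBound),
    seed = as.integer(seed), alphaMode = match.arg(alphaMode)
  )
}

#' Feature-selection settings
#'
#' Extends [DMOControl-class] with the wrapper-objective knobs: the kNN
#' neighbourhood size, the number of cross-validation folds, the hold-out
#' fraction, the binarization threshold, the all-zero-mask repair policy and
#' optional z-score standardization.
#'
#' @slot kNeighbors kNN neighbourhood size (default 5).
#' @slot nFolds cross-validation folds (default 10); auto-reduced with a
#'   warning to the smallest class count in the training split when
#'   infeasible.
#' @slot testFraction hold-out fraction (default 0.2, i.e. an 80/20 split).
#' @slot threshold binarization threshold in (0,1); a coordinate strictly
#'   above it selects the feature.
#' @slot repairPolicy `"random_one"` (set one random bit in an all-zero mask)
#'   or `"penalty"` (leave the mask, score it with the worst error 1.0).
#' @slot standardize fit a z-score scaling on training folds only.
#' @exportClass FSControl
setClass("FSControl",
  contains = "DMOControl",
  representation(
    kNeighbors = "integer",
    nFolds = "integer",
    testFraction = "numeric",
    threshold = "numeric",
    repairPolicy = "character",
    standardize = "logical"
  )
)

setValidity("FSControl", function(object) {
  msg <- character()
  if (object@kNeighbors < 1L) msg <- c(msg, "kNeighbors must be >= 1")
  if (object@nFolds < 2L) msg <- c(msg, "nFolds must be >= 2")
  if (object@testFraction <= 0 || object@testFraction >= 1) {
    msg <- c(msg, "testFraction must be in (0,1)")
  }
  if (object@threshold <= 0 || object@threshold >= 1) {
    msg <- c(msg, "threshold must be in (0,1)")
  }
  if (!object@repairPolicy %in% c("random_one", "penalty")) {
    msg <- c(msg, "repairPolicy must be 'random_one' or 'penalty'")
  }
  if (length(msg)) msg else TRUE
})

#' @param kNeighbors,nFolds,testFraction,threshold,repairPolicy,standardize
#'   see the class slots.
#' @param ... arguments passed to [dmoControl()].
#' @return An [FSControl-class] object.
#' @examples
#' fsControl(maxIter = 50, seed = 1)
#' @rdname FSControl-class
#' @export
fsControl <- function(kNeighbors = 5L, nFolds = 10L, testFraction = 0.2,
                      threshold = 0.5,
                      repairPolicy = c("random_one", "penalty"),
                      standardize = FALSE, ...) {
  base <- dmoControl(...)
  new("FSControl", base,
    kNeighbors = as.integer(kNeighbors), nFolds = as.integer(nFolds),
    testFraction = as.numeric(testFraction), threshold = as.numeric(threshold),
    repairPolicy = match.arg(repairPolicy), standardize = isTRUE(standardize)
  )
}

#' Result of a continuous optimizer run
#'
#' @slot bestPosition best-ever position.
#' @slot bestFitness best-ever (minimal) fitness.
#' @slot history per-iteration best-ever fitness, length `maxIter`;
#'   non-increasing by elitism.
#' @slot nEvaluations number of fitness-function calls.
#' @slot elapsed wall time, seconds.
#' @exportClass DMORun
setClass("DMORun",
  representation(
    bestPosition = "numeric",
    bestFitness = "numeric",
    history = "numeric",
    nEvaluations = "integer",
    elapsed = "numeric"
  )
)

setValidity("DMORun", function(object) {
  msg <- character()
  h <- object@history
  if (length(h) && any(diff(h) > 0)) {
    msg <- c(msg, "history must be non-increasing (elitism)")
  }
  if (length(h) && h[length(h)] != object@bestFitness) {
    msg <- c(msg, "last history entry must equal bestFitness")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a feature-selection run
#'
#' @slot mask best binary feature mask (integer 0/1 of length D).
#' @slot cvError cross-validated classification error of the best mask.
#' @slot history per-iteration best-ever cross-validation error.
#' @slot validation named numeric: `accuracy`, `precision`, `fMeasure` on the
#'   held-out split.
#' @slot nSelected number of selected features.
#' @slot featureIds feature identifiers (length D).
#' @slot elapsed wall time, seconds.
#' @slot seed seed used for the run (NA if the ambient RNG state was used).
#' @slot control the [FSControl-class] actually used, with AUTO values
#'   resolved.
#' @slot nEvaluations number of fitness evaluations.
#' @exportClass FeatureSelectionResult
setClass("FeatureSelectionResult",
  representation(
    mask = "integer",
    cvError = "numeric",
    history = "numeric",
    validation = "numeric",
    nSelected = "integer",
    featureIds = "character",
    elapsed = "numeric",
    seed = "integer",
    control = "FSControl",
    nEvaluations = "integer"
  )
)

setValidity("FeatureSelectionResult", function(object) {
  msg <- character()
  if (!all(object@mask %in% c(0L, 1L))) msg <- c(msg, "mask must be 0/1")
  if (object@nSelected != sum(object@mask)) {
    msg <- c(msg, "nSelected must equal sum(mask)")
  }
  if (object@cvError < 0 || object@cvError > 1) {
    msg <- c(msg, "cvError must lie in [0,1]")
  }
  if (length(object@history) && any(diff(object@history) > 0)) {
    msg <- c(msg, "history must be non-increasing")
  }
  if (any(object@validation < 0 | object@validation > 1)) {
    msg <- c(msg, "validation metrics must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' Aggregate of repeated feature-selection runs
#'
#' @slot runs list of [FeatureSelectionResult-class], one per independent run.
#' @slot meanFitness,sdFitness mean and SD of the per-run best
#'   cross-validation errors (SD is 0 for a single run, by convention).
#' @slot meanAccuracy,meanPrecision,meanFMeasure mean hold-out metrics.
#' @slot meanNSelected mean number of selected features.
#' @slot meanElapsed mean wall time per run, seconds.
#' @slot seeds seed used by each run.
#' @slot datasetName name of the dataset benchmarked.
#' @exportClass BenchmarkSummary
setClass("BenchmarkSummary",
  representation(
    runs = "list",
    meanFitness = "numeric",
    sdFitness = "numeric",
    meanAccuracy = "numeric",
    meanPrecision = "numeric",
    meanFMeasure = "numeric",
    meanNSelected = "numeric",
    meanElapsed = "numeric",
    seeds = "integer",
    datasetName = "character"
  )
)

setValidity("BenchmarkSummary", function(object) {
  msg <- character()
  fits <- vapply(object@runs, function(r) r@cvError, numeric(1))
  if (length(fits) &&
      (object@meanFitness < min(fits) - 1e-12 ||
       object@meanFitness > max(fits) + 1e-12)) {
    msg <- c(msg, "meanFitness must lie within [min, max] of run fitnesses")
  }
  if (object@sdFitness < 0) msg <- c(msg, "sdFitness must be >= 0")
  if (length(msg)) msg else TRUE
})
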