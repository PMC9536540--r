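## Binary adaptation and the wrapper objective: thresholding continuous
## positions into feature masks, mask repair, Euclidean kNN, the
## cross-validated classification-error fitness, the stratified 80/20
## protocol, and the end-to-end selectFeatures() entry point.

#' Threshold a continuous position into a feature mask
#'
#' A coordinate strictly above the threshold selects the feature (bit 1);
#' at or below it the feature is unselected (bit 0). The static threshold is
#' 0.5 by default.
#'
#' @param position numeric vector with coordinates in \[0, 1\].
#' @param threshold threshold in (0, 1).
#' @return Integer 0/1 mask of the same length.
#' @examples
#' binarizePosition(c(0.7, 0.3, 0.51, 0.5)) # 1 0 1 0
#' @export
binarizePosition <- function(position, threshold = 0.5) {
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0 || threshold >= 1) {
    stop("'threshold' must lie in (0, 1)")
  }
  as.integer(position > threshold)
}

#' Repair an all-zero feature mask
#'
#' A mask selecting no features cannot be scored by a classifier. Under the
#' `"random_one"` policy an all-zero mask gets exactly one uniformly chosen
#' bit set; under `"penalty"` the mask is returned unchanged and the caller
#' assigns the worst possible fitness (error 1.0). Non-zero masks pass
#' through unchanged.
#'
#' @param mask integer 0/1 vector.
#' @param policy `"random_one"` or `"penalty"`.
#' @return The (possibly repaired) mask.
#' @export
repairMask <- function(mask, policy = c("random_one", "penalty")) {
  policy <- match.arg(policy)
  if (sum(mask) > 0L || policy == "penalty") return(as.integer(mask))
  mask <- as.integer(mask)
  mask[sample.int(length(mask), 1L)] <- 1L
  mask
}

#' Euclidean distance
#'
#' @param x,y numeric vectors of equal length.
#' @return `sqrt(sum((x - y)^2))`.
#' @examples
#' euclideanDistance(c(0, 0), c(3, 4)) # 5
#' @export
euclideanDistance <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  sqrt(sum((x - y)^2))
}

# Squared Euclidean distances, queries (rows of qy) vs training rows.
distMatrixSq <- function(tr, qy) {
  d2 <- outer(rowSums(qy^2), rowSums(tr^2), "+") - 2 * tcrossprod(qy, tr)
  pmax(d2, 0)
}

#' k-nearest-neighbour prediction
#'
#' Majority vote among the k training instances nearest in Euclidean
#' distance. Distance ties are broken by lower training-row index; a tied
#' vote goes to the tied class whose nearest representative is closest
#' (then, degenerately, to the lowest label under the factor ordering).
#'
#' @param trainFeatures numeric training matrix (instances x features).
#' @param trainLabels factor (or coercible) of training labels.
#' @param query a single query vector, or a matrix with one query per row.
#' @param k neighbourhood size, `k <= nrow(trainFeatures)`.
#' @return Factor of predicted labels (length 1 for a vector query).
#' @export
knnPredict <- function(trainFeatures, trainLabels, query, k = 5L) {
  trainFeatures <- rbind(trainFeatures)
  if (nrow(trainFeatures) == 0L) stop("empty training set")
  if (k < 1L || k > nrow(trainFeatures)) {
    stop("'k' must lie in [1, number of training instances]")
  }
  trainLabels <- as.factor(trainLabels)
  if (length(trainLabels) != nrow(trainFeatures)) {
    stop("one label per training instance is required")
  }
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  if (ncol(query) != ncol(trainFeatures)) {
    stop("query and training features must have the same dimension")
  }
  d2 <- distMatrixSq(trainFeatures, query)
  lev <- levels(trainLabels)
  out <- character(nrow(query))
  for (q in seq_len(nrow(query))) {
    ord <- order(d2[q, ], seq_len(ncol(d2)))  # stable: index breaks ties
    nb <- trainLabels[ord[seq_len(k)]]
    votes <- table(nb)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      # nearest representative among tied classes wins
      first <- vapply(top, function(cl) which(nb == cl)[1L], integer(1))
      top <- top[order(first, match(top, lev))][1L]
    }
    out[q] <- top
  }
  factor(out, levels = lev)
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each instance to one of `nFolds` folds, stratified by class:
#' within each class the instances are shuffled and dealt round-robin, so
#' fold sizes and class proportions are balanced up to rounding. When
#' `nFolds` exceeds the smallest class count it is reduced to that count with
#' a warning.
#'
#' @param labels factor of class labels.
#' @param nFolds requested number of folds.
#' @return Integer vector of fold ids in `1:nFolds` (possibly reduced).
#' @export
makeFolds <- function(labels, nFolds = 10L) {
  labels <- as.factor(labels)
  minClass <- min(table(labels))
  if (nFolds > minClass) {
    warning("reducing nFolds from ", nFolds, " to the smallest class count (",
            minClass, ")")
    nFolds <- as.integer(minClass)
  }
  if (nFolds < 2L) stop("at least 2 folds are required")
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

# z-score parameters from a training block; constant columns get sd 1.
scaleParams <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

applyScale <- function(x, p) {
  sweep(sweep(x, 2L, p$mu, "-"), 2L, p$sd, "/")
}

#' Cross-validated classification error of a feature mask
#'
#' The wrapper fitness: restrict the data to the masked features, then for
#' each fold train the kNN classifier on the remaining folds and predict the
#' held fold; the error is the total number of misclassified instances
#' divided by the total number of instances. Deterministic given the fold
#' assignment.
#'
#' @param features numeric matrix (instances x features) of the training
#'   split.
#' @param labels factor of class labels.
#' @param mask integer 0/1 mask with at least one selected feature.
#' @param foldAssignment integer fold ids from [makeFolds()].
#' @param k kNN neighbourhood size.
#' @param standardize fit a z-score scaling on each fold's training block
#'   only.
#' @return Error rate in \[0, 1\].
#' @export
cvError <- function(features, labels, mask, foldAssignment, k = 5L,
                    standardize = FALSE) {
  sel <- which(mask == 1L)
  if (length(sel) == 0L) stop("'mask' must select at least one feature")
  labels <- as.factor(labels)
  x <- features[, sel, drop = FALSE]
  wrong <- 0L
  for (f in sort(unique(foldAssignment))) {
    held <- foldAssignment == f
    tr <- x[!held, , drop = FALSE]
    te <- x[held, , drop = FALSE]
    if (nrow(tr) < k) stop("fold leaves fewer training instances than 'k'")
    if (standardize) {
      p <- scaleParams(tr)
      tr <- applyScale(tr, p)
      te <- applyScale(te, p)
    }
    pred <- knnPredict(tr, labels[!held], te, k)
    wrong <- wrong + sum(pred != labels[held])
  }
  wrong / nrow(x)
}

#' Stratified train/test split
#'
#' Splits a dataset into training and testing parts (80/20 by default) with
#' per-class proportions preserved up to rounding; every class keeps at
#' least one instance on each side. The split is drawn from the current RNG
#' stream.
#'
#' @param dataset an [FSDataset-class].
#' @param testFraction fraction held out for testing, in (0, 1).
#' @return List with elements `train` and `test`, both [FSDataset-class],
#'   plus `trainIdx` and `testIdx` (row indices into the input).
#' @export
trainTestSplit <- function(dataset, testFraction = 0.2) {
  stopifnot(is(dataset, "FSDataset"))
  if (testFraction <= 0 || testFraction >= 1) {
    stop("'testFraction' must lie in (0, 1)")
  }
  labels <- dataset@labels
  if (any(table(labels) < 2L)) {
    stop("every class needs at least 2 instances to split")
  }
  trainIdx <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    nTr <- round((1 - testFraction) * length(idx))
    nTr <- min(max(nTr, 1L), length(idx) - 1L)
    trainIdx <- c(trainIdx, idx[sample.int(length(idx))][seq_len(nTr)])
  }
  trainIdx <- sort(trainIdx)
  testIdx <- setdiff(seq_along(labels), trainIdx)
  subsetFS <- function(i) {
    new("FSDataset",
      features = dataset@features[i, , drop = FALSE],
      labels = droplevels(dataset@labels[i]),
      featureIds = dataset@featureIds,
      name = dataset@name, informative = dataset@informative
    )
  }
  list(train = subsetFS(trainIdx), test = subsetFS(testIdx),
       trainIdx = trainIdx, testIdx = testIdx)
}

#' Hold-out classification metrics
#'
#' Accuracy is the complement of the classification error rate. For binary
#' problems precision, recall and F-measure refer to the positive class (the
#' second factor level); for multiclass they are macro-averaged over classes,
#' a class with no predicted positives contributing precision 0.
#'
#' @param truth,predicted equal-length factors (or coercibles).
#' @return Named numeric: `accuracy`, `precision`, `fMeasure` (and `recall`).
#' @examples
#' validationMetrics(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
#'                   c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0))
#' @export
validationMetrics <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) == 0L) {
    stop("'truth' and 'predicted' must be non-empty and of equal length")
  }
  truth <- as.factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  acc <- mean(predicted == truth)
  lev <- levels(truth)
  perClass <- function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f = f)
  }
  if (length(lev) == 2L) {
    m <- perClass(lev[2L])  # positive class = second level
  } else {
    m <- rowMeans(vapply(lev, perClass, numeric(3)))
  }
  c(accuracy = acc, precision = unname(m["precision"]),
    recall = unname(m["recall"]), fMeasure = unname(m["f"]))
}

#' Wrapper feature selection with the binary dwarf mongoose optimizer
#'
#' The end-to-end entry point. The dataset is split 80/20 (stratified); one
#' stratified fold assignment is drawn on the training split and reused for
#' every fitness evaluation, making the objective a deterministic function of
#' the mask; the optimizer searches the unit box, each position thresholded
#' by [binarizePosition()], repaired by [repairMask()], and scored by
#' [cvError()]; finally the best mask is evaluated on the held-out split with
#' [validationMetrics()].
#'
#' All randomness (split, folds, optimizer, repairs) is consumed from a
#' single stream seeded by `control@seed`, so identical seeds give
#' bit-identical results.
#'
#' @param dataset an [FSDataset-class] (or anything [asFSDataset()] accepts).
#' @param control an [FSControl-class].
#' @return A [FeatureSelectionResult-class].
#' @examples
#' fit <- selectFeatures(toyFixture(),
#'   fsControl(maxIter = 5, nAgents = 4, nBabysitters = 1,
#'             nFolds = 3, kNeighbors = 1, seed = 7))
#' selectedFeatures(fit)
#' @export
selectFeatures <- function(dataset, control = fsControl()) {
  if (!is(dataset, "FSDataset")) dataset <- asFSDataset(dataset)
  validObject(dataset); validObject(control)
  t0 <- proc.time()[["elapsed"]]
  withSeed(control@seed, {
    nDims <- ncol(dataset@features)
    split <- trainTestSplit(dataset, control@testFraction)
    train <- split$train
    folds <- makeFolds(train@labels, control@nFolds)
    nFoldsUsed <- max(folds)
    minFold <- min(table(folds))
    trainPerFold <- nrow(train@features) - max(table(folds))
    if (control@kNeighbors > trainPerFold) {
      stop("kNeighbors (", control@kNeighbors,
           ") exceeds the smallest per-fold training size (", trainPerFold, ")")
    }
    fitnessFn <- function(position) {
      mask <- binarizePosition(position, control@threshold)
      mask <- repairMask(mask, control@repairPolicy)
      if (sum(mask) == 0L) return(1.0)  # penalty policy
      cvError(train@features, train@labels, mask, folds,
              control@kNeighbors, control@standardize)
    }
    inner <- dmoControl(
      nAgents = control@nAgents, nBabysitters = control@nBabysitters,
      maxIter = control@maxIter, peep = control@peep,
      exchangeL = control@exchangeL, lowerBound = control@lowerBound,
      upperBound = control@upperBound, seed = NA_integer_,
      alphaMode = control@alphaMode
    )
    run <- dmOptimize(fitnessFn, nDims, inner)
    mask <- binarizePosition(run@bestPosition, control@threshold)
    mask <- repairMask(mask, control@repairPolicy)
    if (sum(mask) == 0L) mask[sample.int(length(mask), 1L)] <- 1L
    trX <- train@features[, mask == 1L, drop = FALSE]
    teX <- split$test@features[, mask == 1L, drop = FALSE]
    if (control@standardize) {
      p <- scaleParams(trX)
      trX <- applyScale(trX, p)
      teX <- applyScale(teX, p)
    }
    pred <- knnPredict(trX, train@labels, teX, control@kNeighbors)
    vm <- validationMetrics(
      factor(split$test@labels, levels = levels(train@labels)), pred)
    echoed <- control
    echoed@exchangeL <- resolveExchangeL(control, nDims)
    echoed@nFolds <- as.integer(nFoldsUsed)
    new("FeatureSelectionResult",
      mask = mask,
      cvError = run@bestFitness,
      history = run@history,
      validation = vm[c("accuracy", "precision", "fMeasure")],
      nSelected = sum(mask),
      featureIds = dataset@featureIds,
      elapsed = proc.time()[["elapsed"]] - t0,
      seed = control@seed,
      control = echoed,
      nEvaluations = run@nEvaluations
    )
  })
}
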