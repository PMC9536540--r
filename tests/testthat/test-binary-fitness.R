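# Binarization, mask repair, kNN, the cross-validated wrapper objective and
# the end-to-end feature-selection entry point.

test_that("binarization uses a strict threshold and is monotone", {
  expect_equal(binarizePosition(c(0.7, 0.3, 0.51, 0.5)), c(1L, 0L, 1L, 0L))
  expect_equal(binarizePosition(rep(0, 5)), rep(0L, 5))
  # the worked interpretation of a 0/1 solution vector
  bits <- c(1, 0, 0, 1, 1, 1, 0, 1, 0, 0)
  expect_equal(which(binarizePosition(bits) == 1L), c(1L, 4L, 5L, 6L, 8L))
  expect_error(binarizePosition(c(0.2, 0.8), threshold = 1.2), "threshold")

  set.seed(21)
  for (i in 1:20) {
    x <- runif(10)
    b1 <- binarizePosition(x)
    j <- sample(10, 1)
    x2 <- x; x2[j] <- min(1, x[j] + runif(1))
    b2 <- binarizePosition(x2)
    expect_true(b2[j] >= b1[j])            # monotone per coordinate
    expect_equal(binarizePosition(as.numeric(b1)), b1)  # idempotent embed
  }
})

test_that("mask repair guarantees a non-empty selection", {
  expect_equal(repairMask(c(0L, 1L, 0L)), c(0L, 1L, 0L))
  expect_equal(repairMask(rep(1L, 4)), rep(1L, 4))
  expect_equal(repairMask(rep(0L, 5), "penalty"), rep(0L, 5))
  set.seed(8)
  for (i in 1:25) {
    m <- repairMask(rep(0L, 5))
    expect_equal(sum(m), 1L)
  }
})

test_that("Euclidean distance matches hand computations", {
  expect_equal(euclideanDistance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclideanDistance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclideanDistance(c(1, 1), c(2, 2)), sqrt(2))
  expect_error(euclideanDistance(1:2, 1:3), "equal length")
})

test_that("kNN follows majority vote with the documented tie rules", {
  # single training instance
  p <- knnPredict(rbind(c(0, 0)), "A", c(5, 5), k = 1)
  expect_equal(as.character(p), "A")
  # majority among 3
  tr <- rbind(c(0, 0), c(0.1, 0), c(5, 5))
  p <- knnPredict(tr, c("A", "A", "B"), c(0, 0.05), k = 3)
  expect_equal(as.character(p), "A")
  # vote tie at k = 2: the class with the nearer representative wins
  tr <- rbind(c(0, 0), c(1, 1))
  p <- knnPredict(tr, c("A", "B"), c(0.1, 0.1), k = 2)
  expect_equal(as.character(p), "A")
  # distance tie broken by lower training-row index
  tr <- rbind(c(1, 0), c(-1, 0))
  p <- knnPredict(tr, c("B", "A"), c(0, 0), k = 1)
  expect_equal(as.character(p), "B")
  expect_error(knnPredict(tr, c("A", "B"), c(0, 0), k = 3), "k")
})

test_that("kNN agrees with the exhaustive-scan oracle on random problems", {
  set.seed(31)
  agree <- 0L; total <- 0L
  for (case in 1:100) {
    n <- sample(5:30, 1)
    D <- sample(2:5, 1)
    k <- sample(c(1, 3, 5), 1)
    k <- min(k, n)
    nc <- sample(2:3, 1)
    trX <- matrix(runif(n * D), n, D)
    trY <- factor(sample(letters[1:nc], n, replace = TRUE))
    while (nlevels(droplevels(trY)) < 2) {
      trY <- factor(sample(letters[1:nc], n, replace = TRUE))
    }
    q <- runif(D)
    total <- total + 1L
    pred <- knnPredict(trX, trY, q, k)
    orac <- naiveKnnOracle(trX, trY, q, k)
    if (as.character(pred) == as.character(orac)) agree <- agree + 1L
  }
  expect_equal(agree, total)
})

test_that("stratified folds partition every class and reduce when needed", {
  labels <- factor(rep(c("a", "b"), c(30, 10)))
  set.seed(4)
  f <- makeFolds(labels, 5)
  expect_equal(sort(unique(f)), 1:5)
  # every instance in exactly one fold, classes spread across folds
  expect_length(f, 40)
  expect_true(all(table(f, labels)[, "b"] == 2))
  set.seed(4)
  expect_warning(f2 <- makeFolds(labels, 12), "reducing nFolds")
  expect_equal(max(f2), 10)
})

test_that("cross-validated error separates signal from noise", {
  d <- makeCloudData(n = 40, noiseD = 4, sep = 10, seed = 2)
  set.seed(10)
  folds <- makeFolds(d@labels, 5)
  maskSig <- c(1L, 1L, rep(0L, 4))
  expect_equal(cvError(d@features, d@labels, maskSig, folds, k = 3), 0)
  # determinism given the fold assignment
  expect_identical(
    cvError(d@features, d@labels, maskSig, folds, k = 3),
    cvError(d@features, d@labels, maskSig, folds, k = 3)
  )
  expect_error(cvError(d@features, d@labels, rep(0L, 6), folds, 3),
               "at least one")

  # labels independent of features: error near one half
  set.seed(77)
  x <- matrix(rnorm(200 * 10), 200, 10)
  y <- rep(c(0, 1), 100)
  folds2 <- makeFolds(factor(y), 10)
  e <- cvError(x, factor(y), rep(1L, 10), folds2, k = 5)
  expect_gt(e, 0.4)
  expect_lt(e, 0.6)
  expect_true(e >= 0 && e <= 1)
})

test_that("the stratified 80/20 split is proportionate and reproducible", {
  d <- makeSyntheticData(100, 20, 5, 0, 2, 2, seed = 3)
  set.seed(6)
  sp <- trainTestSplit(d, 0.2)
  expect_equal(nrow(sp$train@features), 80)
  expect_equal(nrow(sp$test@features), 20)
  expect_setequal(c(sp$trainIdx, sp$testIdx), 1:100)
  # 50/50 classes stay balanced within one instance
  expect_true(max(abs(table(sp$train@labels) - 40)) <= 1)
  expect_true(max(abs(table(sp$test@labels) - 10)) <= 1)
  set.seed(6)
  sp2 <- trainTestSplit(d, 0.2)
  expect_identical(sp$trainIdx, sp2$trainIdx)
  # a singleton class cannot be split
  bad <- new("FSDataset",
    features = matrix(rnorm(8), 4, 2), labels = factor(c(1, 1, 1, 2)),
    featureIds = c("f0", "f1"), name = "bad", informative = integer())
  expect_error(trainTestSplit(bad, 0.2), "at least 2 instances")
})

test_that("validation metrics match hand-computed confusion counts", {
  vm <- validationMetrics(c("x", "x", "x"), c("x", "x", "x"))
  expect_equal(unname(vm[c("accuracy", "precision", "fMeasure")]),
               c(1, 1, 1))
  vm <- validationMetrics(rep(c("a", "b"), each = 5),
                          c("b", rep("a", 4), "a", rep("b", 4)))
  expect_equal(vm[["accuracy"]], 0.8)
  # binary, positive class = second level: TP=3 FP=1 FN=2 TN=4
  truth <- factor(c(rep(1, 5), rep(0, 5)), levels = c(0, 1))
  pred <- factor(c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0), levels = c(0, 1))
  vm <- validationMetrics(truth, pred)
  expect_equal(vm[["accuracy"]], 0.7)
  expect_equal(vm[["precision"]], 0.75)
  expect_equal(vm[["recall"]], 0.6)
  expect_equal(vm[["fMeasure"]], 2 * 0.75 * 0.6 / 1.35)
  # accuracy complements the error rate on the same predictions
  expect_equal(vm[["accuracy"]], 1 - mean(pred != truth))
  # macro averaging for multiclass; an unpredicted class scores precision 0
  truth3 <- factor(c("a", "a", "b", "b", "c", "c"))
  pred3 <- factor(c("a", "a", "b", "b", "a", "b"),
                  levels = c("a", "b", "c"))
  vm3 <- validationMetrics(truth3, pred3)
  expect_equal(vm3[["precision"]], mean(c(2 / 3, 2 / 3, 0)))
  expect_error(validationMetrics(c("a", "b"), "a"), "equal length")
})

test_that("selectFeatures minimizes the wrapper objective reproducibly", {
  d <- makeCloudData(n = 40, noiseD = 8, sep = 6, seed = 5)
  ctrl <- fsControl(nAgents = 6, nBabysitters = 2, maxIter = 8,
                    nFolds = 4, kNeighbors = 3, seed = 101)
  fit <- selectFeatures(d, ctrl)
  expect_s4_class(fit, "FeatureSelectionResult")
  expect_true(all(diff(convergence(fit)) <= 0))
  expect_gte(nSelected(fit), 1)
  expect_equal(nSelected(fit), length(selectedFeatures(fit)))
  expect_true(all(validation(fit) >= 0 & validation(fit) <= 1))

  fit2 <- selectFeatures(d, ctrl)
  expect_identical(bestMask(fit), bestMask(fit2))
  expect_identical(convergence(fit), convergence(fit2))
  expect_identical(validation(fit), validation(fit2))

  tiny <- selectFeatures(d, fsControl(nAgents = 2, nBabysitters = 0,
                                      maxIter = 1, nFolds = 4,
                                      kNeighbors = 3, seed = 1))
  expect_length(convergence(tiny), 1)
  expect_gte(nSelected(tiny), 1)

  expect_error(
    selectFeatures(d, fsControl(kNeighbors = 50, nFolds = 4, maxIter = 1,
                                nAgents = 2, nBabysitters = 0, seed = 1)),
    "kNeighbors")
})
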