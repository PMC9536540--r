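## Accessor and show methods for the S4 containers.

#' @rdname accessors
#' @export
setMethod("bestMask", "FeatureSelectionResult", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("bestFitness", "FeatureSelectionResult",
          function(object) object@cvError)

#' @rdname accessors
#' @export
setMethod("bestFitness", "DMORun", function(object) object@bestFitness)

#' @rdname accessors
#' @export
setMethod("convergence", "FeatureSelectionResult",
          function(object) object@history)

#' @rdname accessors
#' @export
setMethod("convergence", "DMORun", function(object) object@history)

#' @rdname accessors
#' @export
setMethod("convergence", "BenchmarkSummary", function(object) {
  do.call(rbind, lapply(object@runs, function(r) r@history))
})

#' @rdname accessors
#' @export
setMethod("selectedFeatures", "FeatureSelectionResult",
          function(object) which(object@mask == 1L))

#' @rdname accessors
#' @export
setMethod("validation", "FeatureSelectionResult",
          function(object) object@validation)

#' @rdname accessors
#' @export
setMethod("nSelected", "FeatureSelectionResult",
          function(object) object@nSelected)

setMethod("show", "FSDataset", function(object) {
  cat("FSDataset '", object@name, "': ", nrow(object@features),
      " instances x ", ncol(object@features), " features, ",
      nlevels(object@labels), " classes\n", sep = "")
  tab <- table(object@labels)
  cat("  class sizes:", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n")
  if (length(object@informative)) {
    cat("  ground-truth informative features:", length(object@informative),
        "\n")
  }
})

#' @export
#' @rdname FSDataset-class
#' @param x an FSDataset.
setMethod("dim", "FSDataset", function(x) dim(x@features))

setMethod("show", "DMOControl", function(object) {
  cat("DMOControl: ", object@nAgents, " agents (",
      object@nBabysitters, " babysitters), ", object@maxIter,
      " iterations, peep ", object@peep, ", L ",
      ifelse(is.na(object@exchangeL), "AUTO", object@exchangeL),
      ", alpha mode '", object@alphaMode, "'\n", sep = "")
})

setMethod("show", "FSControl", function(object) {
  callNextMethod()
  cat("  wrapper: kNN k=", object@kNeighbors, ", ", object@nFolds,
      "-fold CV, hold-out ", object@testFraction * 100, "%, threshold ",
      object@threshold, ", repair '", object@repairPolicy, "'",
      if (object@standardize) ", standardized" else "", "\n", sep = "")
})

setMethod("show", "DMORun", function(object) {
  cat("DMORun: best fitness ", signif(object@bestFitness, 6), " after ",
      length(object@history), " iterations (",
      object@nEvaluations, " evaluations, ",
      signif(object@elapsed, 3), " s)\n", sep = "")
})

setMethod("show", "FeatureSelectionResult", function(object) {
  cat("FeatureSelectionResult: ", object@nSelected, "/",
      length(object@mask), " features selected\n", sep = "")
  cat("  CV error ", signif(object@cvError, 4),
      " | hold-out accuracy ", signif(object@validation[["accuracy"]], 4),
      ", precision ", signif(object@validation[["precision"]], 4),
      ", F-measure ", signif(object@validation[["fMeasure"]], 4), "\n",
      sep = "")
  cat("  seed ", object@seed, ", ", object@nEvaluations, " evaluations, ",
      signif(object@elapsed, 3), " s\n", sep = "")
})

setMethod("show", "BenchmarkSummary", function(object) {
  cat("BenchmarkSummary ('", object@datasetName, "', ",
      length(object@runs), " runs)\n", sep = "")
  cat("  fitness ", signif(object@meanFitness, 4), " +/- ",
      signif(object@sdFitness, 4), " | accuracy ",
      signif(object@meanAccuracy, 4), " | precision ",
      signif(object@meanPrecision, 4), " | F ",
      signif(object@meanFMeasure, 4), "\n", sep = "")
  cat("  mean selected features ", signif(object@meanNSelected, 5),
      ", mean time ", signif(object@meanElapsed, 3), " s\n", sep = "")
})
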