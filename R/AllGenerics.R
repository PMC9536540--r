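#' Accessors for mongooseFS result objects
#'
#' `bestMask` returns the best 0/1 feature mask; `bestFitness` the best
#' (minimal) cross-validated error or objective value; `convergence` the
#' per-iteration best-ever fitness trace; `selectedFeatures` the 1-based
#' indices of the selected features; `validation` the named hold-out metrics
#' (accuracy, precision, F-measure); `nSelected` the selected-feature count.
#'
#' @param object a [FeatureSelectionResult-class], [DMORun-class] or
#'   [BenchmarkSummary-class].
#' @return See the individual descriptions above; `convergence` on a
#'   [BenchmarkSummary-class] returns a matrix with one row per run.
#' @name accessors
#' @examples
#' d <- toyFixture()
#' fit <- selectFeatures(d, fsControl(maxIter = 3, nAgents = 4,
#'   nBabysitters = 1, nFolds = 2, kNeighbors = 1, seed = 1))
#' selectedFeatures(fit)
#' bestFitness(fit)
NULL

#' @rdname accessors
#' @export
setGeneric("bestMask", function(object) standardGeneric("bestMask"))

#' @rdname accessors
#' @export
setGeneric("bestFitness", function(object) standardGeneric("bestFitness"))

#' @rdname accessors
#' @export
setGeneric("convergence", function(object) standardGeneric("convergence"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("validation", function(object) standardGeneric("validation"))

#' @rdname accessors
#' @export
setGeneric("nSelected", function(object) standardGeneric("nSelected"))

#' Coerce to an FSDataset
#'
#' Converts a supported container to [FSDataset-class]. For a `data.frame`,
#' one column holds the class label (`labelCol`, by default the last column).
#' For a `SummarizedExperiment` (features x samples, the Bioconductor
#' orientation), the assay is transposed and the label is taken from a
#' `colData` column.
#'
#' @param x object to coerce.
#' @param labelCol label column name, or `"last"` for the last column
#'   (data.frame) / the column named `"label"` (SummarizedExperiment).
#' @param ... passed to methods.
#' @return An [FSDataset-class].
#' @export
setGeneric("asFSDataset", function(x, labelCol = "last", ...) {
  standardGeneric("asFSDataset")
})
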