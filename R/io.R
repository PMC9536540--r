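## Dataset readers and result writers. CSV is the portable default (header
## row, comma separator, UTF-8); ARFF is read through foreign::read.arff.

#' Read a classification dataset
#'
#' CSV files need a header row; all feature columns must be numeric and
#' complete (missing values are rejected with their location). The label
#' column is named explicitly or taken as the last column.
#'
#' @param path file path.
#' @param format `"csv"` or `"arff"` (default guessed from the extension).
#' @param labelCol label column name, or `"last"`.
#' @param name dataset name (defaults to the file base name).
#' @return An [FSDataset-class].
#' @export
readDataset <- function(path, format = c("auto", "csv", "arff"),
                        labelCol = "last", name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", arff = "arff",
      stop("cannot guess the format of '", path,
           "'; pass format = \"csv\" or \"arff\"")
    )
  }
  df <- switch(format,
    csv = utils::read.csv(path, header = TRUE, check.names = FALSE,
                          fileEncoding = "UTF-8"),
    arff = foreign::read.arff(path)
  )
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  asFSDataset(df, labelCol = labelCol, name = name)
}

#' @rdname asFSDataset
#' @param name dataset name.
#' @export
setMethod("asFSDataset", "data.frame",
  function(x, labelCol = "last", name = "dataset", ...) {
    if (ncol(x) < 2L) stop("a dataset needs at least one feature and a label")
    if (identical(labelCol, "last")) labelCol <- colnames(x)[ncol(x)]
    if (!labelCol %in% colnames(x)) {
      stop("label column '", labelCol, "' not found; candidates: ",
           paste(colnames(x), collapse = ", "))
    }
    labels <- x[[labelCol]]
    feats <- x[, setdiff(colnames(x), labelCol), drop = FALSE]
    bad <- !vapply(feats, is.numeric, logical(1))
    if (any(bad)) {
      stop("non-numeric feature column(s): ",
           paste(colnames(feats)[bad], collapse = ", "))
    }
    m <- as.matrix(feats)
    if (anyNA(m) || anyNA(labels)) {
      idx <- which(is.na(m), arr.ind = TRUE)
      where <- if (nrow(idx)) {
        paste0("row ", idx[1, 1], ", column '", colnames(m)[idx[1, 2]], "'")
      } else {
        paste0("label row ", which(is.na(labels))[1])
      }
      stop("missing value at ", where)
    }
    FSDataset(m, labels, featureIds = colnames(m), name = name)
  }
)

#' @rdname asFSDataset
#' @export
setMethod("asFSDataset", "matrix",
  function(x, labelCol = "last", labels = NULL, name = "dataset", ...) {
    if (is.null(labels)) stop("supply 'labels' when coercing a matrix")
    FSDataset(x, labels, name = name)
  }
)

#' @rdname asFSDataset
#' @export
setMethod("asFSDataset", "ANY", function(x, labelCol = "last", ...) {
  if (is(x, "SummarizedExperiment") &&
      requireNamespace("SummarizedExperiment", quietly = TRUE)) {
    cd <- SummarizedExperiment::colData(x)
    if (identical(labelCol, "last")) labelCol <- "label"
    if (!labelCol %in% colnames(cd)) {
      stop("label column '", labelCol, "' not found in colData; candidates: ",
           paste(colnames(cd), collapse = ", "))
    }
    m <- t(SummarizedExperiment::assay(x))  # to instances x features
    return(FSDataset(m, cd[[labelCol]],
      featureIds = colnames(m), name = "SummarizedExperiment"
    ))
  }
  stop("cannot coerce an object of class '", class(x)[1], "' to FSDataset")
})

#' Write a dataset as CSV (with optional ground-truth sidecar)
#'
#' Writes the portable CSV layout read back by [readDataset()]: a header row
#' `f0,...,f(D-1),label`, one instance per row, full precision. For synthetic
#' data a JSON sidecar (`<path>.json`) records the ground-truth informative
#' indices (0-based) and the dataset name.
#'
#' @param dataset an [FSDataset-class].
#' @param path output CSV path.
#' @param sidecar write the ground-truth JSON sidecar when the dataset
#'   carries informative indices.
#' @return `path`, invisibly.
#' @export
writeDataset <- function(dataset, path, sidecar = TRUE) {
  stopifnot(is(dataset, "FSDataset"))
  df <- as.data.frame(dataset@features)
  colnames(df) <- dataset@featureIds
  df$label <- as.character(dataset@labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar && length(dataset@informative)) {
    jsonlite::write_json(
      list(name = dataset@name,
           informative = dataset@informative - 1L,
           nInstances = nrow(dataset@features),
           nFeatures = ncol(dataset@features),
           nClasses = nlevels(dataset@labels)),
      paste0(path, ".json"), auto_unbox = TRUE
    )
  }
  invisible(path)
}

#' Write feature-selection results to a directory
#'
#' Emits, for a [FeatureSelectionResult-class] or a
#' [BenchmarkSummary-class]: `summary.json` (configuration echo with
#' resolved AUTO values and seeds, metrics, a format-version tag and a
#' timestamp), `convergence.csv` (`run,iteration,best_fitness`),
#' `selected_features.csv` (`run,feature_index` 0-based) and `report.txt`,
#' a human-readable account (1-based feature positions).
#'
#' @param result a [FeatureSelectionResult-class] or [BenchmarkSummary-class].
#' @param outDir output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
writeResults <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  runs <- if (is(result, "BenchmarkSummary")) result@runs else list(result)
  controlList <- function(ctrl) list(
    nAgents = ctrl@nAgents, nBabysitters = ctrl@nBabysitters,
    maxIter = ctrl@maxIter, peep = ctrl@peep, exchangeL = ctrl@exchangeL,
    lowerBound = ctrl@lowerBound, upperBound = ctrl@upperBound,
    alphaMode = ctrl@alphaMode, kNeighbors = ctrl@kNeighbors,
    nFolds = ctrl@nFolds, testFraction = ctrl@testFraction,
    threshold = ctrl@threshold, repairPolicy = ctrl@repairPolicy,
    standardize = ctrl@standardize
  )
  runList <- lapply(runs, function(r) list(
    seed = r@seed, cvError = r@cvError, nSelected = r@nSelected,
    validation = as.list(r@validation), elapsed = r@elapsed,
    nEvaluations = r@nEvaluations,
    selected = which(r@mask == 1L) - 1L
  ))
  payload <- list(
    formatVersion = "1.0",
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    control = controlList(runs[[1]]@control),
    runs = runList
  )
  if (is(result, "BenchmarkSummary")) {
    payload$aggregate <- list(
      meanFitness = result@meanFitness, sdFitness = result@sdFitness,
      meanAccuracy = result@meanAccuracy,
      meanPrecision = result@meanPrecision,
      meanFMeasure = result@meanFMeasure,
      meanNSelected = result@meanNSelected,
      meanElapsed = result@meanElapsed,
      seeds = result@seeds, dataset = result@datasetName
    )
  }
  jsonPath <- file.path(outDir, "summary.json")
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA)

  conv <- do.call(rbind, lapply(seq_along(runs), function(r) {
    data.frame(run = r, iteration = seq_along(runs[[r]]@history),
               best_fitness = runs[[r]]@history)
  }))
  convPath <- file.path(outDir, "convergence.csv")
  utils::write.csv(conv, convPath, row.names = FALSE, quote = FALSE)

  sel <- do.call(rbind, lapply(seq_along(runs), function(r) {
    idx <- which(runs[[r]]@mask == 1L) - 1L
    data.frame(run = r, feature_index = idx)
  }))
  selPath <- file.path(outDir, "selected_features.csv")
  utils::write.csv(sel, selPath, row.names = FALSE, quote = FALSE)

  reportPath <- file.path(outDir, "report.txt")
  lines <- c(
    "Binary dwarf mongoose feature selection",
    paste0("runs: ", length(runs)),
    vapply(seq_along(runs), function(r) {
      x <- runs[[r]]
      paste0("run ", r, " (seed ", x@seed, "): CV error ",
             signif(x@cvError, 4), ", ", x@nSelected,
             " features selected (1-based positions: ",
             paste(which(x@mask == 1L), collapse = " "),
             "), hold-out accuracy ", signif(x@validation[["accuracy"]], 4))
    }, character(1))
  )
  if (is(result, "BenchmarkSummary")) {
    lines <- c(lines, paste0(
      "mean fitness ", signif(result@meanFitness, 4),
      " (SD ", signif(result@sdFitness, 4), "), mean accuracy ",
      signif(result@meanAccuracy, 4), ", mean selected ",
      signif(result@meanNSelected, 4)
    ))
  }
  writeLines(lines, reportPath)
  invisible(c(jsonPath, convPath, selPath, reportPath))
}
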