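#' Write / read a 25-feature table as CSV
#'
#' Fixed header: `subject_id`, `group`, then the 25 feature columns in
#' [qeegFeatureNames()] order.
#'
#' @param featureTable data.frame as produced by [cohortFeatureTable()]
#' @param path CSV file
#' @return `path` invisibly (write); the checked data.frame (read)
#' @export
writeFeatureTable <- function(featureTable, path) {
  cols <- c("subject_id", "group", qeegFeatureNames())
  missing <- setdiff(cols, names(featureTable))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(featureTable[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  ft <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(c("subject_id", "group", qeegFeatureNames()), names(ft))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  ft
}

#' Export a connectivity matrix as labelled CSV
#'
#' The band is recorded in a JSON sidecar (`<path>.json`).
#'
#' @param cm a [ConnectivityMatrix-class]
#' @param path CSV file
#' @return `path`, invisibly
#' @export
writeConnectivity <- function(cm, path) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  utils::write.csv(as.data.frame(cm@values), path, row.names = TRUE)
  jsonlite::write_json(
    list(band = cm@band@name, lo_hz = cm@band@lo, hi_hz = cm@band@hi,
         n_epochs_averaged = cm@nEpochsAveraged),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Export a spanning tree as an edge-list CSV
#'
#' @param tree a [TreeTopology-class]
#' @param path CSV file
#' @return `path`, invisibly
#' @export
writeTree <- function(tree, path) {
  stopifnot(is(tree, "TreeTopology"))
  e <- as.data.frame(tree@edges)
  e$node_i <- tree@nodes[e$i]
  e$node_j <- tree@nodes[e$j]
  utils::write.csv(e, path, row.names = FALSE)
  invisible(path)
}

#' Export a classifier report as JSON
#'
#' Metrics, run parameters and VIMP scores; OOB predictions go to a
#' companion CSV when `predictionsCsv` is given.
#'
#' @param report a [ClassifierReport-class]
#' @param path JSON file
#' @param predictionsCsv optional CSV path for per-subject OOB predictions
#' @return `path`, invisibly
#' @export
writeClassifierReport <- function(report, path, predictionsCsv = NULL) {
  stopifnot(is(report, "ClassifierReport"))
  jsonlite::write_json(
    list(accuracy = report@accuracy, sensitivity = report@sensitivity,
         specificity = report@specificity, labels = report@labels,
         positive_class = report@positiveClass, n_tree = report@nTree,
         m_try = report@mTry, seed = report@seed,
         excluded = report@excluded, vimp = as.list(report@vimp)),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(predictionsCsv))
    utils::write.csv(
      data.frame(subject_id = names(report@oobPredictions),
                 oob_prediction = unname(report@oobPredictions)),
      predictionsCsv, row.names = FALSE)
  invisible(path)
}
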