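#' Full qEEG analysis of one subject
#'
#' Runs the whole pipeline on a raw recording: Hjorth source derivation,
#' epoch extraction, spectral summary (relative band power, peak frequency
#' and its variability over 2-s pieces, theta/alpha ratio), alpha-band PLI
#' matrix, spanning-tree topology, and the ordered 25-feature vector.
#'
#' @param recording an [EEGRecording-class]
#' @param m a [Montage-class]; `NULL` skips re-referencing (e.g. for
#'   recordings that are not on the 10-20 montage)
#' @param epochLengthS,nEpochs,offsetsS epoch selection, see
#'   [extractEpochs()]
#' @param bands band definitions for spectral analysis
#' @param pliBand band for connectivity (default [alphaBand()])
#' @param ... passed to [spectralSummary()]
#' @return list: `spectral` ([SpectralSummary-class]), `connectivity`
#'   ([ConnectivityMatrix-class]), `tree` ([TreeTopology-class]),
#'   `features` (named numeric of length 25)
#' @export
analyzeSubject <- function(recording, m = montage1020(), epochLengthS = 8,
                           nEpochs = 4L, offsetsS = NULL,
                           bands = eegBands(), pliBand = alphaBand(), ...) {
  if (!is.null(m)) recording <- applySourceDerivation(recording, m)
  eps <- extractEpochs(recording, epochLengthS, nEpochs, offsetsS)
  spectral <- spectralSummary(eps, bands = bands, ...)
  conn <- pliMatrix(eps, band = pliBand)
  tree <- spanningTree(conn)
  list(spectral = spectral, connectivity = conn, tree = tree,
       features = buildFeatureVector(spectral, conn, tree))
}

#' Feature table for one or more generated cohorts
#'
#' @param cohorts list of [CohortSpec-class] objects (or a single one)
#' @param m montage passed to [analyzeSubject()]; `NULL` to skip
#'   source derivation
#' @param ... passed to [analyzeSubject()]
#' @return data.frame: `subject_id`, `group`, then the 25 features
#' @export
cohortFeatureTable <- function(cohorts, m = montage1020(), ...) {
  if (is(cohorts, "CohortSpec")) cohorts <- list(cohorts)
  rows <- list()
  for (co in cohorts) {
    subjects <- generateCohort(co)
    for (s in subjects) {
      res <- analyzeSubject(s$recording, m = m, ...)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(subject_id = s$subjectId, group = co@groupLabel),
              as.data.frame(as.list(res$features)))
    }
  }
  do.call(rbind, rows)
}
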