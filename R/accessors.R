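#' Construct an EEG recording
#'
#' @param samples channels x time matrix (µV)
#' @param fs sampling rate in Hz
#' @param channelLabels channel names, one per row
#' @param subjectId subject identifier
#' @return an [EEGRecording-class]
#' @export
eegRecording <- function(samples, fs, channelLabels = rownames(samples),
                         subjectId = "subject") {
  if (is.null(channelLabels))
    channelLabels <- sprintf("CH%02d", seq_len(nrow(samples)))
  samples <- as.matrix(samples)
  rownames(samples) <- channelLabels
  new("EEGRecording", samples = samples, fs = fs,
      channelLabels = channelLabels, subjectId = subjectId)
}

#' @rdname accessors
setMethod("samples", "EEGRecording", function(x) x@samples)
#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "ConnectivityMatrix", function(x) x@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "PowerSpectrum", function(x) x@channelLabels)
#' @rdname accessors
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "EpochSet", function(x) x@subjectId)
#' @rdname accessors
setMethod("epochs", "EpochSet", function(x) x@epochs)
#' @rdname accessors
setMethod("nEpochs", "EpochSet", function(x) length(x@epochs))
#' @rdname accessors
setMethod("connectivityValues", "ConnectivityMatrix", function(x) x@values)
#' @rdname accessors
setMethod("treeEdges", "TreeTopology", function(x) x@edges)
#' @rdname accessors
setMethod("relativePower", "SpectralSummary", function(x) x@relPower)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, nrow(object@samples), ncol(object@samples),
              object@fs, ncol(object@samples) / object@fs))
  cat("  channels:", paste(object@channelLabels, collapse = " "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet '%s': %d epochs of %g s, %d channels @ %g Hz\n",
              object@subjectId, length(object@epochs), object@epochLengthS,
              length(object@channelLabels), object@fs))
})

setMethod("show", "FrequencyBand", function(object) {
  cat(sprintf("FrequencyBand %s: (%g, %g] Hz\n",
              object@name, object@lo, object@hi))
})

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage: %d channels, Hjorth neighbor sets of size %d-%d\n",
              length(object@labels),
              min(lengths(object@neighbors)), max(lengths(object@neighbors))))
})

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum: %d channels, %g-%g Hz at %g Hz resolution\n",
              ncol(object@density), min(object@freqs), max(object@freqs),
              object@resolution))
})

setMethod("show", "SpectralSummary", function(object) {
  cat(sprintf("SpectralSummary: %d channels\n", length(object@channelLabels)))
  cat("  mean relative power:",
      paste(sprintf("%s=%.3f", rownames(object@relPower),
                    rowMeans(object@relPower)), collapse = " "), "\n")
  cat(sprintf("  global peak %.2f Hz (variability %.3f Hz), theta/alpha %.3f\n",
              object@globalPeakFreq, object@peakFreqVariability,
              object@thetaAlphaRatio))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  ut <- object@values[upper.tri(object@values)]
  cat(sprintf("ConnectivityMatrix (PLI, %s %g-%g Hz): %d channels, %d epochs\n",
              object@band@name, object@band@lo, object@band@hi,
              nrow(object@values), object@nEpochsAveraged))
  cat(sprintf("  PLI lowest %.3f mean %.3f highest %.3f\n",
              min(ut), mean(ut), max(ut)))
})

setMethod("show", "TreeTopology", function(object) {
  cat(sprintf("TreeTopology: %d nodes, %d edges%s\n", length(object@nodes),
              nrow(object@edges),
              if (object@degenerate) " [degenerate input]" else ""))
  cat(" ", paste(sprintf("%s=%.3f", names(object@metrics), object@metrics),
                 collapse = " "), "\n")
})

setMethod("show", "SubjectSpec", function(object) {
  cat(sprintf(paste0("SubjectSpec: dominant %.2f Hz, %d channels @ %g Hz, ",
                     "%d x %g s epochs, noise SD %.3g, seed %d\n"),
              object@dominantFreq, object@nChannels, object@fs,
              object@nEpochs, object@epochLengthS, object@noiseSd,
              object@seed))
  cat("  band fractions:",
      paste(sprintf("%s=%.2f", names(object@bandFractions),
                    object@bandFractions), collapse = " "), "\n")
  if (nrow(object@coupling))
    cat(sprintf("  %d coupled pairs, strength %.2f-%.2f\n",
                nrow(object@coupling), min(object@coupling$strength),
                max(object@coupling$strength)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec '%s': %d subjects, seed %d\n",
              object@groupLabel, object@nSubjects, object@seed))
})

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf(paste0("ClassifierReport (%s vs %s, positive = %s): ",
                     "accuracy %.3f, sensitivity %.3f, specificity %.3f\n"),
              object@labels[1], object@labels[2], object@positiveClass,
              object@accuracy, object@sensitivity, object@specificity))
  top <- head(sort(object@vimp, decreasing = TRUE), 3)
  cat("  top VIMP:", paste(sprintf("%s=%.4f", names(top), top),
                           collapse = ", "), "\n")
  if (length(object@excluded))
    cat("  never out-of-bag (excluded):",
        paste(object@excluded, collapse = ", "), "\n")
})
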