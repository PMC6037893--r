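#' @import methods
NULL

#' Frequency band
#'
#' A named frequency interval. Band membership of a spectral bin at
#' frequency f is decided by `lo < f <= hi`, so that adjacent bands sharing
#' an edge partition the axis without double counting and an oscillation at
#' a shared edge (e.g. 10 Hz between alpha-1 and alpha-2) belongs to the
#' lower band, whose printed range ends at that edge.
#'
#' @slot name band name
#' @slot lo lower edge in Hz (exclusive)
#' @slot hi upper edge in Hz (inclusive)
#' @export
setClass("FrequencyBand",
  representation(name = "character", lo = "numeric", hi = "numeric"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      return("band name must be a single non-empty string")
    if (!(object@lo < object@hi))
      return("band invariant violated: lo < hi required")
    TRUE
  })

#' Multichannel EEG recording
#'
#' Continuous multichannel signal in microvolts, channels in rows.
#'
#' @slot samples channels x time numeric matrix (µV)
#' @slot fs sampling frequency in Hz
#' @slot channelLabels ordered, unique channel names
#' @slot subjectId subject identifier
#' @export
setClass("EEGRecording",
  representation(samples = "matrix", fs = "numeric",
                 channelLabels = "character", subjectId = "character"),
  validity = function(object) {
    if (length(object@fs) != 1L || object@fs <= 0)
      return("invariant violated: fs > 0")
    if (nrow(object@samples) != length(object@channelLabels))
      return("invariant violated: one label per channel row")
    if (anyDuplicated(object@channelLabels))
      return("invariant violated: channel labels must be unique")
    TRUE
  })

#' Set of fixed-length epochs
#'
#' Artifact-free segments of one subject's recording; the unit of all
#' quantitative analysis. All epochs share shape, sampling rate and labels.
#'
#' @slot epochs list of channels x time matrices
#' @slot fs sampling frequency in Hz
#' @slot channelLabels ordered channel names
#' @slot epochLengthS epoch length in seconds
#' @slot subjectId subject identifier
#' @export
setClass("EpochSet",
  representation(epochs = "list", fs = "numeric", channelLabels = "character",
                 epochLengthS = "numeric", subjectId = "character"),
  validity = function(object) {
    if (length(object@epochs) < 1L) return("at least one epoch required")
    dims <- vapply(object@epochs, dim, integer(2))
    if (any(dims[1, ] != length(object@channelLabels)))
      return("invariant violated: every epoch needs one row per channel label")
    if (length(unique(dims[2, ])) != 1L)
      return("invariant violated: all epochs must have identical shape")
    if (object@fs <= 0) return("invariant violated: fs > 0")
    TRUE
  })

#' Electrode montage with neighbor relation
#'
#' Channel list plus the neighbor sets used for Hjorth source derivation.
#'
#' @slot labels ordered channel names
#' @slot neighbors named list mapping each label to its neighbor labels
#' @export
setClass("Montage",
  representation(labels = "character", neighbors = "list"),
  validity = function(object) {
    if (!setequal(names(object@neighbors), object@labels))
      return("neighbors must be keyed by exactly the montage labels")
    for (lab in object@labels) {
      nb <- object@neighbors[[lab]]
      if (length(nb) < 2L)
        return(sprintf("invariant violated: channel %s has < 2 neighbors", lab))
      if (!all(nb %in% object@labels))
        return(sprintf("neighbor of %s outside montage", lab))
      for (x in nb) if (!(lab %in% object@neighbors[[x]]))
        return(sprintf("invariant violated: neighbor relation not symmetric (%s -> %s)",
                       lab, x))
    }
    TRUE
  })

#' Power spectral density per channel
#'
#' @slot freqs strictly increasing Hz grid
#' @slot density frequency x channel matrix of power density (µV²/Hz)
#' @slot resolution frequency grid step in Hz
#' @slot channelLabels channel names (columns of density)
#' @export
setClass("PowerSpectrum",
  representation(freqs = "numeric", density = "matrix", resolution = "numeric",
                 channelLabels = "character"),
  validity = function(object) {
    if (any(diff(object@freqs) <= 0))
      return("invariant violated: freqs strictly increasing")
    if (min(object@density) < 0)
      return("invariant violated: density >= 0 everywhere")
    if (nrow(object@density) != length(object@freqs))
      return("density rows must match frequency grid")
    if (ncol(object@density) != length(object@channelLabels))
      return("density columns must match channel labels")
    TRUE
  })

#' Spectral feature summary for one subject
#'
#' @slot relPower band x channel matrix of relative power fractions
#' @slot peakFreq per-channel peak frequency (Hz)
#' @slot globalPeakFreq peak of the channel-averaged spectrum (Hz)
#' @slot peakFreqVariability SD of the global peak frequency over sub-epochs (Hz)
#' @slot thetaAlphaRatio theta / (theta + alpha1 + alpha2), from channel means
#' @slot channelLabels channel names
#' @export
setClass("SpectralSummary",
  representation(relPower = "matrix", peakFreq = "numeric",
                 globalPeakFreq = "numeric", peakFreqVariability = "numeric",
                 thetaAlphaRatio = "numeric", channelLabels = "character"),
  validity = function(object) {
    if (min(object@relPower) < -1e-12 || max(object@relPower) > 1 + 1e-9)
      return("invariant violated: relative power fractions must lie in [0,1]")
    if (length(object@thetaAlphaRatio) == 1L &&
        (object@thetaAlphaRatio < 0 || object@thetaAlphaRatio > 1))
      return("invariant violated: theta/alpha ratio must lie in [0,1]")
    TRUE
  })

#' Symmetric Phase Lag Index matrix
#'
#' @slot values channels x channels symmetric matrix, zero diagonal, entries in [0,1]
#' @slot band the frequency band the PLI was computed in
#' @slot nEpochsAveraged number of epochs averaged
#' @slot channelLabels channel names
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", band = "FrequencyBand",
                 nEpochsAveraged = "integer", channelLabels = "character"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("matrix must be square")
    if (max(abs(v - t(v))) > 1e-12)
      return("invariant violated: matrix symmetric (<= 1e-12 asymmetry)")
    if (any(diag(v) != 0)) return("invariant violated: diagonal = 0")
    if (min(v) < 0 || max(v) > 1)
      return("invariant violated: all entries in [0,1]")
    if (length(object@channelLabels) != nrow(v))
      return("one label per matrix row required")
    TRUE
  })

#' Spanning-tree backbone and topology metrics
#'
#' @slot nodes channel labels
#' @slot edges (N-1) x 3 matrix: node index i, node index j, edge weight
#' @slot metrics named numeric: degree_max_norm, leaf_fraction, diameter_norm,
#'   tree_hierarchy
#' @slot degenerate TRUE when the input matrix carried no information
#'   (all weights equal) and the tree is purely the tie-break order
#' @export
setClass("TreeTopology",
  representation(nodes = "character", edges = "matrix", metrics = "numeric",
                 degenerate = "logical"),
  validity = function(object) {
    n <- length(object@nodes)
    if (nrow(object@edges) != n - 1L)
      return("invariant violated: a tree on N nodes has exactly N-1 edges")
    TRUE
  })

#' Specification of one synthetic EEG subject
#'
#' Ground-truth generative parameters: a narrowband dominant rhythm, a
#' per-band variance budget, optional phase-lagged coupling between channel
#' pairs, and white observation noise.
#'
#' @slot dominantFreq peak frequency of the rhythmic component (Hz)
#' @slot bandFractions named fractions of signal variance per band; sum to 1
#' @slot coupling data.frame with columns i, j, lag, strength
#' @slot noiseSd white observation noise SD (signal units)
#' @slot nChannels number of channels
#' @slot fs sampling frequency (Hz)
#' @slot epochLengthS epoch length (s)
#' @slot nEpochs number of epochs
#' @slot seed RNG seed (Mersenne-Twister)
#' @slot rhythmShare fraction of the dominant band's variance carried by the
#'   pure sinusoid (rest is band-limited noise)
#' @slot bands named list of FrequencyBand defining the variance budget
#' @slot channelLabels channel names, length nChannels
#' @export
setClass("SubjectSpec",
  representation(dominantFreq = "numeric", bandFractions = "numeric",
                 coupling = "data.frame", noiseSd = "numeric",
                 nChannels = "integer", fs = "numeric",
                 epochLengthS = "numeric", nEpochs = "integer",
                 seed = "integer", rhythmShare = "numeric",
                 bands = "list", channelLabels = "character"))

#' Specification of a synthetic cohort
#'
#' @slot groupLabel cohort group name
#' @slot nSubjects number of subjects
#' @slot template SubjectSpec shared by all subjects before jitter
#' @slot jitter named non-negative spreads: dominant_freq (Hz SD),
#'   band_fractions (per-band SD before renormalization),
#'   coupling_strength (SD), noise_sd (SD)
#' @slot seed cohort seed; per-subject seeds derived by a counter scheme
#' @export
setClass("CohortSpec",
  representation(groupLabel = "character", nSubjects = "integer",
                 template = "SubjectSpec", jitter = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nSubjects < 1L) return("invariant violated: n_subjects >= 1")
    if (length(object@jitter) && any(object@jitter < 0))
      return("invariant violated: jitter values >= 0")
    TRUE
  })

#' Out-of-bag random-forest classification report
#'
#' @slot accuracy,sensitivity,specificity OOB performance fractions
#' @slot vimp named permutation importance (mean decrease in OOB accuracy)
#' @slot oobPredictions per-subject OOB predicted label (NA if never OOB)
#' @slot labels the two class labels
#' @slot positiveClass label treated as positive for sensitivity
#' @slot nTree,mTry,seed run parameters
#' @slot excluded subject names never out of bag, excluded from metrics
#' @export
setClass("ClassifierReport",
  representation(accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", vimp = "numeric",
                 oobPredictions = "character", labels = "character",
                 positiveClass = "character", nTree = "integer",
                 mTry = "integer", seed = "integer", excluded = "character"),
  validity = function(object) {
    for (s in c("accuracy", "sensitivity", "specificity")) {
      v <- slot(object, s)
      if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
        return(sprintf("invariant violated: %s in [0,1]", s))
    }
    TRUE
  })
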