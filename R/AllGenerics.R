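#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("connectivityValues", function(x) standardGeneric("connectivityValues"))

#' @rdname accessors
#' @export
setGeneric("treeMetrics", function(x) standardGeneric("treeMetrics"))

#' @rdname accessors
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))

#' @rdname accessors
#' @export
setGeneric("relativePower", function(x) standardGeneric("relativePower"))

#' Zero-phase band-pass filtering
#'
#' @param x an [EEGRecording-class], [EpochSet-class], matrix (channels in
#'   rows) or numeric vector
#' @param band a [FrequencyBand-class]
#' @param fs sampling rate in Hz (taken from the object when it carries one)
#' @param order Butterworth order of the one-way filter; applied
#'   forward-backward, so effective attenuation is doubled
#' @return an object of the same type as `x`, filtered
#' @export
setGeneric("bandpassFilter",
  function(x, band, fs, order = 4L) standardGeneric("bandpassFilter"))

#' Accessor generics
#'
#' Read-only access to the slots of the package's S4 containers.
#'
#' @param x an object of one of the package's S4 classes
#' @name accessors
NULL
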