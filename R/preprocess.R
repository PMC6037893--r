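#' Hjorth source-derivation referencing
#'
#' Re-references each channel to the unweighted mean of its montage
#' neighbors: `out[c] = in[c] - mean(in[neighbors(c)])`, all neighbor means
#' computed from the original (pre-derivation) signals. This local Laplacian
#' sharpens spatial resolution and removes any spatially uniform component
#' exactly. The output is restricted to the montage channels, in montage
#' order.
#'
#' @param recording an [EEGRecording-class] whose labels cover the montage
#' @param m a [Montage-class]
#' @return a re-referenced [EEGRecording-class]
#' @export
applySourceDerivation <- function(recording, m = montage1020()) {
  stopifnot(is(recording, "EEGRecording"), is(m, "Montage"))
  missing <- setdiff(m@labels, recording@channelLabels)
  if (length(missing))
    stop("recording is missing montage channel(s): ",
         paste(missing, collapse = ", "))
  x <- recording@samples
  rownames(x) <- recording@channelLabels
  out <- matrix(0, length(m@labels), ncol(x),
                dimnames = list(m@labels, NULL))
  for (lab in m@labels) {
    nb <- m@neighbors[[lab]]
    out[lab, ] <- x[lab, ] - colMeans(x[nb, , drop = FALSE])
  }
  eegRecording(out, recording@fs, m@labels, recording@subjectId)
}

.designBandpass <- function(band, fs, order) {
  if (band@hi >= fs / 2)
    stop(sprintf("band %s upper edge %g Hz is at or above Nyquist (%g Hz)",
                 band@name, band@hi, fs / 2))
  if (band@lo <= 0) stop("band lower edge must be positive")
  signal::butter(order, c(band@lo, band@hi) / (fs / 2), type = "pass")
}

.filtMatrix <- function(x, band, fs, order) {
  bf <- .designBandpass(band, fs, order)
  t(apply(x, 1L, function(row) signal::filtfilt(bf, row)))
}

#' @rdname bandpassFilter
setMethod("bandpassFilter", signature(x = "numeric"),
  function(x, band, fs, order = 4L) {
    bf <- .designBandpass(band, fs, order)
    as.numeric(signal::filtfilt(bf, x))
  })

#' @rdname bandpassFilter
setMethod("bandpassFilter", signature(x = "matrix"),
  function(x, band, fs, order = 4L) .filtMatrix(x, band, fs, order))

#' @rdname bandpassFilter
setMethod("bandpassFilter", signature(x = "EEGRecording"),
  function(x, band, fs, order = 4L) {
    out <- .filtMatrix(x@samples, band, x@fs, order)
    eegRecording(out, x@fs, x@channelLabels, x@subjectId)
  })

#' @rdname bandpassFilter
setMethod("bandpassFilter", signature(x = "EpochSet"),
  function(x, band, fs, order = 4L) {
    new("EpochSet",
        epochs = lapply(x@epochs, .filtMatrix, band = band, fs = x@fs,
                        order = order),
        fs = x@fs, channelLabels = x@channelLabels,
        epochLengthS = x@epochLengthS, subjectId = x@subjectId)
  })

#' Extract fixed-length epochs from a recording
#'
#' Visual artifact-free epoch selection is replaced by explicit offsets; by
#' default the epochs are spread evenly over the recording (contiguous when
#' the recording is exactly filled). Segments must fit and must not overlap.
#'
#' @param recording an [EEGRecording-class]
#' @param epochLengthS epoch length in seconds (default 8 s, so that four
#'   epochs split into sixteen 2-s pieces)
#' @param nEpochs number of epochs (default 4)
#' @param offsetsS optional start times in seconds, one per epoch
#' @return an [EpochSet-class]
#' @export
extractEpochs <- function(recording, epochLengthS = 8, nEpochs = 4L,
                          offsetsS = NULL) {
  stopifnot(is(recording, "EEGRecording"))
  fs <- recording@fs
  nTot <- ncol(recording@samples)
  len <- round(epochLengthS * fs)
  if (is.null(offsetsS)) {
    if (nEpochs * len > nTot)
      stop(sprintf("%d epochs of %g s do not fit in a %.1f s recording",
                   nEpochs, epochLengthS, nTot / fs))
    stride <- if (nEpochs > 1) (nTot - len) / (nEpochs - 1) else 0
    starts <- round((seq_len(nEpochs) - 1) * stride) + 1L
  } else {
    if (length(offsetsS) != nEpochs)
      stop("offsetsS must supply one start time per epoch")
    starts <- round(offsetsS * fs) + 1L
  }
  ends <- starts + len - 1L
  if (any(starts < 1L) || any(ends > nTot))
    stop("epoch segment out of bounds: recording has ", nTot, " samples")
  o <- order(starts)
  if (any(starts[o][-1] <= ends[o][-nEpochs]))
    stop("epoch segments overlap")
  eps <- lapply(seq_len(nEpochs), function(k)
    recording@samples[, starts[k]:ends[k], drop = FALSE])
  new("EpochSet", epochs = eps, fs = fs,
      channelLabels = recording@channelLabels, epochLengthS = epochLengthS,
      subjectId = recording@subjectId)
}

#' Split epochs into shorter consecutive pieces
#'
#' Each epoch is divided into non-overlapping pieces of exactly
#' `round(pieceLengthS * fs)` samples; a trailing remainder shorter than one
#' piece is discarded. Four 8-s epochs with 2-s pieces give the sixteen
#' sub-epochs used for peak-frequency variability.
#'
#' @param x an [EpochSet-class]
#' @param pieceLengthS piece length in seconds (default 2 s)
#' @return an [EpochSet-class] with `sum(floor(epochLength / pieceLength))`
#'   epochs
#' @export
splitEpochs <- function(x, pieceLengthS = 2) {
  stopifnot(is(x, "EpochSet"))
  len <- round(pieceLengthS * x@fs)
  nAvail <- ncol(x@epochs[[1]])
  if (len > nAvail)
    stop(sprintf("piece of %g s is longer than the %g s epochs",
                 pieceLengthS, x@epochLengthS))
  pieces <- list()
  for (ep in x@epochs) {
    nPieces <- floor(ncol(ep) / len)
    for (k in seq_len(nPieces))
      pieces[[length(pieces) + 1L]] <-
        ep[, ((k - 1L) * len + 1L):(k * len), drop = FALSE]
  }
  new("EpochSet", epochs = pieces, fs = x@fs,
      channelLabels = x@channelLabels, epochLengthS = pieceLengthS,
      subjectId = x@subjectId)
}
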