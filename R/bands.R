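#' Construct a frequency band
#'
#' @param name band name
#' @param lo,hi band edges in Hz; a spectral bin at f belongs to the band
#'   when `lo < f <= hi`
#' @return a [FrequencyBand-class]
#' @export
#' @examples
#' frequencyBand("alpha", 8, 13)
frequencyBand <- function(name, lo, hi) {
  new("FrequencyBand", name = name, lo = lo, hi = hi)
}

#' The six canonical EEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha-1 8-10, alpha-2 10-13, beta 13-30 and
#' gamma 30-48 Hz. Together they partition 0.5-48 Hz without overlap (the
#' default broadband denominator for relative power).
#'
#' @return named list of [FrequencyBand-class] objects
#' @export
eegBands <- function() {
  list(
    delta  = frequencyBand("delta",  0.5, 4),
    theta  = frequencyBand("theta",  4,   8),
    alpha1 = frequencyBand("alpha1", 8,  10),
    alpha2 = frequencyBand("alpha2", 10, 13),
    beta   = frequencyBand("beta",  13,  30),
    gamma  = frequencyBand("gamma", 30,  48)
  )
}

#' The alpha band used for Phase Lag Index connectivity
#'
#' 8-13 Hz, the union of alpha-1 and alpha-2, filtered as one band.
#'
#' @return a [FrequencyBand-class]
#' @export
alphaBand <- function() frequencyBand("alpha", 8, 13)

#' Which bands contain a frequency
#'
#' Membership rule `lo < f <= hi`, matching spectral-bin assignment.
#'
#' @param freq frequency in Hz
#' @param bands named list of [FrequencyBand-class]
#' @return character vector of band names containing `freq`
#' @export
bandsContaining <- function(freq, bands = eegBands()) {
  names(bands)[vapply(bands, function(b) freq > b@lo & freq <= b@hi, logical(1))]
}
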