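.taper <- function(window, n) {
  switch(match.arg(window, c("rect", "hamming", "hann")),
         rect = rep(1, n),
         hamming = 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
         hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

#' Welch-averaged power spectral density
#'
#' Mean periodogram per channel across all epochs: each epoch is cut into
#' `segmentS`-second segments with the given overlap, mean-subtracted,
#' tapered, and the one-sided periodograms are averaged. Normalization is
#' chosen so that the integrated density equals the time-domain variance
#' (Parseval). The default 2-s segments give 0.5 Hz resolution.
#'
#' The default taper is rectangular: the sampling grid is commensurate with
#' the band edges, so on-grid line components then land in a single bin with
#' no leakage across band boundaries. Hamming or Hann tapers are available
#' for signals with strong off-grid lines.
#'
#' @param x an [EpochSet-class]
#' @param segmentS Welch segment length in seconds
#' @param overlap fractional segment overlap in `[0,1)`
#' @param window taper: "rect" (default), "hamming" or "hann"
#' @return a [PowerSpectrum-class]
#' @export
powerSpectrum <- function(x, segmentS = 2, overlap = 0.5, window = "rect") {
  stopifnot(is(x, "EpochSet"))
  fs <- x@fs
  segLen <- round(segmentS * fs)
  if (ncol(x@epochs[[1]]) < segLen)
    stop(sprintf("epochs of %g s are shorter than the %g s analysis segment",
                 x@epochLengthS, segmentS))
  w <- .taper(window, segLen)
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(segLen / 2) + 1L
  freqs <- (seq_len(nf) - 1L) * fs / segLen
  oneSided <- rep(2, nf)
  oneSided[1] <- 1
  if (segLen %% 2L == 0L) oneSided[nf] <- 1
  step <- max(1L, round(segLen * (1 - overlap)))
  nch <- length(x@channelLabels)
  acc <- matrix(0, nf, nch)
  nseg <- 0L
  for (ep in x@epochs) {
    starts <- seq(1L, ncol(ep) - segLen + 1L, by = step)
    for (s in starts) {
      seg <- ep[, s:(s + segLen - 1L), drop = FALSE]
      seg <- seg - rowMeans(seg)
      X <- stats::mvfft(t(seg * rep(w, each = nch)))
      acc <- acc + Mod(X[seq_len(nf), , drop = FALSE])^2
      nseg <- nseg + 1L
    }
  }
  dens <- acc / nseg * scale * oneSided
  new("PowerSpectrum", freqs = freqs, density = dens,
      resolution = fs / segLen, channelLabels = x@channelLabels)
}

.binsIn <- function(freqs, lo, hi) which(freqs > lo & freqs <= hi)

#' Relative band power per channel
#'
#' Fraction of integrated spectral density falling in each band, relative to
#' the broadband denominator. A bin at frequency f belongs to band (lo, hi]
#' when `lo < f <= hi`, so the six canonical bands partition the default
#' 0.5-48 Hz denominator exactly and the fractions sum to one.
#'
#' @param spectrum a [PowerSpectrum-class]
#' @param bands named list of [FrequencyBand-class]
#' @param denominatorRange length-2 broadband range in Hz (default
#'   `c(0.5, 48)`; set `c(0.5, 30)` to drop gamma from the denominator)
#' @return band x channel matrix of fractions in `[0,1]`
#' @export
relativeBandPower <- function(spectrum, bands = eegBands(),
                              denominatorRange = c(0.5, 48)) {
  stopifnot(is(spectrum, "PowerSpectrum"))
  den <- .binsIn(spectrum@freqs, denominatorRange[1], denominatorRange[2])
  tot <- colSums(spectrum@density[den, , drop = FALSE])
  if (any(tot <= 0))
    stop("zero total power in the denominator range for channel(s): ",
         paste(spectrum@channelLabels[tot <= 0], collapse = ", "))
  out <- matrix(0, length(bands), ncol(spectrum@density),
                dimnames = list(names(bands), spectrum@channelLabels))
  for (b in names(bands)) {
    idx <- intersect(.binsIn(spectrum@freqs, bands[[b]]@lo, bands[[b]]@hi),
                     den)
    out[b, ] <- colSums(spectrum@density[idx, , drop = FALSE]) / tot
  }
  out
}

#' Peak (dominant) frequency per channel and globally
#'
#' Argmax of the spectral density inside the search range, per channel; the
#' global value is the argmax of the channel-averaged spectrum. Ties break
#' toward the lower frequency. The default 4-13 Hz range covers the
#' theta-alpha dominant rhythm and keeps delta-dominant spectra from
#' swamping the estimate.
#'
#' @param spectrum a [PowerSpectrum-class]
#' @param searchRange length-2 range in Hz, inclusive
#' @return list with `perChannel` (named numeric, Hz) and `global` (Hz)
#' @export
peakFrequency <- function(spectrum, searchRange = c(4, 13)) {
  stopifnot(is(spectrum, "PowerSpectrum"))
  idx <- which(spectrum@freqs >= searchRange[1] &
               spectrum@freqs <= searchRange[2])
  if (!length(idx))
    stop("empty search range: no spectral bins in [",
         searchRange[1], ", ", searchRange[2], "] Hz")
  f <- spectrum@freqs[idx]
  d <- spectrum@density[idx, , drop = FALSE]
  perChannel <- f[apply(d, 2L, which.max)]
  names(perChannel) <- spectrum@channelLabels
  list(perChannel = perChannel, global = f[which.max(rowMeans(d))])
}

#' Variability of the global peak frequency across sub-epochs
#'
#' The global peak frequency is computed independently for each sub-epoch
#' (by default the sixteen 2-s pieces of the four selected epochs) and its
#' standard deviation is returned. The population formula (divisor n) is the
#' default.
#'
#' @param x an [EpochSet-class] of sub-epochs (at least 2)
#' @param searchRange peak search range in Hz
#' @param divisor "population" (n, default) or "sample" (n-1)
#' @param ... passed to [powerSpectrum()]
#' @return standard deviation in Hz
#' @export
peakFrequencyVariability <- function(x, searchRange = c(4, 13),
                                     divisor = "population", ...) {
  stopifnot(is(x, "EpochSet"))
  if (length(x@epochs) < 2L)
    stop("at least 2 sub-epochs are required to estimate variability")
  peaks <- vapply(x@epochs, function(ep) {
    one <- new("EpochSet", epochs = list(ep), fs = x@fs,
               channelLabels = x@channelLabels,
               epochLengthS = ncol(ep) / x@fs, subjectId = x@subjectId)
    peakFrequency(powerSpectrum(one, ...), searchRange)$global
  }, numeric(1))
  divisor <- match.arg(divisor, c("population", "sample"))
  if (divisor == "population")
    sqrt(mean((peaks - mean(peaks))^2))
  else
    stats::sd(peaks)
}

#' Theta/alpha ratio
#'
#' `theta / (theta + alpha1 + alpha2)`, computed from channel-mean relative
#' powers: an index of EEG slowing in `[0,1]`.
#'
#' @param relPower band x channel matrix from [relativeBandPower()]
#' @return dimensionless ratio
#' @export
thetaAlphaRatio <- function(relPower) {
  need <- c("theta", "alpha1", "alpha2")
  if (!all(need %in% rownames(relPower)))
    stop("relPower must contain theta, alpha1 and alpha2 rows")
  m <- rowMeans(relPower[need, , drop = FALSE])
  den <- sum(m)
  if (den <= 0) stop("zero denominator: theta + alpha1 + alpha2 power is 0")
  unname(m["theta"] / den)
}

#' Full spectral summary for one subject
#'
#' Relative band power, per-channel and global peak frequency, the
#' across-sub-epoch peak-frequency variability and the theta/alpha ratio,
#' from one epoch set.
#'
#' @param x an [EpochSet-class]
#' @param bands named list of [FrequencyBand-class]
#' @param denominatorRange broadband denominator for relative power (Hz)
#' @param searchRange peak-frequency search range (Hz)
#' @param pieceLengthS sub-epoch length for variability (default 2 s)
#' @param ... passed to [powerSpectrum()]
#' @return a [SpectralSummary-class]
#' @export
spectralSummary <- function(x, bands = eegBands(),
                            denominatorRange = c(0.5, 48),
                            searchRange = c(4, 13), pieceLengthS = 2, ...) {
  spec <- powerSpectrum(x, ...)
  rp <- relativeBandPower(spec, bands, denominatorRange)
  pk <- peakFrequency(spec, searchRange)
  pv <- peakFrequencyVariability(splitEpochs(x, pieceLengthS),
                                 searchRange, ...)
  new("SpectralSummary", relPower = rp, peakFreq = pk$perChannel,
      globalPeakFreq = pk$global, peakFreqVariability = pv,
      thetaAlphaRatio = thetaAlphaRatio(rp),
      channelLabels = x@channelLabels)
}
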