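#' Analytic-signal instantaneous phase
#'
#' Phase of the analytic signal (the signal plus i times its Hilbert
#' transform), in (-pi, pi]. The analytic signal is built in the frequency
#' domain (negative frequencies zeroed, positive doubled). The caller is
#' expected to band-limit the signal first. A margin of samples at each end
#' (default 0.25 s) is flagged via the `"edgeMargin"` attribute for
#' exclusion from downstream averaging, to suppress filter and Hilbert
#' transients.
#'
#' @param x single-channel numeric signal
#' @param fs sampling rate in Hz
#' @param edgeMarginS margin flagged at each end, in seconds
#' @return numeric phase series with attribute `edgeMargin` (samples)
#' @export
instantaneousPhase <- function(x, fs, edgeMarginS = 0.25) {
  if (stats::sd(x) == 0)
    stop("constant signal: instantaneous phase is undefined")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  analytic <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  phase <- Arg(analytic)
  attr(phase, "edgeMargin") <- round(edgeMarginS * fs)
  phase
}

#' Phase Lag Index of two phase series
#'
#' `PLI = | mean over time of sign(sin(phase_a - phase_b)) |`, with
#' `sign(0) = 0` so that a strictly zero-lag phase relation scores 0. The
#' PLI ranges between 0 (no consistent phase lead/lag) and 1 (one signal
#' always leads); it is insensitive to zero-lag (volume-conduction)
#' coupling by construction. Edge margins must already be removed.
#'
#' @param phaseA,phaseB equal-length phase series in radians
#' @return PLI in `[0,1]`
#' @export
pliPair <- function(phaseA, phaseB) {
  if (length(phaseA) != length(phaseB))
    stop("phase series length mismatch: ", length(phaseA), " vs ",
         length(phaseB))
  abs(mean(sign(sin(phaseA - phaseB))))
}

.dropMargin <- function(phase) {
  m <- attr(phase, "edgeMargin")
  n <- length(phase)
  if (is.null(m) || m == 0L) return(as.numeric(phase))
  if (2L * m >= n) stop("edge margins leave no samples")
  phase[(m + 1L):(n - m)]
}

#' Alpha-band Phase Lag Index matrix
#'
#' Per epoch: band-pass filter, extract instantaneous phases, drop the edge
#' margins, and compute the PLI for every unordered channel pair; the final
#' matrix is the mean over epochs. The default band is the 8-13 Hz alpha
#' band (alpha-1 and alpha-2 filtered as one band).
#'
#' @param x an [EpochSet-class]
#' @param band a [FrequencyBand-class]; default [alphaBand()]
#' @param edgeMarginS per-end margin excluded from the sign average (s)
#' @param order Butterworth order passed to [bandpassFilter()]
#' @return a [ConnectivityMatrix-class]
#' @export
pliMatrix <- function(x, band = alphaBand(), edgeMarginS = 0.25,
                      order = 4L) {
  stopifnot(is(x, "EpochSet"))
  nch <- length(x@channelLabels)
  filtered <- bandpassFilter(x, band, order = order)
  acc <- matrix(0, nch, nch)
  for (ep in filtered@epochs) {
    ph <- lapply(seq_len(nch), function(c)
      .dropMargin(instantaneousPhase(ep[c, ], x@fs, edgeMarginS)))
    for (i in seq_len(nch - 1L)) {
      for (j in (i + 1L):nch) {
        v <- pliPair(ph[[i]], ph[[j]])
        acc[i, j] <- acc[i, j] + v
        acc[j, i] <- acc[j, i] + v
      }
    }
  }
  vals <- acc / length(filtered@epochs)
  dimnames(vals) <- list(x@channelLabels, x@channelLabels)
  new("ConnectivityMatrix", values = vals, band = band,
      nEpochsAveraged = length(filtered@epochs),
      channelLabels = x@channelLabels)
}

#' Lowest / mean / highest PLI over all channel pairs
#'
#' Reductions over the upper triangle of the connectivity matrix, the three
#' PLI entries of the subject feature vector.
#'
#' @param cm a [ConnectivityMatrix-class]
#' @return named numeric: `pli_lowest`, `pli_mean`, `pli_highest`
#' @export
pliFeatures <- function(cm) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  ut <- cm@values[upper.tri(cm@values)]
  c(pli_lowest = min(ut), pli_mean = mean(ut), pli_highest = max(ut))
}
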