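.completeFractions <- function(bandFractions, bands) {
  fr <- stats::setNames(numeric(length(bands)), names(bands))
  if (is.null(names(bandFractions)) ||
      !all(names(bandFractions) %in% names(bands)))
    stop("band_fractions must be named with declared band names (",
         paste(names(bands), collapse = ", "), ")")
  fr[names(bandFractions)] <- bandFractions
  fr
}

#' Specify a synthetic EEG subject
#'
#' Each channel of a generated subject is the sum of (a) a narrowband
#' sinusoid at the dominant frequency carrying `rhythmShare` of its band's
#' variance, (b) band-limited Gaussian noise per band (white noise passed
#' through the same zero-phase band-pass filters the analysis uses, scaled
#' to the requested variance fraction) and (c) white observation noise.
#' Coupled channel pairs share the dominant-rhythm source: the second
#' channel mixes in the first channel's source with a constant phase lag
#' and the given mixing weight.
#'
#' @param dominantFreq peak frequency in Hz; must lie inside exactly one band
#' @param bandFractions named non-negative fractions of signal variance per
#'   band, summing to 1
#' @param coupling optional data.frame with columns `i`, `j` (distinct
#'   channel indices), `lag` (radians) and `strength` in `[0,1]`
#' @param noiseSd white observation noise SD in signal units (the rhythmic
#'   plus band-noise variance is 1)
#' @param nChannels,fs,epochLengthS,nEpochs geometry of the recording
#' @param seed RNG seed (Mersenne-Twister); generation is fully
#'   deterministic given the spec
#' @param rhythmShare fraction of the dominant band's variance carried by
#'   the pure sinusoid
#' @param bands band definitions for the variance budget
#' @param channelLabels optional channel names (defaults to the 10-20 list
#'   for 21 channels)
#' @return a [SubjectSpec-class]
#' @export
subjectSpec <- function(dominantFreq, bandFractions, coupling = NULL,
                        noiseSd = 0, nChannels = 2L, fs = 500,
                        epochLengthS = 8, nEpochs = 4L, seed = 1L,
                        rhythmShare = 0.5, bands = eegBands(),
                        channelLabels = NULL) {
  fr <- .completeFractions(bandFractions, bands)
  if (any(fr < 0))
    stop("invariant violated: band_fractions values must be >= 0")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("invariant violated: band_fractions must sum to 1 (got ",
         format(sum(fr)), ")")
  home <- bandsContaining(dominantFreq, bands)
  if (length(home) != 1L)
    stop("invariant violated: dominant_freq ", dominantFreq,
         " Hz must lie inside exactly one declared band")
  if (dominantFreq >= fs / 2)
    stop("dominant_freq must be below the Nyquist frequency")
  if (is.null(coupling))
    coupling <- data.frame(i = integer(), j = integer(),
                           lag = numeric(), strength = numeric())
  coupling <- as.data.frame(coupling)
  if (nrow(coupling)) {
    if (any(coupling$i == coupling$j) ||
        any(c(coupling$i, coupling$j) < 1) ||
        any(c(coupling$i, coupling$j) > nChannels))
      stop("invariant violated: coupling channel indices must be distinct ",
           "and in 1..", nChannels)
    if (any(coupling$strength < 0 | coupling$strength > 1))
      stop("invariant violated: coupling strength must lie in [0,1]")
  }
  if (noiseSd < 0) stop("noise_sd must be >= 0")
  if (is.null(channelLabels))
    channelLabels <- if (nChannels == 21L) channels1020()
                     else sprintf("CH%02d", seq_len(nChannels))
  new("SubjectSpec", dominantFreq = dominantFreq, bandFractions = fr,
      coupling = coupling, noiseSd = noiseSd,
      nChannels = as.integer(nChannels), fs = fs,
      epochLengthS = epochLengthS, nEpochs = as.integer(nEpochs),
      seed = as.integer(seed), rhythmShare = rhythmShare, bands = bands,
      channelLabels = channelLabels)
}

#' Generate one synthetic subject
#'
#' Deterministic given the spec: the RNG is seeded from `spec@seed` and all
#' draws happen in a fixed order (channel phases, then band noise by band
#' and channel, then observation noise).
#'
#' @param spec a [SubjectSpec-class]
#' @param filterOrder Butterworth order for the band-limiting filters (the
#'   same filters the preprocessing module applies)
#' @return an [EEGRecording-class] of
#'   `nChannels x (fs * epochLengthS * nEpochs)` samples
#' @export
generateSubject <- function(spec, filterOrder = 4L) {
  stopifnot(is(spec, "SubjectSpec"))
  set.seed(spec@seed)
  fs <- spec@fs
  nch <- spec@nChannels
  n <- round(fs * spec@epochLengthS) * spec@nEpochs
  tt <- (seq_len(n) - 1L) / fs
  f0 <- spec@dominantFreq
  home <- bandsContaining(f0, spec@bands)
  fr <- spec@bandFractions
  rhythmVar <- spec@rhythmShare * fr[home]
  amp <- sqrt(2 * rhythmVar)

  phases <- stats::runif(nch, 0, 2 * pi)
  x <- matrix(0, nch, n)
  rhythmSd <- amp / sqrt(2)
  if (rhythmVar > 0) {
    for (c in seq_len(nch))
      x[c, ] <- amp * sin(2 * pi * f0 * tt + phases[c])
    # coupled pairs: channel j mixes in channel i's source, lagged; mixing
    # happens from the original per-channel phases, then the rhythm is
    # rescaled to keep the channel's variance budget intact
    if (nrow(spec@coupling)) {
      for (r in seq_len(nrow(spec@coupling))) {
        i <- spec@coupling$i[r]; j <- spec@coupling$j[r]
        s <- spec@coupling$strength[r]; lag <- spec@coupling$lag[r]
        mix <- (1 - s) * sin(2 * pi * f0 * tt + phases[j]) +
               s * sin(2 * pi * f0 * tt + phases[i] - lag)
        msd <- stats::sd(mix)
        if (msd > 1e-12) x[j, ] <- mix * (rhythmSd / msd)
      }
    }
  }

  for (b in names(spec@bands)) {
    v <- fr[b] - if (b == home) rhythmVar else 0
    if (v <= 1e-12) next
    band <- spec@bands[[b]]
    for (c in seq_len(nch)) {
      bn <- bandpassFilter(stats::rnorm(n), band, fs, order = filterOrder)
      x[c, ] <- x[c, ] + bn / stats::sd(bn) * sqrt(v)
    }
  }

  if (spec@noiseSd > 0)
    x <- x + matrix(stats::rnorm(nch * n, sd = spec@noiseSd), nch, n)
  eegRecording(x, fs, spec@channelLabels,
               subjectId = sprintf("synthetic_seed%d", spec@seed))
}

#' Two coupled channels with a known phase lag
#'
#' Channel 1 carries a unit sinusoid at `freq`; channel 2 carries a
#' `strength`-weighted copy of the same source delayed by `lag` radians at
#' that frequency. Independent white noise of SD `noiseSd` is added to each
#' channel. The analytic PLI of the pair is 1 for any constant `lag` with
#' `sin(lag) != 0` and exactly 0 at zero lag; this is the oracle input for
#' the PLI estimator.
#'
#' @param freq oscillation frequency in Hz, `0 < freq < fs/2`
#' @param lag constant phase lag in radians
#' @param strength mixing weight in `[0,1]`
#' @param durationS duration in seconds
#' @param fs sampling rate in Hz
#' @param noiseSd white noise SD per channel
#' @param seed RNG seed
#' @return a two-channel [EEGRecording-class]
#' @export
coupledPair <- function(freq, lag, strength, durationS, fs = 500,
                        noiseSd = 0, seed = 1L) {
  if (freq >= fs / 2 || freq <= 0)
    stop("freq must lie strictly between 0 and the Nyquist frequency ",
         fs / 2, " Hz")
  if (strength < 0 || strength > 1) stop("strength must lie in [0,1]")
  set.seed(as.integer(seed))
  n <- round(durationS * fs)
  tt <- (seq_len(n) - 1L) / fs
  ch1 <- sin(2 * pi * freq * tt)
  ch2 <- strength * sin(2 * pi * freq * tt - lag)
  if (noiseSd > 0) {
    ch1 <- ch1 + stats::rnorm(n, sd = noiseSd)
    ch2 <- ch2 + stats::rnorm(n, sd = noiseSd)
  }
  eegRecording(rbind(ch1, ch2), fs, c("CH1", "CH2"),
               subjectId = sprintf("pair_seed%d", seed))
}

#' Specify a synthetic cohort
#'
#' Per-subject parameters are drawn from the template plus Gaussian jitter.
#' Per-subject seeds derive from the cohort seed by a fixed counter scheme
#' (`seed + 104729 * k`), so adding a subject never perturbs earlier ones.
#'
#' @param groupLabel cohort group name
#' @param nSubjects number of subjects (>= 1)
#' @param template a [SubjectSpec-class]
#' @param jitter named non-negative SDs; recognized names: `dominant_freq`
#'   (Hz), `band_fractions` (per-band, renormalized after jitter),
#'   `coupling_strength` (clamped to `[0,1]`), `noise_sd` (truncated at 0)
#' @param seed cohort seed
#' @return a [CohortSpec-class]
#' @export
cohortSpec <- function(groupLabel, nSubjects, template, jitter = numeric(),
                       seed = 1L) {
  new("CohortSpec", groupLabel = groupLabel,
      nSubjects = as.integer(nSubjects), template = template,
      jitter = jitter, seed = as.integer(seed))
}

.jv <- function(jitter, name) if (name %in% names(jitter)) jitter[[name]] else 0

.subjectSeed <- function(cohortSeed, k) {
  as.integer((as.numeric(cohortSeed) + 104729 * k) %% 2147483647)
}

#' Draw one subject's spec from a cohort template
#'
#' @param cohort a [CohortSpec-class]
#' @param k subject index (1-based)
#' @return a [SubjectSpec-class] with a derived seed
#' @export
drawSubjectSpec <- function(cohort, k) {
  tpl <- cohort@template
  j <- cohort@jitter
  sSeed <- .subjectSeed(cohort@seed, k)
  # jitter stream is offset from the signal stream so the two never overlap
  set.seed(.subjectSeed(as.numeric(cohort@seed) + 500009, k))
  f0 <- tpl@dominantFreq + stats::rnorm(1, 0, .jv(j, "dominant_freq"))
  f0 <- min(max(f0, 0.6), 47.5)
  fr <- tpl@bandFractions +
    stats::rnorm(length(tpl@bandFractions), 0, .jv(j, "band_fractions"))
  fr <- pmax(fr, 1e-3)
  fr <- fr / sum(fr)
  cp <- tpl@coupling
  if (nrow(cp))
    cp$strength <- pmin(1, pmax(0, cp$strength +
      stats::rnorm(nrow(cp), 0, .jv(j, "coupling_strength"))))
  ns <- max(0, tpl@noiseSd + stats::rnorm(1, 0, .jv(j, "noise_sd")))
  subjectSpec(dominantFreq = f0, bandFractions = fr, coupling = cp,
              noiseSd = ns, nChannels = tpl@nChannels, fs = tpl@fs,
              epochLengthS = tpl@epochLengthS, nEpochs = tpl@nEpochs,
              seed = sSeed, rhythmShare = tpl@rhythmShare,
              bands = tpl@bands, channelLabels = tpl@channelLabels)
}

#' Generate a synthetic cohort with ground truth
#'
#' @param cohort a [CohortSpec-class]
#' @return list with one element per subject, each a list holding
#'   `subjectId`, `recording` and the ground-truth `spec`
#' @export
generateCohort <- function(cohort) {
  stopifnot(is(cohort, "CohortSpec"))
  lapply(seq_len(cohort@nSubjects), function(k) {
    sp <- drawSubjectSpec(cohort, k)
    rec <- generateSubject(sp)
    rec@subjectId <- sprintf("%s_%02d", cohort@groupLabel, k)
    list(subjectId = rec@subjectId, recording = rec, spec = sp)
  })
}

#' Ground-truth manifest of a generated cohort
#'
#' @param subjects result of [generateCohort()]
#' @param groupLabel group name recorded in the manifest
#' @return data.frame: subject id, group, generative parameters
#' @export
cohortGroundTruth <- function(subjects, groupLabel = "") {
  do.call(rbind, lapply(subjects, function(s) {
    sp <- s$spec
    fr <- as.list(sp@bandFractions)
    names(fr) <- paste0("frac_", names(fr))
    cbind(data.frame(subject_id = s$subjectId, group = groupLabel,
                     dominant_freq = sp@dominantFreq,
                     noise_sd = sp@noiseSd, n_channels = sp@nChannels,
                     fs = sp@fs, epoch_length_s = sp@epochLengthS,
                     n_epochs = sp@nEpochs, seed = sp@seed,
                     mean_coupling_strength =
                       if (nrow(sp@coupling)) mean(sp@coupling$strength)
                       else 0),
          as.data.frame(fr))
  }))
}

.chainCoupling <- function(nChannels, strength, lag = pi / 4) {
  data.frame(i = seq_len(nChannels - 1L), j = 2:nChannels,
             lag = lag, strength = strength)
}

#' Archetype subject templates
#'
#' Generator defaults emulating the group-level spectral and connectivity
#' profiles of the three clinical archetypes: DLB-like (dominant rhythm
#' 6.9 Hz, theta-heavy, weak alpha coupling), AD-like (8.4 Hz,
#' alpha/beta-richer, stronger coupling) and mixed DLB+AD-like (6.9 Hz,
#' intermediate). Band fractions follow the published group means, with the
#' remainder assigned to gamma so the variance budget closes. These are
#' emulation defaults, not a reproduction of any patient data.
#'
#' @param nChannels number of channels (default 21)
#' @param seed template seed (per-subject seeds are derived by the cohort)
#' @return a [SubjectSpec-class]
#' @export
dlbTemplate <- function(nChannels = 21L, seed = 1L) {
  subjectSpec(dominantFreq = 6.9,
              bandFractions = c(delta = 0.41, theta = 0.34, alpha1 = 0.07,
                                alpha2 = 0.04, beta = 0.06, gamma = 0.08),
              coupling = .chainCoupling(nChannels, strength = 0.15),
              noiseSd = 0.3, nChannels = nChannels, seed = seed)
}

#' @rdname dlbTemplate
#' @export
adTemplate <- function(nChannels = 21L, seed = 1L) {
  subjectSpec(dominantFreq = 8.4,
              bandFractions = c(delta = 0.32, theta = 0.18, alpha1 = 0.15,
                                alpha2 = 0.09, beta = 0.15, gamma = 0.11),
              coupling = .chainCoupling(nChannels, strength = 0.4),
              noiseSd = 0.3, nChannels = nChannels, seed = seed)
}

#' @rdname dlbTemplate
#' @export
mixedTemplate <- function(nChannels = 21L, seed = 1L) {
  subjectSpec(dominantFreq = 6.9,
              bandFractions = c(delta = 0.42, theta = 0.26, alpha1 = 0.09,
                                alpha2 = 0.04, beta = 0.08, gamma = 0.11),
              coupling = .chainCoupling(nChannels, strength = 0.2),
              noiseSd = 0.3, nChannels = nChannels, seed = seed)
}

#' Archetype cohort specification
#'
#' @param archetype "dlb", "ad" or "mixed"
#' @param nSubjects subjects per cohort
#' @param seed cohort seed
#' @param nChannels channels per subject
#' @param jitter between-subject spreads (see [cohortSpec()])
#' @return a [CohortSpec-class]
#' @export
archetypeCohort <- function(archetype = c("dlb", "ad", "mixed"),
                            nSubjects = 20L, seed = 1L, nChannels = 21L,
                            jitter = c(dominant_freq = 0.5,
                                       band_fractions = 0.02,
                                       coupling_strength = 0.05,
                                       noise_sd = 0.05)) {
  archetype <- match.arg(archetype)
  tpl <- switch(archetype, dlb = dlbTemplate(nChannels),
                ad = adTemplate(nChannels), mixed = mixedTemplate(nChannels))
  cohortSpec(groupLabel = archetype, nSubjects = nSubjects, template = tpl,
             jitter = jitter, seed = seed)
}

#' Read a cohort specification from YAML
#'
#' Expected keys: `group_label`, `n_subjects`, `seed`, optional `jitter`
#' mapping, and a `template` mapping with `dominant_freq`,
#' `band_fractions`, optional `coupling` (list of `[i, j, lag, strength]`),
#' `noise_sd`, `n_channels`, `fs`, `epoch_length_s`, `n_epochs`.
#'
#' @param path YAML file
#' @return a [CohortSpec-class]
#' @export
readCohortSpec <- function(path) {
  y <- yaml::read_yaml(path)
  tp <- y$template
  coupling <- NULL
  if (!is.null(tp$coupling))
    coupling <- do.call(rbind, lapply(tp$coupling, function(r)
      data.frame(i = r[[1]], j = r[[2]], lag = r[[3]], strength = r[[4]])))
  tpl <- subjectSpec(
    dominantFreq = tp$dominant_freq,
    bandFractions = unlist(tp$band_fractions),
    coupling = coupling,
    noiseSd = if (is.null(tp$noise_sd)) 0 else tp$noise_sd,
    nChannels = if (is.null(tp$n_channels)) 21L else tp$n_channels,
    fs = if (is.null(tp$fs)) 500 else tp$fs,
    epochLengthS = if (is.null(tp$epoch_length_s)) 8 else tp$epoch_length_s,
    nEpochs = if (is.null(tp$n_epochs)) 4L else tp$n_epochs)
  cohortSpec(groupLabel = y$group_label, nSubjects = y$n_subjects,
             template = tpl, jitter = unlist(y$jitter), seed = y$seed)
}
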