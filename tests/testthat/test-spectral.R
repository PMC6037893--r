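test_that("a pure sinusoid concentrates its spectral mass at its frequency", {
  eps <- extractEpochs(sineRecording(10, durationS = 32), 8, 4L)
  sp <- powerSpectrum(eps)
  expect_lte(sp@resolution, 0.5)
  inWin <- which(sp@freqs >= 9.5 & sp@freqs <= 10.5)
  expect_gte(sum(sp@density[inWin, 1]) / sum(sp@density[, 1]), 0.95)
})

test_that("zero input gives an all-zero density", {
  eps <- asEpochSet(matrix(0, 2, 4000))
  expect_equal(max(powerSpectrum(eps)@density), 0)
})

test_that("integrated density matches time-domain variance (Parseval)", {
  set.seed(4)
  x <- rbind(rnorm(16000), rnorm(16000, sd = 3))
  eps <- extractEpochs(eegRecording(x, 500), 8, 4L)
  sp <- powerSpectrum(eps)
  tot <- unname(colSums(sp@density) * sp@resolution)
  expect_equal(tot[1], stats::var(x[1, ]), tolerance = 0.05)
  expect_equal(tot[2], stats::var(x[2, ]), tolerance = 0.05)
})

test_that("white-noise spectra are flat across 5-Hz windows", {
  set.seed(8)
  eps <- extractEpochs(eegRecording(matrix(rnorm(32000), 1), 500), 2, 16L)
  sp <- powerSpectrum(eps)
  wins <- lapply(seq(5, 45, by = 5), function(lo)
    mean(sp@density[sp@freqs > lo & sp@freqs <= lo + 5, 1]))
  r <- range(unlist(wins))
  expect_gt(r[1] / r[2], 1 / 1.4)
})

test_that("epochs shorter than the analysis segment are rejected", {
  eps <- asEpochSet(matrix(rnorm(500), 1, 500))
  expect_error(powerSpectrum(eps), "shorter than")
})

test_that("relative band powers normalize, bound and scale-invariantly", {
  set.seed(6)
  x <- matrix(rnorm(3 * 16000), 3)
  eps <- extractEpochs(eegRecording(x, 500), 8, 4L)
  rp <- relativeBandPower(powerSpectrum(eps))
  expect_true(all(rp >= 0 & rp <= 1))
  expect_lt(max(abs(colSums(rp) - 1)), 1e-6)
  # scale invariance
  rp2 <- relativeBandPower(powerSpectrum(
    extractEpochs(eegRecording(x * 17.3, 500), 8, 4L)))
  expect_lt(max(abs(rp2 - rp)), 1e-9)
  # flat-spectrum expectation for delta: (4 - 0.5) / (48 - 0.5)
  expect_lt(abs(mean(rp["delta", ]) - 3.5 / 47.5), 0.02)
})

test_that("a pure 10 Hz sinusoid is almost entirely alpha-1", {
  eps <- extractEpochs(sineRecording(10, durationS = 32), 8, 4L)
  rp <- relativeBandPower(powerSpectrum(eps))
  expect_gte(rp["alpha1", 1], 0.95)
})

test_that("zero total power is an error, not a fraction", {
  eps <- asEpochSet(matrix(0, 1, 4000))
  expect_error(relativeBandPower(powerSpectrum(eps)), "zero total power")
})

test_that("peak frequency finds the argmax with a low-frequency tie-break", {
  eps <- extractEpochs(sineRecording(7, durationS = 32), 8, 4L)
  pk <- peakFrequency(powerSpectrum(eps))
  expect_equal(pk$global, 7, tolerance = 0.25)
  # the larger-amplitude component dominates a mixture
  tt <- (0:15999) / 500
  mix <- rbind(2 * sin(2 * pi * 6 * tt) + sin(2 * pi * 10 * tt))
  pk2 <- peakFrequency(powerSpectrum(
    extractEpochs(eegRecording(mix, 500), 8, 4L)))
  expect_equal(pk2$global, 6, tolerance = 0.25)
  # exact equal-power tie in the channel average breaks to the lower bin
  dens <- matrix(1e-6, 19, 2)
  freqs <- seq(4, 13, by = 0.5)
  dens[freqs == 6, 1] <- 1
  dens[freqs == 10, 2] <- 1
  spt <- new("PowerSpectrum", freqs = freqs, density = dens,
             resolution = 0.5, channelLabels = c("a", "b"))
  pk3 <- peakFrequency(spt)
  expect_equal(unname(pk3$perChannel), c(6, 10))
  expect_equal(pk3$global, 6)
  expect_error(peakFrequency(spt, c(50, 60)), "empty search range")
})

test_that("peak-frequency variability follows the population SD", {
  # 16 identical sub-epochs -> zero variability
  piece <- sineRecording(7, durationS = 2)
  eps <- new("EpochSet", epochs = rep(list(samples(piece)), 16L), fs = 500,
             channelLabels = channelLabels(piece), epochLengthS = 2,
             subjectId = "s")
  expect_equal(peakFrequencyVariability(eps), 0)
  # 8 pieces at 6 Hz and 8 at 8 Hz -> SD exactly 1 (divisor n)
  p6 <- samples(sineRecording(6, durationS = 2))
  p8 <- samples(sineRecording(8, durationS = 2))
  eps2 <- new("EpochSet", epochs = c(rep(list(p6), 8), rep(list(p8), 8)),
              fs = 500, channelLabels = "CH01", epochLengthS = 2,
              subjectId = "s")
  expect_equal(peakFrequencyVariability(eps2), 1.0)
  expect_equal(peakFrequencyVariability(eps2, divisor = "sample"),
               stats::sd(rep(c(6, 8), each = 8)))
  expect_error(peakFrequencyVariability(
    new("EpochSet", epochs = list(p6), fs = 500, channelLabels = "CH01",
        epochLengthS = 2, subjectId = "s")), "at least 2")
})

test_that("a stationary synthetic subject has sub-resolution variability", {
  sp <- subjectSpec(7, c(theta = 0.6, delta = 0.2, alpha1 = 0.1,
                         alpha2 = 0.05, beta = 0.05),
                    noiseSd = 0.2, nChannels = 3, seed = 3L)
  v <- peakFrequencyVariability(
    splitEpochs(extractEpochs(generateSubject(sp))))
  expect_lt(v, 1.0)
})

test_that("theta/alpha ratio follows its closed form", {
  mk <- function(th, a1, a2) {
    rp <- matrix(c(th, a1, a2), 3, 2,
                 dimnames = list(c("theta", "alpha1", "alpha2"), NULL))
    rp
  }
  expect_equal(thetaAlphaRatio(mk(0.18, 0.15, 0.09)), 0.18 / 0.42,
               tolerance = 1e-12)
  expect_equal(round(thetaAlphaRatio(mk(0.18, 0.15, 0.09)), 1), 0.4)
  expect_equal(thetaAlphaRatio(mk(0, 0.2, 0.1)), 0)
  expect_equal(thetaAlphaRatio(mk(0.3, 0.2, 0.1)), 0.5)
  expect_error(thetaAlphaRatio(mk(0, 0, 0)), "zero denominator")
})

test_that("raising the generator's theta fraction raises the ratio", {
  levels <- seq(0.1, 0.5, by = 0.1)
  ratios <- vapply(levels, function(th) {
    rest <- 1 - th
    mean(vapply(1:10, function(s) {
      sp <- subjectSpec(6, c(theta = th, delta = rest * 0.5,
                             alpha1 = rest * 0.3, alpha2 = rest * 0.2),
                        noiseSd = 0.1, nChannels = 1, seed = s)
      ss <- spectralSummary(extractEpochs(generateSubject(sp)))
      ss@thetaAlphaRatio
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("generated dominant frequencies are recovered within resolution", {
  for (f0 in c(6.9, 8.4, 10.2)) {
    home <- bandsContaining(f0)
    fr <- c(delta = 0.15, theta = 0.15, alpha1 = 0.1, alpha2 = 0.1,
            beta = 0.05)
    fr[home] <- fr[home] + (1 - sum(fr))
    sp <- subjectSpec(f0, fr, noiseSd = 0.1, nChannels = 2, seed = 11L)
    ss <- spectralSummary(extractEpochs(generateSubject(sp)))
    expect_lte(abs(ss@globalPeakFreq - f0), 0.5)
  }
})
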