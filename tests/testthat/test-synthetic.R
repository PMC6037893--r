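test_that("subject specs validate their invariants with informative errors", {
  expect_error(subjectSpec(10, c(alpha1 = 0.5, theta = 0.4)),
               "sum to 1")
  expect_error(subjectSpec(10, c(alpha1 = -0.2, theta = 1.2)),
               ">= 0")
  expect_error(subjectSpec(60, c(alpha1 = 1)), "exactly one declared band")
  expect_error(subjectSpec(10, c(alpha1 = 1), nChannels = 2,
                           coupling = data.frame(i = 1, j = 1, lag = 0,
                                                 strength = 0.5)),
               "distinct")
  expect_error(subjectSpec(10, c(alpha1 = 1), nChannels = 2,
                           coupling = data.frame(i = 1, j = 3, lag = 0,
                                                 strength = 0.5)),
               "coupling channel indices")
  expect_error(subjectSpec(10, c(alpha1 = 1), nChannels = 2,
                           coupling = data.frame(i = 1, j = 2, lag = 0,
                                                 strength = 1.5)),
               "strength")
})

test_that("generation is bit-identical given the same spec and seed", {
  sp <- subjectSpec(10, c(alpha1 = 0.7, theta = 0.3), noiseSd = 0.1,
                    nChannels = 3, seed = 42L)
  r1 <- generateSubject(sp)
  r2 <- generateSubject(sp)
  expect_identical(samples(r1), samples(r2))
  expect_equal(dim(samples(r1)), c(3L, 500L * 8L * 4L))
})

test_that("a single narrowband source concentrates its band's power", {
  # pure sinusoid at the alpha-1 upper edge (rhythmShare 1: no band noise)
  sp <- subjectSpec(10, c(alpha1 = 1), noiseSd = 0, nChannels = 2,
                    seed = 1L, rhythmShare = 1)
  rp <- relativeBandPower(powerSpectrum(extractEpochs(generateSubject(sp))))
  expect_true(all(rp["alpha1", ] >= 0.95))
})

test_that("band fractions are recovered within 0.05, averaged over seeds", {
  target <- c(theta = 0.5, alpha1 = 0.3, delta = 0.2)
  got <- rowMeans(vapply(1:20, function(s) {
    sp <- subjectSpec(6, target, noiseSd = 0.05, nChannels = 1, seed = s,
                      epochLengthS = 30, nEpochs = 2L)
    rp <- relativeBandPower(powerSpectrum(
      extractEpochs(generateSubject(sp), 30, 2L)))
    rowMeans(rp)[names(target)]
  }, numeric(3)))
  expect_lt(max(abs(got - target)), 0.05)
})

test_that("with no observation noise the per-band variance budget closes", {
  sp <- subjectSpec(6, c(theta = 0.4, delta = 0.3, alpha1 = 0.2,
                         beta = 0.1),
                    noiseSd = 0, nChannels = 1, seed = 7L,
                    epochLengthS = 30, nEpochs = 2L)
  rp <- relativeBandPower(powerSpectrum(
    extractEpochs(generateSubject(sp), 30, 2L)))
  got <- rowMeans(rp)[c("theta", "delta", "alpha1", "beta")]
  expect_lt(max(abs(got - c(0.4, 0.3, 0.2, 0.1))), 0.05)
})

test_that("coupled pairs hit the analytic PLI cases", {
  expect_equal(rawPairPli(coupledPair(10, pi / 2, 1, 8, noiseSd = 0)), 1.0)
  expect_equal(rawPairPli(coupledPair(10, 0, 1, 8, noiseSd = 0)), 0.0)
  expect_error(coupledPair(300, pi / 2, 1, 8), "Nyquist")
})

test_that("the noisy coupled pair reproduces its frozen reference PLI", {
  # Monte-Carlo reference computed once from raw analytic phases and frozen
  v <- rawPairPli(coupledPair(10, pi / 4, 0.8, 60, noiseSd = 0.3, seed = 7L))
  expect_equal(v, 0.8705882, tolerance = 1e-6)
  expect_gt(v, 0.5)
  expect_lt(v, 1.0)
})

test_that("measured PLI is non-decreasing in coupling strength", {
  curve <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s) {
    mean(vapply(1:20, function(sd1)
      rawPairPli(coupledPair(10, pi / 4, s, 20, noiseSd = 0.5, seed = sd1)),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(curve) >= 0))
  expect_lt(curve[1], 0.1)
  expect_gt(curve[5], 0.5)
})

test_that("cohorts derive distinct, stable per-subject seeds", {
  co <- cohortSpec("g", 41L, subjectSpec(10, c(alpha1 = 1), nChannels = 2,
                                         seed = 1L),
                   jitter = c(dominant_freq = 0.3), seed = 9L)
  subs <- generateCohort(co)
  expect_length(subs, 41L)
  seeds <- vapply(subs, function(s) s$spec@seed, integer(1))
  expect_length(unique(seeds), 41L)
  # adding subjects never perturbs earlier ones
  co2 <- cohortSpec("g", 5L, co@template, jitter = co@jitter, seed = 9L)
  subs2 <- generateCohort(co2)
  expect_identical(samples(subs2[[3]]$recording), samples(subs[[3]]$recording))
})

test_that("zero jitter replicates the template while recordings differ", {
  tpl <- subjectSpec(10, c(alpha1 = 0.8, theta = 0.2), noiseSd = 0.1,
                     nChannels = 2, seed = 1L)
  subs <- generateCohort(cohortSpec("g", 3L, tpl, seed = 4L))
  doms <- vapply(subs, function(s) s$spec@dominantFreq, numeric(1))
  expect_true(all(doms == 10))
  expect_false(identical(samples(subs[[1]]$recording),
                         samples(subs[[2]]$recording)))
  gt <- cohortGroundTruth(subs, "g")
  expect_equal(nrow(gt), 3L)
  expect_true(all(gt$dominant_freq == 10))
})

test_that("the shipped example configs parse", {
  co <- readCohortSpec(system.file("extdata", "cohort_dlb_example.yaml",
                                   package = "qeegtools"))
  expect_equal(co@nSubjects, 5L)
  expect_equal(co@template@dominantFreq, 6.9)
  expect_equal(nrow(co@template@coupling), 5L)
  m <- readMontage(system.file("extdata", "montage_1020.yaml",
                               package = "qeegtools"))
  expect_identical(m@labels, channels1020())
})

test_that("cohort specs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "group_label: demo",
    "n_subjects: 3",
    "seed: 5",
    "jitter:",
    "  dominant_freq: 0.4",
    "template:",
    "  dominant_freq: 6.9",
    "  band_fractions: {delta: 0.4, theta: 0.35, alpha1: 0.1, alpha2: 0.05, beta: 0.05, gamma: 0.05}",
    "  noise_sd: 0.2",
    "  n_channels: 4",
    "  coupling:",
    "    - [1, 2, 0.785, 0.5]"), path)
  co <- readCohortSpec(path)
  expect_s4_class(co, "CohortSpec")
  expect_equal(co@nSubjects, 3L)
  expect_equal(co@template@dominantFreq, 6.9)
  expect_equal(co@template@coupling$strength, 0.5)
  expect_equal(unname(co@jitter["dominant_freq"]), 0.4)
})
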