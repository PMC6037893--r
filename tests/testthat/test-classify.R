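test_that("the feature vector has the fixed 25-name order", {
  nm <- qeegFeatureNames()
  expect_length(nm, 25L)
  expect_equal(nm[19], "theta_alpha_ratio")
  expect_equal(nm[23:25],
               c("mst_degree_highest", "mst_leaf_number",
                 "mst_tree_hierarchy"))
  expect_equal(nm[1:3],
               c("delta_power_lowest", "delta_power_mean",
                 "delta_power_highest"))
  expect_false("diameter" %in% nm || any(grepl("gamma", nm)))
})

test_that("a complete subject yields 25 bounded, ordered features", {
  sp <- subjectSpec(9, c(alpha1 = 0.4, theta = 0.3, delta = 0.2,
                         beta = 0.1),
                    noiseSd = 0.2, nChannels = 6, seed = 5L)
  res <- analyzeSubject(generateSubject(sp), m = NULL)
  fv <- res$features
  expect_length(fv, 25L)
  expect_identical(names(fv), qeegFeatureNames())
  powers <- fv[grepl("_power_", names(fv))]
  expect_true(all(powers >= 0 & powers <= 1))
  plis <- fv[grepl("^pli_", names(fv))]
  expect_true(all(plis >= 0 & plis <= 1))
})

test_that("identical channels collapse lowest/mean/highest reductions", {
  x <- samples(sineRecording(9, durationS = 32))
  x <- x + 0.2 * samples(sineRecording(6, durationS = 32)) +
       0.05 * samples(sineRecording(20, durationS = 32))
  rec <- eegRecording(rbind(x[1, ], x[1, ], x[1, ]), 500)
  ss <- spectralSummary(extractEpochs(rec))
  for (b in c("delta", "theta", "alpha1", "beta")) {
    rp <- relativePower(ss)[b, ]
    expect_equal(min(rp), max(rp))
  }
  expect_equal(min(ss@peakFreq), max(ss@peakFreq))
})

test_that("the OOB forest is deterministic and honors its bootstrap", {
  set.seed(100)
  X <- matrix(rnorm(40 * 25), 40, 25,
              dimnames = list(NULL, qeegFeatureNames()))
  lab <- rep(c("ad", "dlb"), each = 20)
  r1 <- randomForestOOB(X, lab, nTree = 500L, mTry = 5L, seed = 1L)
  r2 <- randomForestOOB(X, lab, nTree = 500L, mTry = 5L, seed = 1L)
  expect_identical(r1@oobPredictions, r2@oobPredictions)
  expect_identical(r1@vimp, r2@vimp)
  expect_equal(r1@accuracy, r2@accuracy)
  expect_length(r1@oobPredictions, 40L)
  expect_length(r1@excluded, 0L)
  expect_error(randomForestOOB(X, rep("a", 40)), "two distinct labels")
  expect_error(randomForestOOB(X[1:8, ], rep(c("a", "b"), 4)),
               "at least 5")
})

test_that("the out-of-bag fraction matches the 2n/3 bootstrap theory", {
  set.seed(101)
  n <- 40
  X <- matrix(rnorm(n * 25), n, 25,
              dimnames = list(NULL, qeegFeatureNames()))
  lab <- rep(c("ad", "dlb"), each = n / 2)
  set.seed(1)
  rf <- randomForest::randomForest(
    x = as.data.frame(X), y = factor(lab), ntree = 1000L, mtry = 5L,
    replace = TRUE, sampsize = ceiling(2 * n / 3))
  expected <- (1 - 1 / n)^ceiling(2 * n / 3)
  expect_equal(mean(rf$oob.times) / 1000, expected, tolerance = 0.02)
  expect_true(all(rf$oob.times >= 1L))
})

test_that("a 3-SD theta/alpha contrast is classified near its Bayes rate", {
  lab <- rep(c("ad", "dlb"), each = 20)
  runs <- lapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 25), 40, 25,
                dimnames = list(NULL, qeegFeatureNames()))
    X[21:40, "theta_alpha_ratio"] <-
      X[21:40, "theta_alpha_ratio"] + 3
    r <- randomForestOOB(X, lab, nTree = 500L, mTry = 5L, seed = 1L)
    list(acc = r@accuracy, top = names(which.max(r@vimp)), vimp = r@vimp)
  })
  accs <- vapply(runs, `[[`, numeric(1), "acc")
  expect_gte(mean(accs), 0.9)
  # the constructed feature carries the top VIMP in every replicate
  expect_true(all(vapply(runs, `[[`, "", "top") == "theta_alpha_ratio"))
  # and pure-noise features never exceed it (20-seed average)
  vimpMean <- rowMeans(vapply(runs, `[[`, numeric(25), "vimp"))
  expect_equal(names(which.max(vimpMean)), "theta_alpha_ratio")
})

test_that("exchangeable cohorts classify at chance", {
  set.seed(200)
  X <- matrix(rnorm(40 * 25), 40, 25,
              dimnames = list(NULL, qeegFeatureNames()))
  lab <- rep(c("ad", "dlb"), each = 20)
  r <- randomForestOOB(X, lab, nTree = 500L, mTry = 5L, seed = 2L)
  expect_gte(r@accuracy, 0.35)
  expect_lte(r@accuracy, 0.65)
})

test_that("subject order does not matter beyond seeded resampling", {
  set.seed(7)
  X <- matrix(rnorm(40 * 25), 40, 25,
              dimnames = list(NULL, qeegFeatureNames()))
  X[21:40, "theta_alpha_ratio"] <- X[21:40, "theta_alpha_ratio"] + 3
  lab <- rep(c("ad", "dlb"), each = 20)
  r1 <- randomForestOOB(X, lab, nTree = 500L, mTry = 5L, seed = 1L)
  perm <- sample(40)
  r2 <- randomForestOOB(X[perm, ], lab[perm], nTree = 500L, mTry = 5L,
                        seed = 1L)
  expect_lt(abs(r1@accuracy - r2@accuracy), 0.1)
})

test_that("group comparisons follow ANOVA / Kruskal-Wallis conventions", {
  # identical groups (same values, within-group spread): no evidence
  x <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  res <- compareGroups(x, g)
  expect_equal(unname(res$anova["statistic"]), 0)
  expect_equal(unname(res$anova["p"]), 1)
  # all-constant degenerate input
  resc <- compareGroups(rep(5, 12), g)
  expect_equal(unname(resc$anova["statistic"]), 0)
  expect_equal(unname(resc$anova["p"]), 1)
  # 10-SD separation is detected by both methods
  set.seed(9)
  x2 <- c(rnorm(20), rnorm(20, mean = 10))
  g2 <- rep(c("a", "b"), each = 20)
  res2 <- compareGroups(x2, g2)
  expect_lt(res2$anova[["p"]], 1e-6)
  expect_lt(res2$kruskal[["p"]], 1e-6)
  # Bonferroni multiplies raw pairwise p by the comparison count
  res3 <- compareGroups(c(rnorm(20), rnorm(20, 2), rnorm(20, 4)),
                        rep(c("a", "b", "c"), each = 20))
  expect_equal(res3$posthoc$p_adj,
               pmin(1, res3$posthoc$p_raw * 3))
  expect_error(compareGroups(1:5, c("a", "a", "a", "a", "b")),
               "at least 2 observations")
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(3)
  ps <- replicate(1000, {
    compareGroups(rnorm(30), rep(1:3, each = 10))$anova[["p"]]
  })
  D <- suppressWarnings(stats::ks.test(ps, "punif")$statistic)
  expect_lt(unname(D), 0.05)
})

test_that("feature tables and classifier reports round-trip to disk", {
  set.seed(300)
  ft <- cbind(data.frame(subject_id = sprintf("s%02d", 1:10),
                         group = rep(c("a", "b"), 5)),
              as.data.frame(matrix(rnorm(250), 10, 25,
                                   dimnames = list(NULL, qeegFeatureNames()))))
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(ft, path)
  back <- readFeatureTable(path)
  expect_equal(back, ft, tolerance = 1e-12)
  expect_error(writeFeatureTable(ft[, -3], path), "lacks column")

  set.seed(301)
  X <- matrix(rnorm(40 * 25), 40, 25,
              dimnames = list(NULL, qeegFeatureNames()))
  r <- randomForestOOB(X, rep(c("a", "b"), each = 20), nTree = 200L,
                       seed = 3L)
  jpath <- withr::local_tempfile(fileext = ".json")
  cpath <- withr::local_tempfile(fileext = ".csv")
  writeClassifierReport(r, jpath, cpath)
  j <- jsonlite::read_json(jpath)
  expect_equal(j$accuracy, r@accuracy)
  expect_equal(j$n_tree, 200L)
  expect_equal(nrow(utils::read.csv(cpath)), 40L)
})
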