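#' The fixed 25-feature order of the qEEG classifier
#'
#' Lowest/mean/highest relative power across the 21 channels for delta,
#' theta, alpha-1, alpha-2 and beta (positions 1-15); lowest/mean/highest
#' peak frequency (16-18); theta/alpha ratio (19); lowest/mean/highest
#' alpha-band PLI over all channel pairs (20-22); and the spanning-tree
#' highest degree, leaf number and tree hierarchy (23-25). Gamma power and
#' the tree diameter are computed by the pipeline but are not classifier
#' features.
#'
#' @return character vector of 25 feature names, in order
#' @export
qeegFeatureNames <- function() {
  powers <- as.vector(vapply(c("delta", "theta", "alpha1", "alpha2", "beta"),
    function(b) paste0(b, "_power_", c("lowest", "mean", "highest")),
    character(3)))
  c(powers,
    paste0("peak_freq_", c("lowest", "mean", "highest")),
    "theta_alpha_ratio",
    paste0("pli_", c("lowest", "mean", "highest")),
    "mst_degree_highest", "mst_leaf_number", "mst_tree_hierarchy")
}

.lmh <- function(x) c(min(x), mean(x), max(x))

#' Assemble the 25-feature vector of one subject
#'
#' Lowest/mean/highest reductions are taken over the channels (powers, peak
#' frequency) or over the upper triangle of the PLI matrix; the tree
#' contributes its normalized highest degree, leaf fraction and hierarchy.
#' The tree diameter is intentionally not a feature.
#'
#' @param spectral a [SpectralSummary-class]
#' @param connectivity a [ConnectivityMatrix-class]
#' @param tree a [TreeTopology-class]
#' @return named numeric of length 25, ordered as [qeegFeatureNames()]
#' @export
buildFeatureVector <- function(spectral, connectivity, tree) {
  if (missing(spectral) || missing(connectivity) || missing(tree))
    stop("all of spectral, connectivity and tree are required; missing: ",
         paste(c("spectral", "connectivity", "tree")[c(missing(spectral),
             missing(connectivity), missing(tree))], collapse = ", "))
  stopifnot(is(spectral, "SpectralSummary"),
            is(connectivity, "ConnectivityMatrix"), is(tree, "TreeTopology"))
  rp <- spectral@relPower
  need <- c("delta", "theta", "alpha1", "alpha2", "beta")
  if (!all(need %in% rownames(rp)))
    stop("spectral summary lacks band(s): ",
         paste(setdiff(need, rownames(rp)), collapse = ", "))
  vals <- c(
    as.vector(vapply(need, function(b) .lmh(rp[b, ]), numeric(3))),
    .lmh(spectral@peakFreq),
    spectral@thetaAlphaRatio,
    unname(pliFeatures(connectivity)),
    unname(tree@metrics[c("degree_max_norm", "leaf_fraction",
                          "tree_hierarchy")]))
  stats::setNames(vals, qeegFeatureNames())
}

#' Out-of-bag random-forest classification
#'
#' An ensemble of CART trees, each grown on a bootstrap sample of size
#' `ceiling(2n/3)` drawn with replacement (set `conventionalBootstrap =
#' TRUE` for the usual size-n bootstrap), with `mTry` features considered
#' per split. Cross-validation is internal: each subject is predicted by
#' majority vote over the trees whose bootstrap excluded it, so no separate
#' test set is needed. Variable importance (VIMP) is permutation
#' importance: the mean decrease in OOB accuracy when a feature is permuted
#' within the OOB samples. The forest is fitted by
#' [randomForest::randomForest()]; the run is deterministic given `seed`.
#'
#' @param features numeric matrix or data.frame, one row per subject
#' @param labels class label per subject (exactly two classes, each with at
#'   least 5 subjects)
#' @param nTree number of trees
#' @param mTry features sampled per split (default `floor(sqrt(p))`)
#' @param seed RNG seed
#' @param positive label treated as positive for sensitivity/specificity;
#'   default the lexicographically first label
#' @param conventionalBootstrap use the standard size-n bootstrap instead
#'   of the 2n/3 variant
#' @return a [ClassifierReport-class]
#' @export
randomForestOOB <- function(features, labels, nTree = 1000L,
                            mTry = max(1L, floor(sqrt(ncol(features)))),
                            seed = 1L, positive = NULL,
                            conventionalBootstrap = FALSE) {
  x <- as.data.frame(features)
  y <- factor(labels)
  if (nlevels(y) != 2L)
    stop("exactly two distinct labels are required, got ", nlevels(y))
  if (any(table(y) < 5L))
    stop("each class needs at least 5 subjects")
  if (is.null(positive)) positive <- sort(levels(y))[1]
  if (!positive %in% levels(y)) stop("positive class not among the labels")
  n <- nrow(x)
  sampSize <- if (conventionalBootstrap) n else ceiling(2 * n / 3)
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = as.integer(nTree), mtry = as.integer(mTry),
    replace = TRUE, sampsize = sampSize, importance = TRUE)
  pred <- rf$predicted
  neverOob <- rf$oob.times == 0L
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(n))
  use <- !neverOob & !is.na(pred)
  isPos <- y == positive
  acc <- mean(pred[use] == y[use])
  sens <- mean(pred[use & isPos] == y[use & isPos])
  spec <- mean(pred[use & !isPos] == y[use & !isPos])
  vimp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  predChr <- stats::setNames(as.character(pred), ids)
  new("ClassifierReport", accuracy = acc, sensitivity = sens,
      specificity = spec, vimp = vimp, oobPredictions = predChr,
      labels = levels(y), positiveClass = positive,
      nTree = as.integer(nTree), mTry = as.integer(mTry),
      seed = as.integer(seed), excluded = ids[neverOob])
}

#' Group comparison of a feature
#'
#' One-way ANOVA (F) and Kruskal-Wallis (H) across the groups, plus
#' Bonferroni-corrected pairwise post-hoc t-tests (raw p multiplied by the
#' number of comparisons, capped at 1). Degenerate all-constant input
#' (zero between- and within-group variance) is reported as F = 0, p = 1.
#'
#' @param x numeric feature values
#' @param groups group membership, at least 2 groups with at least 2
#'   observations each
#' @return list with `anova` (statistic, p), `kruskal` (statistic, p) and
#'   `posthoc` (data.frame: group1, group2, p_raw, p_adj)
#' @export
compareGroups <- function(x, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("at least 2 groups are required")
  if (any(table(g) < 2L))
    stop("every group needs at least 2 observations")
  if (stats::sd(x) == 0) {
    # all-constant input: no evidence either way
    fstat <- 0; pAov <- 1
    kw <- list(statistic = 0, p.value = 1)
  } else {
    fit <- stats::aov(x ~ g)
    tab <- summary(fit)[[1]]
    fstat <- tab[["F value"]][1]
    pAov <- tab[["Pr(>F)"]][1]
    if (is.na(fstat)) { fstat <- 0; pAov <- 1 }
    kw <- tryCatch(stats::kruskal.test(x, g),
                   error = function(e) list(statistic = 0, p.value = 1))
  }
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  nComp <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(nComp), function(k) {
    a <- x[g == pairs[1, k]]; b <- x[g == pairs[2, k]]
    p <- if (stats::sd(c(a, b)) == 0) 1
         else tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k], p_raw = p,
               p_adj = min(1, p * nComp))
  }))
  list(anova = c(statistic = unname(fstat), p = unname(pAov)),
       kruskal = c(statistic = unname(kw$statistic), p = unname(kw$p.value)),
       posthoc = posthoc)
}

#' Group comparison across a whole feature table
#'
#' Applies [compareGroups()] to every feature column.
#'
#' @param featureTable data.frame with a `group` column and feature columns
#' @param features columns to test (default: all 25 classifier features
#'   present in the table)
#' @return data.frame: feature, anova_F, anova_p, kruskal_H, kruskal_p
#' @export
compareGroupsTable <- function(featureTable,
                               features = intersect(qeegFeatureNames(),
                                                    names(featureTable))) {
  do.call(rbind, lapply(features, function(f) {
    res <- compareGroups(featureTable[[f]], featureTable$group)
    data.frame(feature = f,
               anova_F = res$anova[["statistic"]],
               anova_p = res$anova[["p"]],
               kruskal_H = res$kruskal[["statistic"]],
               kruskal_p = res$kruskal[["p"]])
  }))
}
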