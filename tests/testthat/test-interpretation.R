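fakeLinearModel <- function(w, names = paste0("Otu", seq_along(w))) {
  new("FittedModel", modelName = "l2_logistic", hyperparams = list(cost = 1),
      fit = NULL, featureIds = names, classLevels = c("healthy", "SRN"),
      weights = as.numeric(w), seed = 1L)
}

test_that("weight ranks order by |w| with signs and deterministic ties", {
  r <- rankWeights(fakeLinearModel(c(3, -2, 0)))
  expect_equal(unname(r$perSplit[, 1]), c(1, 2, 3))
  expect_equal(unname(r$signs[, 1]), c(1, -1, 0))

  tied <- rankWeights(fakeLinearModel(c(2, -2, 1)))
  expect_equal(unname(tied$perSplit[, 1]), c(1.5, 1.5, 3))
  # reporting order at equal median rank is by feature id
  expect_equal(tied$aggregate$feature[1:2], c("Otu1", "Otu2"))

  nonlin <- new("FittedModel", modelName = "random_forest",
                hyperparams = list(), fit = NULL, featureIds = "a",
                classLevels = c("healthy", "SRN"), weights = numeric(0),
                seed = 1L)
  expect_error(rankWeights(nonlin), "linear")
})

test_that("a dominant informative feature earns median rank 1 across splits", {
  # many features keep the compositional depletion of the non-informative
  # columns small relative to the ten-fold boost of the informative one
  syn <- signalData(nSamples = 100L, nFeatures = 100L, nInformative = 1L,
                    effectSize = 10)
  tab <- minmaxNormalize(syn$table)
  bench <- runBenchmark(tab, syn$labels, models = "l2_logistic",
                        nSplits = 5L, cvRepeats = 1L, grids = tinyGrids(),
                        baseSeed = 3L, keepModels = TRUE)
  r <- rankWeights(bench$models$l2_logistic, topN = 5L)
  inf <- syn$groundTruth$informative[1L]
  expect_equal(r$aggregate$median_rank[r$aggregate$feature == inf], 1)
  expect_equal(r$top[1L], inf)
})

test_that("perfect-correlation grouping follows the sign and tie rules", {
  m <- cbind(a = 1:5, b = c(10, 20, 30, 40, 50), c = 5:1,
             d = c(2, 1, 4, 3, 5))
  rownames(m) <- paste0("s", 1:5)
  g <- findPerfectGroups(OtuTable(m))
  expect_equal(nGroups(g), 3L)
  multi <- groupMembers(g)[groupSizes(g) > 1L]
  expect_setequal(multi[[1L]], c("a", "b"))  # rho = +1 grouped
  # c (rho = -1 with a) and d (|rho| < 1) stay singletons

  # all-zero columns are degenerate and stay singletons
  z <- cbind(m[, 1:2], z1 = rep(0, 5), z2 = rep(0, 5))
  gz <- findPerfectGroups(OtuTable(z))
  expect_equal(sort(unname(groupSizes(gz))), c(1L, 1L, 2L))

  # below the significance sample size everything is a singleton
  g4 <- findPerfectGroups(OtuTable(m[1:4, ]))
  expect_equal(nGroups(g4), 4L)
})

test_that("grouping partitions the feature universe", {
  syn <- generateSyntheticOtus(nSamples = 40L, nFeatures = 25L,
                               nInformative = 2L, blockSizes = c(3L, 2L),
                               sparsity = 0.3, depthMean = 1000L,
                               seed = 8L)
  g <- findPerfectGroups(syn$table)
  expect_equal(sum(groupSizes(g)), nFeatures(syn$table))
  expect_setequal(unlist(groupMembers(g)), featureIds(syn$table))
  expect_setequal(groupMembers(g)[groupSizes(g) == 3L][[1L]],
                  syn$groundTruth$blocks[[1L]])
})

test_that("permuting an inert feature leaves the AUROC untouched", {
  syn <- signalData(nSamples = 60L, nFeatures = 10L, nInformative = 1L,
                    effectSize = 10)
  x <- abundances(minmaxNormalize(syn$table))
  # a hand-built linear model that only uses the informative feature
  w <- numeric(ncol(x))
  names(w) <- colnames(x)
  inf <- syn$groundTruth$informative[1L]
  w[inf] <- 1
  fm <- fakeLinearModel(w, colnames(x))
  fm@fit <- list(w = w, b = 0)
  fm@modelName <- "l2_svm_linear"
  g <- findPerfectGroups(OtuTable(x, stage = "normalized"))
  imp <- permutationImportance(fm, x, syn$labels, g, nPerms = 10L,
                               seed = 2L)
  inert <- imp$drop[!grepl(inf, imp$members)]
  expect_true(all(abs(inert) < 1e-12))
  expect_gt(imp$drop[grepl(inf, imp$members)], 0.2)
  expect_equal(imp$rank[grepl(inf, imp$members)], 1L)
  expect_true(all(imp$base_auc == imp$base_auc[1L]))
})

test_that("degenerate and mismatched importance inputs error", {
  syn <- signalData(nSamples = 20L, nFeatures = 6L)
  x <- abundances(minmaxNormalize(syn$table))
  fm <- fitModel(modelSpec("l2_logistic"), x, syn$labels,
                 list(cost = 1), 1)
  g <- findPerfectGroups(OtuTable(x, stage = "normalized"))
  expect_error(permutationImportance(fm, x[1, , drop = FALSE],
                                     syn$labels[1], g), "fewer than two")
  gBad <- new("CorrelationGroups", featureIds = c("ghost"),
              membership = c(ghost = 1L))
  expect_error(permutationImportance(fm, x, syn$labels, gBad),
               "unknown feature")
})

test_that("grouped permutation beats per-column permutation on split weights", {
  # one informative feature duplicated into a perfect block of two: an
  # L2-penalized linear model spreads weight across the twins, so jointly
  # permuting the pair must hurt more than permuting either column alone
  syn <- generateSyntheticOtus(nSamples = 120L, nFeatures = 12L,
                               nInformative = 1L, effectSize = 10,
                               caseFraction = 0.5, blockSizes = 2L,
                               sparsity = 0.2, depthMean = 2000L,
                               seed = 13L)
  tab <- minmaxNormalize(syn$table)
  x <- abundances(tab)
  fm <- fitModel(modelSpec("l2_svm_linear"), x, syn$labels,
                 list(cost = 1), 1)
  twins <- syn$groundTruth$blocks[[1L]]
  # weight really is split across the twins
  expect_true(all(modelWeights(fm)[twins] > 0))

  grouped <- findPerfectGroups(tab)
  singletons <- new("CorrelationGroups", featureIds = featureIds(tab),
                    membership = setNames(seq_len(nFeatures(tab)),
                                          featureIds(tab)))
  impG <- permutationImportance(fm, x, syn$labels, grouped,
                                nPerms = 20L, seed = 3L)
  impS <- permutationImportance(fm, x, syn$labels, singletons,
                                nPerms = 20L, seed = 3L)
  dropJoint <- impG$drop[impG$size == 2L]
  dropTwins <- impS$drop[impS$members %in% twins]
  expect_length(dropJoint, 1L)
  expect_gt(dropJoint, max(dropTwins))
})

test_that("importance aggregation ranks by median drop across splits", {
  s1 <- data.frame(group = 1:2, members = c("a", "b"), size = 1L,
                   base_auc = 0.8, perm_auc = c(0.6, 0.75),
                   drop = c(0.2, 0.05))
  s2 <- data.frame(group = 1:2, members = c("a", "b"), size = 1L,
                   base_auc = 0.82, perm_auc = c(0.52, 0.80),
                   drop = c(0.3, 0.02))
  agg <- aggregateImportance(list(s1, s2))
  expect_equal(agg$members, c("a", "b"))
  expect_equal(agg$median_drop, c(0.25, 0.035))
  expect_equal(agg$rank, 1:2)
})

test_that("top-list overlap counts intersections", {
  expect_equal(compareTopFeatures(letters[1:20], letters[1:20]), 20L)
  expect_equal(compareTopFeatures(letters[1:10], LETTERS[1:10]), 0L)
  expect_equal(compareTopFeatures(c("a", "b", "c"), c("b", "c", "d")), 2L)
})
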