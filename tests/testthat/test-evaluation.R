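test_that("auroc matches hand-computed and degenerate cases", {
  y <- binLabels(c(1, 1, 1, -1))
  expect_equal(auroc(c(0.9, 0.8, 0.6, 0.7), y), 2 / 3)
  expect_equal(auroc(rep(0.5, 4), y), 0.5)
  expect_equal(auroc(c(3, 4, 5, 1), y), 1)
  expect_equal(auroc(c(3, 4, 5, 9), y), 0)
  expect_error(auroc(1:3, binLabels(c(1, 1, 1))), "both classes")
  expect_error(auroc(c(1, NA), binLabels(c(1, -1))), "finite")
})

test_that("auroc equals brute-force pair counting on random instances", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:60, 1)
    scores <- if (i %% 3 == 0) sample(0:5, n, TRUE) else rnorm(n)
    labels <- binLabels(c(1, -1, rnorm(n - 2)))  # both classes guaranteed
    expect_equal(auroc(scores, labels), pairCountAuroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("auroc is antisymmetric and invariant to monotone transforms", {
  set.seed(5)
  for (i in 1:20) {
    scores <- rnorm(30)
    labels <- binLabels(c(1, -1, rnorm(28)))
    a <- auroc(scores, labels)
    expect_equal(auroc(-scores, labels), 1 - a)
    expect_equal(auroc(exp(2 * scores) + 3, labels), a)
    expect_equal(auroc(rank(scores), labels), a)
  }
})

test_that("auroc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  scores <- rnorm(80)
  labels <- binLabels(c(1, -1, rnorm(78)))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<",
                                        levels = c("healthy", "SRN"))))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})

test_that("the benchmark loop is deterministic and well-formed", {
  syn <- signalData(nSamples = 50L, nFeatures = 15L)
  tab <- minmaxNormalize(syn$table)
  run <- function() {
    runBenchmark(tab, syn$labels, models = "l2_logistic", nSplits = 2L,
                 cvRepeats = 1L, grids = tinyGrids(), baseSeed = 4L)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2L)
  expect_equal(r1$split_id, 0:1)
  expect_true(all(r1$cv_auc >= 0 & r1$cv_auc <= 1))
  expect_true(all(r1$test_auc >= 0 & r1$test_auc <= 1))

  expect_error(runBenchmark(syn$table, syn$labels, models = "l2_logistic"),
               "normalized")
  expect_error(runBenchmark(tab, syn$labels, models = "oracle_net"),
               "unknown model")
})

test_that("train-only normalization runs from a counts-stage table", {
  syn <- signalData(nSamples = 50L, nFeatures = 15L)
  r <- runBenchmark(syn$table, syn$labels, models = "l2_logistic",
                    nSplits = 2L, cvRepeats = 1L, grids = tinyGrids(),
                    baseSeed = 1L, normalizeWithinTrain = TRUE)
  expect_equal(nrow(r), 2L)
  expect_true(all(r$test_auc >= 0 & r$test_auc <= 1))
})

test_that("summaries use linear-interpolation quartiles and report gaps", {
  res <- data.frame(split_id = 0:3, model = "m",
                    hyperparams = "cost=1",
                    cv_auc = c(0.7, 0.8, 0.75, 0.85),
                    test_auc = c(1, 2, 3, 4) / 10 + 0.5)
  s <- summarizePerformance(res)
  expect_equal(s$test_q1, 0.5 + 0.175)   # type-7 quartiles of 0.6..0.9
  expect_equal(s$test_q3, 0.5 + 0.325)
  expect_equal(s$range, 0.3)
  expect_equal(s$generalization_gap, median(res$cv_auc) - median(res$test_auc))

  single <- summarizePerformance(res[1, ])
  expect_equal(single$test_median, single$test_min)
  expect_equal(single$test_median, single$test_max)

  three <- summarizePerformance(transform(res[1:3, ],
                                          test_auc = c(0.6, 0.7, 0.8)))
  expect_equal(three$test_median, 0.7)
  expect_equal(three$range, 0.2, tolerance = 1e-12)
  expect_error(summarizePerformance(res[0, ]), "nonempty")
})

test_that("learning curve reduces to the benchmark at full size and widens below", {
  # moderate signal so cvAUC saturates at neither size
  syn <- signalData(nSamples = 60L, nFeatures = 15L, effectSize = 2)
  tab <- minmaxNormalize(syn$table)
  full <- runBenchmark(tab, syn$labels, models = "l2_logistic",
                       nSplits = 5L, cvRepeats = 1L, grids = tinyGrids(),
                       baseSeed = 2L)
  lc <- learningCurve(tab, syn$labels, models = "l2_logistic",
                      sizes = c(20L, 60L), nSplits = 5L, cvRepeats = 1L,
                      grids = tinyGrids(), baseSeed = 2L)
  expect_equal(lc$cv_auc[lc$size == 60L], full$cv_auc)
  iqr <- function(v) diff(quantile(v, c(0.25, 0.75), type = 7))
  expect_gte(iqr(lc$cv_auc[lc$size == 20L]),
             iqr(lc$cv_auc[lc$size == 60L]))
  # subsample class balance preserved up to ceiling rounding
  expect_error(learningCurve(tab, syn$labels, sizes = 5L, k = 5L),
               "at least 2\\*k")
})
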