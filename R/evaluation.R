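# AUROC, the repeated-split benchmark loop, performance summaries and the
# sample-size (learning-curve) analysis.

#' Rank-based AUROC
#'
#' The Mann-Whitney form: the probability that a uniformly chosen positive
#' sample scores above a uniformly chosen negative one, with ties counting
#' one half.  0.5 is chance, 1 is perfect separation, 0 perfectly inverted.
#'
#' @param scores finite numeric scores, higher = more positive-like.
#' @param labels two-level factor (or logical, `TRUE` = positive), same
#'   length as `scores`; second factor level = positive class.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.8, 0.6, 0.7), factor(c("SRN", "SRN", "SRN", "healthy"),
#'       levels = c("healthy", "SRN")))
#' @export
auroc <- function(scores, labels) {
  if (is.logical(labels)) {
    labels <- factor(labels, levels = c(FALSE, TRUE))
  }
  labels <- checkLabels(labels)
  stopIfNot(length(scores) == length(labels),
            "scores and labels must have equal length")
  stopIfNot(all(is.finite(scores)), "scores must be finite")
  pos <- labels == positiveLevel(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC undefined: both classes must be present")
  }
  r <- rank(scores)  # midranks handle ties as 1/2 wins
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the full repeated-split benchmark
#'
#' For each of `nSplits` data splits and each requested model family:
#' stratified 80/20 holdout -> repeated stratified k-fold grid search
#' ([gridSearch()]) -> final fit on the training set -> AUROC on the
#' held-out test set.  Split `s` uses seed `baseSeed + s`, so each split is
#' independently reproducible and the loop is embarrassingly parallel in
#' principle (no state is shared between splits).
#'
#' @param x an [OtuTable-class].  At the default
#'   `normalizeWithinTrain = FALSE` it must already be stage `"normalized"`
#'   (the study normalized the full table once before splitting); with
#'   `normalizeWithinTrain = TRUE` pass a counts/rarefied table and min-max
#'   statistics are computed on each split's training rows only and applied
#'   (clipped) to its test rows.
#' @param labels two-level factor named by sample id.
#' @param models character vector of model names (see [listModels()]).
#' @param nSplits number of random data splits.
#' @param trainFraction per-class training fraction.
#' @param k,cvRepeats cross-validation folds and repeats.
#' @param grids optional named list overriding [defaultGrid()] per model.
#' @param baseSeed integer; split `s` runs under seed `baseSeed + s`.
#' @param normalizeWithinTrain compute min-max statistics on training rows
#'   only (leakage-free variant) instead of using the table as given.
#' @param keepModels also return fitted models and test ids per
#'   (split, model) for the interpretation stage.
#' @return If `keepModels = FALSE` (default) a data.frame with one row per
#'   (split, model): `split_id`, `model`, `hyperparams`, `cv_auc`,
#'   `test_auc`.  Otherwise a list with elements `results` (that
#'   data.frame), `models` (nested list `[[model]][[split]]` of
#'   [FittedModel-class]) and `splits` (list of holdout index lists).
#' @export
runBenchmark <- function(x, labels, models = listModels(), nSplits = 100L,
                         trainFraction = 0.8, k = 5L, cvRepeats = 10L,
                         grids = NULL, baseSeed = 0L,
                         normalizeWithinTrain = FALSE,
                         keepModels = FALSE) {
  stopIfNot(is(x, "OtuTable"), "x must be an OtuTable")
  if (!normalizeWithinTrain && tableStage(x) != "normalized") {
    stop("x must be min-max normalized (see minmaxNormalize()), or set ",
         "normalizeWithinTrain = TRUE for counts/rarefied input")
  }
  labels <- checkLabels(labels, sampleIds(x))
  stopIfNot(length(labels) == nSamples(x),
            "labels must cover every sample")
  unknown <- setdiff(models, listModels())
  stopIfNot(length(unknown) == 0L,
            "unknown model(s): ", paste(unknown, collapse = ", "))
  specs <- lapply(models, function(nm) {
    if (!is.null(grids[[nm]])) modelSpec(nm, grids[[nm]]) else modelSpec(nm)
  })
  names(specs) <- models

  raw <- abundances(x)
  rows <- vector("list", nSplits * length(models))
  fitted <- if (keepModels) {
    setNames(rep(list(vector("list", nSplits)), length(models)), models)
  }
  splits <- vector("list", nSplits)

  for (s in seq_len(nSplits)) {
    seed <- as.integer(baseSeed) + s - 1L
    split <- stratifiedHoldout(labels, trainFraction, seed = seed)
    splits[[s]] <- split
    if (normalizeWithinTrain) {
      pars <- minmaxParams(raw[split$train, , drop = FALSE])
      xs <- abundances(minmaxNormalize(x, params = pars))
    } else {
      xs <- raw
    }
    xTrain <- xs[split$train, , drop = FALSE]
    yTrain <- labels[split$train]
    scheme <- stratifiedKfold(yTrain, k = k, repeats = cvRepeats,
                              seed = seed)
    for (mi in seq_along(models)) {
      spec <- specs[[mi]]
      tuning <- gridSearch(spec, xTrain, yTrain, scheme, seed = seed)
      final <- finalizeModel(spec, tuning$best, xTrain, yTrain, seed = seed)
      testScores <- decisionScores(final, xs[split$test, , drop = FALSE])
      testAuc <- auroc(testScores, labels[split$test])
      rows[[(s - 1L) * length(models) + mi]] <- data.frame(
        split_id = s - 1L,
        model = spec$name,
        hyperparams = formatHyperparams(tuning$best),
        cv_auc = tuning$bestCvAuc,
        test_auc = testAuc,
        stringsAsFactors = FALSE
      )
      if (keepModels) fitted[[spec$name]][[s]] <- final
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  if (keepModels) {
    list(results = results, models = fitted, splits = splits,
         labels = labels, normalizeWithinTrain = normalizeWithinTrain)
  } else {
    results
  }
}

#' Summarize per-model AUROC distributions across splits
#'
#' Quartiles use the linear-interpolation convention (R's default type 7)
#' so IQRs are reproducible.  The generalization gap is median cvAUC minus
#' median test AUROC: a small gap indicates the models are not overfit to
#' their training sets.
#'
#' @param results benchmark data.frame from [runBenchmark()].
#' @return data.frame, one row per model: n_splits, median/q1/q3/min/max of
#'   test and cv AUROC, `range` (max - min of test AUROC) and
#'   `generalization_gap`.
#' @export
summarizePerformance <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- results$results
  }
  stopIfNot(is.data.frame(results) && nrow(results) > 0L,
            "results must be a nonempty benchmark table")
  stats <- lapply(split(results, results$model), function(d) {
    qT <- quantile(d$test_auc, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    qC <- quantile(d$cv_auc, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(
      model = d$model[1L], n_splits = nrow(d),
      test_median = qT[2L], test_q1 = qT[1L], test_q3 = qT[3L],
      test_min = min(d$test_auc), test_max = max(d$test_auc),
      range = max(d$test_auc) - min(d$test_auc),
      cv_median = qC[2L], cv_q1 = qC[1L], cv_q3 = qC[3L],
      cv_min = min(d$cv_auc), cv_max = max(d$cv_auc),
      generalization_gap = qC[2L] - qT[2L],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, stats)
  rownames(out) <- NULL
  out
}

#' Cross-validation performance as a function of sample size
#'
#' For each requested size, each split draws a stratified subsample of that
#' size (class ratio preserved up to ceiling rounding) and runs the standard
#' per-split pipeline on it; the spread of cvAUC across splits shows how
#' sample size limits model stability.
#'
#' @param x normalized [OtuTable-class].
#' @param labels two-level factor named by sample id.
#' @param models character vector of model names.
#' @param sizes integer subsample sizes; each must be at least `2 * k` and
#'   at most `nSamples(x)`.
#' @param ... further arguments passed to [runBenchmark()] (`nSplits`, `k`,
#'   `cvRepeats`, `grids`, `baseSeed`, ...).
#' @return data.frame: one row per (size, split, model) with `cv_auc` and
#'   `test_auc`.
#' @export
learningCurve <- function(x, labels, models = c("l2_logistic",
                                                "random_forest"),
                          sizes, k = 5L, baseSeed = 0L, ...) {
  labels <- checkLabels(labels, sampleIds(x))
  stopIfNot(all(sizes >= 2 * k), "each size must be at least 2*k")
  stopIfNot(all(sizes <= nSamples(x)), "size exceeds the number of samples")
  out <- lapply(sizes, function(sz) {
    if (sz == nSamples(x)) {
      sub <- sampleIds(x)
    } else {
      frac <- sz / nSamples(x)
      perClass <- lapply(levels(labels), function(cl) {
        members <- names(labels)[labels == cl]
        withSeed(baseSeed + sz, sample(members,
                                       min(length(members),
                                           ceiling(frac * length(members)))))
      })
      sub <- head(unlist(perClass), sz)
    }
    xSub <- OtuTable(abundances(x)[sub, , drop = FALSE],
                     stage = tableStage(x))
    res <- runBenchmark(xSub, labels[sub], models = models, k = k,
                        baseSeed = baseSeed, ...)
    data.frame(size = sz, res, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
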