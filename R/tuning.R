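# Grid-search hyperparameter selection by mean cross-validation AUROC.

#' Grid search over a model's hyperparameter settings
#'
#' Every grid setting is fitted on each (repeat, fold) training portion and
#' scored on the corresponding held-out fold; the unweighted mean AUROC over
#' all k x repeats folds is the setting's cvAUC.  The chosen setting is the
#' argmax; exact ties go to the more regularized setting (smaller cost,
#' narrower kernel, shallower tree, fewer features per split, smaller
#' learning rate), i.e. the earliest row of the canonically ordered grid.
#'
#' @param spec a `ModelSpec`.
#' @param x samples-by-features normalized matrix or [OtuTable-class]
#'   containing exactly the training samples.
#' @param labels two-level factor named by sample id (training samples).
#' @param scheme a `CvScheme` from [stratifiedKfold()] built on the same
#'   samples.
#' @param seed integer seed forwarded to stochastic learners.
#' @return A `TuningResult`: list with `settings` (data.frame of
#'   hyperparameters plus `mean_cvauc`), `foldAucs` (settings x folds
#'   matrix), `best` (named list of chosen hyperparameters) and `bestCvAuc`.
#' @export
gridSearch <- function(spec, x, labels, scheme, seed = 1L) {
  if (is(x, "OtuTable")) x <- abundances(x)
  labels <- checkLabels(labels, rownames(x))
  stopIfNot(setequal(rownames(x), scheme$sampleIds),
            "CV scheme was not built on these training samples")
  settings <- gridSettings(spec)
  nFolds <- scheme$k * scheme$repeats
  foldAucs <- matrix(NA_real_, nrow(settings), nFolds)

  for (s in seq_len(nrow(settings))) {
    hp <- as.list(settings[s, , drop = FALSE])
    col <- 0L
    for (r in seq_len(scheme$repeats)) {
      assignment <- scheme$folds[[r]]
      for (f in seq_len(scheme$k)) {
        col <- col + 1L
        inIds <- names(assignment)[assignment != f]
        outIds <- names(assignment)[assignment == f]
        m <- fitModel(spec, x[inIds, , drop = FALSE], labels[inIds],
                      hp, seed = seed)
        sc <- decisionScores(m, x[outIds, , drop = FALSE])
        foldAucs[s, col] <- auroc(sc, labels[outIds])
      }
    }
  }
  meanCv <- rowMeans(foldAucs)
  bestIdx <- which.max(meanCv)  # first max = most regularized on ties
  out <- list(
    model = spec$name,
    settings = cbind(settings, mean_cvauc = meanCv),
    foldAucs = foldAucs,
    best = as.list(settings[bestIdx, , drop = FALSE]),
    bestCvAuc = meanCv[bestIdx]
  )
  class(out) <- "TuningResult"
  out
}

#' @export
print.TuningResult <- function(x, ...) {
  cat(sprintf("TuningResult: %s, %d setting(s); best cvAUC %.3f at %s\n",
              x$model, nrow(x$settings), x$bestCvAuc,
              formatHyperparams(x$best)))
  invisible(x)
}

#' Refit the chosen setting on the full training set
#'
#' @param spec a `ModelSpec`.
#' @param hyperparams the chosen setting (e.g. `tuning$best`).
#' @param x,labels full training data (the same samples the grid search
#'   saw).
#' @param seed integer seed; use the split seed so the fit is re-derivable.
#' @return A [FittedModel-class].
#' @export
finalizeModel <- function(spec, hyperparams, x, labels, seed = 1L) {
  fitModel(spec, x, labels, hyperparams, seed = seed)
}

#' Export a tuning result as a long table
#'
#' @param tuning a `TuningResult`.
#' @return data.frame with one row per setting: model, hyperparameters,
#'   mean cvAUC.
#' @export
tuningTable <- function(tuning) {
  data.frame(model = tuning$model, tuning$settings, row.names = NULL)
}
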