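# The seven classifier families: registry, default grids, uniform
# fit/score contract.  Every family exposes a continuous decision score
# (never a hard 0/1 label) so AUROC is always well defined; the positive
# class is the second factor level (SRN) everywhere.

.modelRegistry <- list(
  l2_logistic   = list(linearity = "linear",
                       label = "L2-regularized logistic regression"),
  l1_svm_linear = list(linearity = "linear",
                       label = "L1-regularized linear SVM"),
  l2_svm_linear = list(linearity = "linear",
                       label = "L2-regularized linear SVM"),
  svm_rbf       = list(linearity = "nonlinear",
                       label = "SVM with RBF kernel"),
  decision_tree = list(linearity = "nonlinear", label = "Decision tree"),
  random_forest = list(linearity = "nonlinear", label = "Random forest"),
  xgboost       = list(linearity = "nonlinear",
                       label = "Gradient boosted trees (XGBoost)")
)

#' Names of the seven supported classifier families
#'
#' Three linear families (L2 logistic regression, L1- and L2-regularized
#' linear SVMs) and four nonlinear ones (RBF SVM, decision tree, random
#' forest, XGBoost).
#'
#' @return character vector of model names.
#' @export
listModels <- function() names(.modelRegistry)

#' Default hyperparameter grid for a model family
#'
#' Grids are ordered from most to least regularized in every dimension (the
#' deterministic tie-break in [gridSearch()] prefers earlier, i.e. more
#' regularized, settings).  Regularized families tune `cost` over a
#' log-spaced ladder 1e-4..1e2 (smaller cost = stronger regularization); the
#' RBF SVM additionally tunes the kernel width `sigma` of
#' `exp(-sigma * ||u - v||^2)`; the decision tree tunes `maxdepth` 1..8; the
#' random forest tunes the features considered per split via `mtryFactor`
#' (mtry = round(mtryFactor * sqrt(p))); XGBoost tunes learning rate `eta`
#' and row-subsampling fraction `subsample`.  All grids can be overridden
#' per run.
#'
#' @param name a model name from [listModels()].
#' @return named list of ordered candidate-value vectors.
#' @examples
#' defaultGrid("l1_svm_linear")
#' @export
defaultGrid <- function(name) {
  costLadder <- 10^seq(-4, 2)
  switch(name,
    l2_logistic   = list(cost = costLadder),
    l1_svm_linear = list(cost = costLadder),
    l2_svm_linear = list(cost = costLadder),
    svm_rbf       = list(cost = 10^seq(-2, 2),
                         sigma = 10^seq(-4, 0)),
    decision_tree = list(maxdepth = 1:8),
    random_forest = list(mtryFactor = c(0.5, 1, 2)),
    xgboost       = list(eta = c(0.01, 0.1, 0.3),
                         subsample = c(0.5, 0.75, 1)),
    stop("unknown model name: '", name, "'")
  )
}

#' Describe a classifier family
#'
#' @param name a model name from [listModels()].
#' @param grid optional hyperparameter grid overriding [defaultGrid()].
#' @return A `ModelSpec`: list with `name`, `linearity`, `label`, `grid`.
#' @export
modelSpec <- function(name, grid = defaultGrid(name)) {
  if (!name %in% names(.modelRegistry)) {
    stop("unknown model name: '", name, "'")
  }
  stopIfNot(length(grid) > 0L && all(lengths(grid) > 0L),
            "hyperparameter grid must be nonempty")
  entry <- .modelRegistry[[name]]
  structure(list(name = name, linearity = entry$linearity,
                 label = entry$label, grid = grid),
            class = "ModelSpec")
}

#' @export
print.ModelSpec <- function(x, ...) {
  cat(sprintf("ModelSpec: %s [%s]\n", x$label, x$linearity))
  for (h in names(x$grid)) {
    cat(sprintf("  %s: %s\n", h, paste(x$grid[[h]], collapse = ", ")))
  }
  invisible(x)
}

# Hyperparameter settings in tie-break order: rows ordered lexicographically
# by the grid's (most->least regularized) value order.
gridSettings <- function(spec) {
  g <- rev(spec$grid)  # expand.grid varies the first factor fastest
  df <- expand.grid(g, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, rev(names(df)), drop = FALSE]
  df[do.call(order, df), , drop = FALSE]
}

# e1071 reports decision values in a column named "A/B": positive values
# favour class A.  Return +1 if positive decision values favour the
# positive class, else -1.
.e1071Orientation <- function(decisionColname, positive) {
  first <- strsplit(decisionColname, "/", fixed = TRUE)[[1L]][1L]
  if (identical(first, positive)) 1 else -1
}

#' Fit one classifier family at fixed hyperparameters
#'
#' @param spec a `ModelSpec` from [modelSpec()].
#' @param x samples-by-features numeric matrix (normalized abundances) or an
#'   [OtuTable-class].
#' @param labels two-level factor, one entry per row of `x`; second level =
#'   positive class.
#' @param hyperparams named list, one value per grid dimension of `spec`.
#' @param seed integer seed for stochastic learners (random forest,
#'   XGBoost); recorded for all families.
#' @return A [FittedModel-class].
#' @export
fitModel <- function(spec, x, labels, hyperparams, seed = 1L) {
  if (is(x, "OtuTable")) x <- abundances(x)
  labels <- checkLabels(labels, rownames(x))
  stopIfNot(length(labels) == nrow(x),
            "labels must have one entry per sample")
  if (length(unique(labels)) < 2L) {
    stop("cannot train on a single-class training set")
  }
  missingHp <- setdiff(names(spec$grid), names(hyperparams))
  stopIfNot(length(missingHp) == 0L,
            "missing hyperparameter(s): ", paste(missingHp, collapse = ", "))
  pos <- positiveLevel(labels)
  p <- ncol(x)
  weights <- numeric(0)

  fit <- switch(spec$name,
    l2_logistic = {
      # glmnet ridge logistic; cost C maps to lambda = 1/(n*C) so the
      # penalized objective matches the LiblineaR-style C parameterization
      xg <- if (p < 2L) cbind(x, .pad = 0) else x
      # glmnet warns about small per-class counts in tiny CV folds; the
      # fit is still well defined there
      f <- withCallingHandlers(
        glmnet::glmnet(xg, labels, family = "binomial", alpha = 0,
                       lambda = 1 / (nrow(x) * hyperparams$cost),
                       standardize = FALSE),
        warning = function(w) {
          if (grepl("fewer than 8", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      weights <- drop(coef(f))[-1L][seq_len(p)]
      f
    },
    l1_svm_linear = {
      f <- fitLinearSvm(x, signedResponse(labels), cost = hyperparams$cost,
                        penalty = "l1")
      weights <- f$w
      f
    },
    l2_svm_linear = {
      f <- fitLinearSvm(x, signedResponse(labels), cost = hyperparams$cost,
                        penalty = "l2")
      weights <- f$w
      f
    },
    svm_rbf = {
      f <- e1071::svm(x, labels, kernel = "radial",
                      gamma = hyperparams$sigma, cost = hyperparams$cost,
                      scale = FALSE)
      dv <- attr(predict(f, x[1:2, , drop = FALSE],
                         decision.values = TRUE), "decision.values")
      attr(f, "orientation") <- .e1071Orientation(colnames(dv)[1L], pos)
      f
    },
    decision_tree = {
      df <- data.frame(.class = labels, x, check.names = FALSE)
      rpart::rpart(.class ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = hyperparams$maxdepth, cp = 0,
                     minsplit = 10L, xval = 0L))
    },
    random_forest = {
      mtry <- max(1L, min(p, round(hyperparams$mtryFactor * sqrt(p))))
      ranger::ranger(x = x, y = labels, probability = TRUE,
                     num.trees = 500L, mtry = mtry,
                     seed = as.integer(seed), num.threads = 1L)
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(labels) - 1L)
      withSeed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = hyperparams$eta,
                      subsample = hyperparams$subsample,
                      max_depth = 6L, nthread = 1L),
        data = dtrain, nrounds = 100L, verbose = 0L))
    },
    stop("unknown model name: '", spec$name, "'")
  )

  new("FittedModel", modelName = spec$name,
      hyperparams = as.list(hyperparams), fit = fit,
      featureIds = colnames(x), classLevels = levels(labels),
      weights = as.numeric(weights), seed = as.integer(seed))
}

#' Continuous decision scores for new samples
#'
#' Returns one finite real per sample, oriented so that higher scores mean
#' more likely positive class (SRN).  AUROC computed from these scores is
#' invariant to any strictly increasing rescaling, so probability outputs
#' (trees, forests, XGBoost) and margin outputs (SVMs, logistic link) are
#' interchangeable.
#'
#' @param model a [FittedModel-class].
#' @param x samples-by-features matrix or [OtuTable-class]; feature ids must
#'   match the training features.
#' @return named numeric vector of scores.
#' @export
decisionScores <- function(model, x) {
  if (is(x, "OtuTable")) x <- abundances(x)
  if (!identical(colnames(x), model@featureIds)) {
    if (is.null(colnames(x)) || !setequal(colnames(x), model@featureIds)) {
      stop("feature ids of the new data do not match the training features")
    }
    x <- x[, model@featureIds, drop = FALSE]
  }
  pos <- model@classLevels[2L]
  scores <- switch(model@modelName,
    l2_logistic = {
      xg <- if (ncol(x) < 2L) cbind(x, .pad = 0) else x
      drop(predict(model@fit, xg, type = "link"))
    },
    l1_svm_linear = ,
    l2_svm_linear = predictLinearSvm(model@fit, x),
    svm_rbf = {
      dv <- attr(predict(model@fit, x, decision.values = TRUE),
                 "decision.values")
      attr(model@fit, "orientation") * dv[, 1L]
    },
    decision_tree = {
      df <- data.frame(x, check.names = FALSE)
      predict(model@fit, df, type = "prob")[, pos]
    },
    random_forest = {
      predict(model@fit, data = x, num.threads = 1L,
              verbose = FALSE)$predictions[, pos]
    },
    xgboost = {
      predict(model@fit, xgboost::xgb.DMatrix(x))
    },
    stop("unknown model name: '", model@modelName, "'")
  )
  scores <- as.numeric(scores)
  names(scores) <- rownames(x)
  stopIfNot(all(is.finite(scores)), "non-finite decision score produced")
  scores
}
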