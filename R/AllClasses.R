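#' OtuTable: a samples-by-OTU abundance table
#'
#' `OtuTable` extends [SummarizedExperiment::SummarizedExperiment] and holds
#' one abundance assay with OTUs as rows and samples as columns (the usual
#' Bioconductor orientation; [abundances()] returns the transposed
#' samples-by-features matrix the learning code consumes).  The `stage` slot
#' records where the table sits in the preprocessing chain: raw `"counts"`,
#' `"rarefied"` (every sample subsampled to a common read depth) or
#' `"normalized"` (each OTU min-max scaled to \[0, 1\]).
#'
#' @slot stage character(1), one of `"counts"`, `"rarefied"`, `"normalized"`.
#'
#' @seealso [readShared()], [rarefy()], [minmaxNormalize()],
#'   [generateSyntheticOtus()]
#' @export
setClass("OtuTable",
  contains = "SummarizedExperiment",
  slots = c(stage = "character")
)

.validOtuTable <- function(object) {
  msg <- NULL
  m <- SummarizedExperiment::assay(object)
  if (!object@stage %in% c("counts", "rarefied", "normalized")) {
    msg <- c(msg, "stage must be one of counts, rarefied, normalized")
  }
  if (any(!is.finite(m))) {
    msg <- c(msg, "abundances must be finite")
  } else if (any(m < 0)) {
    msg <- c(msg, "abundances must be non-negative")
  }
  if (anyDuplicated(colnames(m))) msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(rownames(m))) msg <- c(msg, "OTU ids must be unique")
  if (identical(object@stage, "normalized") && length(m) && max(m) > 1 + 1e-9) {
    msg <- c(msg, "normalized abundances must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
}

setValidity("OtuTable", .validOtuTable)

#' Construct an OtuTable from a samples-by-OTU matrix
#'
#' @param values numeric matrix, samples in rows, OTUs in columns, with
#'   rownames (sample ids) and colnames (OTU ids).
#' @param stage preprocessing stage of the values; see [OtuTable-class].
#'
#' @return An [OtuTable-class] object.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("Otu", 1:4)))
#' OtuTable(m)
#' @export
OtuTable <- function(values, stage = c("counts", "rarefied", "normalized")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry sample ids (rownames) and OTU ids (colnames)")
  }
  if (!is.numeric(values)) stop("abundances must be numeric")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = t(values))
  )
  new("OtuTable", se, stage = stage)
}

#' @describeIn OtuTable-class number of samples
#' @param x,object an `OtuTable`
#' @export
nSamples <- function(x) ncol(SummarizedExperiment::assay(x))

#' @describeIn OtuTable-class number of OTU features
#' @export
nFeatures <- function(x) nrow(SummarizedExperiment::assay(x))

#' @describeIn OtuTable-class sample identifiers
#' @export
sampleIds <- function(x) colnames(SummarizedExperiment::assay(x))

#' @describeIn OtuTable-class OTU identifiers
#' @export
featureIds <- function(x) rownames(SummarizedExperiment::assay(x))

#' Extract the abundance matrix in machine-learning orientation
#'
#' @param x an [OtuTable-class]
#' @return numeric matrix, samples in rows, OTUs in columns.
#' @export
abundances <- function(x) t(SummarizedExperiment::assay(x))

#' @describeIn OtuTable-class preprocessing stage
#' @export
tableStage <- function(x) x@stage

setMethod("show", "OtuTable", function(object) {
  cat(sprintf("OtuTable: %d samples x %d OTUs (stage: %s)\n",
              nSamples(object), nFeatures(object), object@stage))
  m <- SummarizedExperiment::assay(object)
  if (length(m)) {
    cat(sprintf("  sparsity: %.1f%% zeros; abundance range [%g, %g]\n",
                100 * mean(m == 0), min(m), max(m)))
  }
})

#' CorrelationGroups: a partition of OTUs into jointly-permuted groups
#'
#' Groups collect OTUs whose pairwise Spearman rank correlation is perfect
#' (rho = 1 up to a numeric tolerance, with p below a significance cutoff);
#' every other OTU sits in a singleton group.  The partition drives grouped
#' permutation importance: all members of a group are permuted together.
#'
#' @slot featureIds character, all feature ids in table order.
#' @slot membership integer group id per feature, named by feature id.
#'
#' @seealso [findPerfectGroups()], [permutationImportance()]
#' @export
setClass("CorrelationGroups",
  slots = c(featureIds = "character", membership = "integer")
)

setValidity("CorrelationGroups", function(object) {
  msg <- NULL
  if (length(object@membership) != length(object@featureIds)) {
    msg <- c(msg, "membership must assign every feature to a group")
  }
  if (!identical(names(object@membership), object@featureIds)) {
    msg <- c(msg, "membership names must equal featureIds")
  }
  if (length(object@membership) && anyNA(object@membership)) {
    msg <- c(msg, "membership must not contain NA")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn CorrelationGroups-class number of groups in the partition
#' @param x,object a `CorrelationGroups`
#' @export
nGroups <- function(x) length(unique(x@membership))

#' @describeIn CorrelationGroups-class list of member feature-id vectors,
#'   one element per group
#' @export
groupMembers <- function(x) {
  split(x@featureIds, x@membership)
}

#' @describeIn CorrelationGroups-class integer group sizes
#' @export
groupSizes <- function(x) {
  lengths(groupMembers(x))
}

setMethod("show", "CorrelationGroups", function(object) {
  sz <- groupSizes(object)
  cat(sprintf(
    "CorrelationGroups: %d features in %d groups (%d multi-feature)\n",
    length(object@featureIds), length(sz), sum(sz > 1L)))
  if (any(sz > 1L)) {
    cat("  multi-feature group sizes:",
        paste(sort(sz[sz > 1L], decreasing = TRUE), collapse = ", "), "\n")
  }
})

#' FittedModel: a trained classifier with its provenance
#'
#' Wraps the fitted state of one classifier family together with the
#' hyperparameters it was trained with, the feature universe it expects, the
#' class levels (second level = positive/SRN class) and, for linear
#' families, the signed feature-weight vector.
#'
#' @slot modelName character(1), one of [listModels()].
#' @slot hyperparams named list of hyperparameter values.
#' @slot fit the underlying fitted object (glmnet/e1071/rpart/ranger/xgboost
#'   or the internal linear-SVM solver state).
#' @slot featureIds character, training feature ids in order.
#' @slot classLevels character(2), negative then positive class.
#' @slot weights numeric, signed feature weights for linear families
#'   (length 0 otherwise).
#' @slot seed integer seed the fit was performed under.
#'
#' @seealso [fitModel()], [decisionScores()], [modelWeights()]
#' @export
setClass("FittedModel",
  slots = c(
    modelName = "character",
    hyperparams = "list",
    fit = "ANY",
    featureIds = "character",
    classLevels = "character",
    weights = "numeric",
    seed = "integer"
  )
)

setValidity("FittedModel", function(object) {
  msg <- NULL
  if (length(object@classLevels) != 2L) {
    msg <- c(msg, "classLevels must have length 2")
  }
  if (length(object@weights) &&
      length(object@weights) != length(object@featureIds)) {
    msg <- c(msg, "weights must have one entry per feature")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel: %s (%s)\n", object@modelName,
              formatHyperparams(object@hyperparams)))
  cat(sprintf("  %d features; positive class: %s\n",
              length(object@featureIds), object@classLevels[2L]))
  if (length(object@weights)) {
    cat(sprintf("  linear weights: %d nonzero of %d\n",
                sum(object@weights != 0), length(object@weights)))
  }
})

#' @describeIn FittedModel-class signed feature weights of a linear model
#'   (named numeric); errors for nonlinear families
#' @param model a `FittedModel`
#' @export
modelWeights <- function(model) {
  if (!length(model@weights)) {
    stop("model '", model@modelName,
         "' is not linear: no feature weight vector is defined")
  }
  setNames(model@weights, model@featureIds)
}
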