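# Shared fixtures, built in code at test time.

# Tiny mothur shared file on disk; returns the path.
writeToyShared <- function(counts = NULL, numOtus = NULL,
                           path = tempfile(fileext = ".shared")) {
  if (is.null(counts)) {
    counts <- matrix(c(5, 0, 3, 2,
                       0, 0, 0, 0,
                       1, 4, 2, 9), 3, 4, byrow = TRUE,
                     dimnames = list(c("sampleA", "sampleB", "sampleC"),
                                     paste0("Otu000", 1:4)))
  }
  if (is.null(numOtus)) numOtus <- ncol(counts)
  df <- data.frame(label = "0.03", Group = rownames(counts),
                   numOtus = numOtus, counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Small labeled table with a clear class signal, used across modules.
signalData <- function(nSamples = 60L, nFeatures = 30L, nInformative = 4L,
                       effectSize = 8, seed = 11L, ...) {
  generateSyntheticOtus(nSamples = nSamples, nFeatures = nFeatures,
                        nInformative = nInformative,
                        effectSize = effectSize, caseFraction = 0.5,
                        blockSizes = integer(0), sparsity = 0.2,
                        depthMean = 2000L, seed = seed, ...)
}

# Fast single-point grids so model fits stay cheap in unit tests.
tinyGrids <- function() {
  list(
    l2_logistic   = list(cost = 1),
    l1_svm_linear = list(cost = 1),
    l2_svm_linear = list(cost = 1),
    svm_rbf       = list(cost = 1, sigma = 0.01),
    decision_tree = list(maxdepth = 3L),
    random_forest = list(mtryFactor = 1),
    xgboost       = list(eta = 0.3, subsample = 1)
  )
}

# Brute-force AUROC by counting case-control pairs (independent oracle).
pairCountAuroc <- function(scores, labels) {
  pos <- scores[labels == levels(labels)[2L]]
  neg <- scores[labels == levels(labels)[1L]]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

binLabels <- function(x) factor(ifelse(x > 0, "SRN", "healthy"),
                                levels = c("healthy", "SRN"))
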