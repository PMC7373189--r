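# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# The caller's RNG state is untouched.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr, .rng_kind = "Mersenne-Twister")
}

# Validate a label factor against a sample-id universe.  Labels must be a
# two-level factor named by sample id; the SECOND level is the positive
# (case) class everywhere in the package.
checkLabels <- function(labels, sampleIds = NULL) {
  if (!is.factor(labels)) {
    labels <- factor(labels)
  }
  if (nlevels(labels) != 2L) {
    stop("labels must have exactly two classes, got ", nlevels(labels),
         call. = FALSE)
  }
  if (is.null(names(labels))) {
    if (!is.null(sampleIds)) {
      if (length(labels) != length(sampleIds)) {
        stop("labels length does not match number of samples", call. = FALSE)
      }
      names(labels) <- sampleIds
    }
  } else if (!is.null(sampleIds)) {
    missing <- setdiff(names(labels), sampleIds)
    if (length(missing) > 0L) {
      stop("labels contain sample ids absent from the table: ",
           paste(head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    labels <- labels[intersect(sampleIds, names(labels))]
  }
  labels
}

positiveLevel <- function(labels) levels(labels)[2L]

# y in {-1, +1} with +1 = positive (second) level
signedResponse <- function(labels) {
  ifelse(as.integer(labels) == 2L, 1, -1)
}

# Collapse a named hyperparameter list to a stable "a=1, b=2" string.
formatHyperparams <- function(hp) {
  paste(sprintf("%s=%s", names(hp), vapply(hp, format, character(1L))),
        collapse = ", ")
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}
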