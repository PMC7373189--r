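# Stratified holdout splits and repeated stratified k-fold CV schemes.

#' Stratified train/test holdout split
#'
#' Per class, `ceiling(trainFraction * n_c)` members are assigned to the
#' training set uniformly at random; the rest form the held-out test set.
#' Ceiling rounding reproduces the study's printed allocation: 261 healthy +
#' 229 SRN at 0.8 gives a 393-sample training set with 184 SRN and a
#' 97-sample test set with 45 SRN.
#'
#' @param labels two-level factor named by sample id (see
#'   [assignSrnLabels()]).
#' @param trainFraction fraction of each class assigned to training.
#' @param seed integer RNG seed.
#' @return list with character vectors `train` and `test` (sample ids, in
#'   original label order) plus the `seed` used.
#' @export
stratifiedHoldout <- function(labels, trainFraction = 0.8, seed = 1L) {
  labels <- checkLabels(labels)
  stopIfNot(!is.null(names(labels)), "labels must be named by sample id")
  stopIfNot(trainFraction > 0 && trainFraction < 1,
            "trainFraction must lie strictly in (0, 1)")
  classCounts <- table(labels)
  if (any(classCounts < 2L)) {
    stop("cannot stratify: class '",
         names(classCounts)[which.min(classCounts)],
         "' has fewer than 2 members")
  }
  ids <- names(labels)
  trainIds <- withSeed(seed, {
    unlist(lapply(levels(labels), function(cl) {
      members <- ids[labels == cl]
      nTrain <- ceiling(trainFraction * length(members))
      sample(members, nTrain)
    }), use.names = FALSE)
  })
  list(train = ids[ids %in% trainIds],
       test = ids[!ids %in% trainIds],
       seed = as.integer(seed))
}

#' Repeated stratified k-fold cross-validation scheme
#'
#' For each repeat, every class is shuffled and dealt round-robin into `k`
#' folds, so per-fold class counts differ by at most one from perfect
#' stratification and every fold contains both classes whenever each class
#' has at least `k` members.
#'
#' @param labels two-level factor named by sample id, restricted to the
#'   training samples.
#' @param k number of folds.
#' @param repeats number of independent repetitions.
#' @param seed integer RNG seed.
#' @return A `CvScheme`: list with `k`, `repeats`, `sampleIds` and `folds`,
#'   a list of `repeats` integer vectors assigning each sample to a fold in
#'   `1..k`.
#' @export
stratifiedKfold <- function(labels, k = 5L, repeats = 1L, seed = 1L) {
  labels <- checkLabels(labels)
  stopIfNot(!is.null(names(labels)), "labels must be named by sample id")
  stopIfNot(k >= 2L, "k must be at least 2")
  stopIfNot(repeats >= 1L, "repeats must be at least 1")
  classCounts <- table(labels)
  if (any(classCounts < k)) {
    stop("cannot build ", k, "-fold stratified CV: class '",
         names(classCounts)[which.min(classCounts)], "' has only ",
         min(classCounts), " members")
  }
  ids <- names(labels)
  folds <- withSeed(seed, {
    lapply(seq_len(repeats), function(r) {
      assignment <- integer(length(ids))
      names(assignment) <- ids
      for (cl in levels(labels)) {
        members <- which(labels == cl)
        assignment[members[sample.int(length(members))]] <-
          rep_len(seq_len(k), length(members))
      }
      assignment
    })
  })
  structure(
    list(k = as.integer(k), repeats = as.integer(repeats),
         sampleIds = ids, folds = folds, seed = as.integer(seed)),
    class = "CvScheme"
  )
}

#' @export
print.CvScheme <- function(x, ...) {
  cat(sprintf("CvScheme: %d-fold x %d repeat(s) over %d samples\n",
              x$k, x$repeats, length(x$sampleIds)))
  invisible(x)
}

#' Export split assignments as a long table
#'
#' @param split result of [stratifiedHoldout()].
#' @param splitId integer identifier recorded in the output.
#' @return data.frame with columns `split_id`, `sample_id`, `role`.
#' @export
splitManifest <- function(split, splitId = 0L) {
  data.frame(
    split_id = splitId,
    sample_id = c(split$train, split$test),
    role = rep(c("train", "test"), c(length(split$train),
                                     length(split$test)))
  )
}
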