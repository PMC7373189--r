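# Model interpretation: signed absolute-weight ranks for linear families
# and correlation-grouped permutation importance for any family.

#' Rank features of linear models by absolute weight
#'
#' Within each fitted model (one per data split) features are ranked by
#' descending absolute weight — rank 1 is the largest |w| — with exact ties
#' sharing their average rank.  The sign of the weight says which class a
#' feature pushes toward: negative = protective (healthy), positive = risk
#' (SRN).  Features are then aggregated by the median of their per-split
#' ranks; the `topN` features with the smallest median rank are reported
#' (ties in the median broken by feature id for a deterministic listing).
#'
#' @param models list of linear [FittedModel-class] objects (e.g. from
#'   `runBenchmark(..., keepModels = TRUE)`), one per split.
#' @param topN number of top features to report.
#' @return list with `perSplit` (features x splits matrix of ranks),
#'   `signs` (features x splits matrix in \{-1, 0, 1\}), `aggregate`
#'   (data.frame feature / median_rank / median_sign, sorted) and `top`
#'   (character vector of the topN feature ids).
#' @export
rankWeights <- function(models, topN = 20L) {
  if (is(models, "FittedModel")) models <- list(models)
  stopIfNot(length(models) > 0L, "need at least one fitted model")
  for (m in models) {
    if (!length(m@weights)) {
      stop("rankWeights() needs linear models; '", m@modelName,
           "' has no weight vector")
    }
  }
  feats <- models[[1L]]@featureIds
  ranks <- vapply(models, function(m) {
    stopIfNot(identical(m@featureIds, feats),
              "all models must share one feature universe")
    rank(-abs(m@weights), ties.method = "average")
  }, numeric(length(feats)))
  signs <- vapply(models, function(m) sign(m@weights),
                  numeric(length(feats)))
  ranks <- matrix(ranks, nrow = length(feats),
                  dimnames = list(feats, NULL))
  signs <- matrix(signs, nrow = length(feats),
                  dimnames = list(feats, NULL))
  med <- apply(ranks, 1L, median)
  medSign <- apply(signs, 1L, median)
  ord <- order(med, feats)
  agg <- data.frame(feature = feats[ord], median_rank = med[ord],
                    median_sign = medSign[ord], row.names = NULL,
                    stringsAsFactors = FALSE)
  list(perSplit = ranks, signs = signs, aggregate = agg,
       top = agg$feature[seq_len(min(topN, nrow(agg)))])
}

# Two-sided p-value for a Spearman correlation r at sample size n.
# For |r| = 1 the exact permutation bound 2/n! is used up to n = 10,
# beyond which it is far below any usual alpha and the t approximation
# (which gives 0 at |r| = 1) takes over.
spearmanP <- function(r, n) {
  if (abs(r) >= 1) {
    if (n <= 10) return(2 / factorial(n))
    return(0)
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Partition OTUs into groups of perfectly rank-correlated features
#'
#' Computes the Spearman rank-correlation matrix (midranks for ties) and
#' merges features whose pairwise correlation reaches `threshold` (default
#' 1, within `tol`) with p-value below `alpha` into one group by transitive
#' closure; all other features become singletons.  Anticorrelated pairs
#' (rho = -1) are not grouped.  Features constant across samples have no
#' defined rank correlation and stay singletons.  Note that with rho
#' exactly 1 and n >= 5 samples the p-value condition (p = 2/n! < 0.01) is
#' automatically met, so the operative filter is the correlation tolerance.
#'
#' @param x an [OtuTable-class] (any stage; Spearman correlation is
#'   invariant to the monotone min-max map).
#' @param alpha significance level for the correlation p-value.
#' @param threshold correlation required to merge (default perfect, 1).
#' @param tol numeric tolerance on the threshold.
#' @return A [CorrelationGroups-class].
#' @export
findPerfectGroups <- function(x, alpha = 0.01, threshold = 1,
                              tol = 1e-12) {
  m <- if (is(x, "OtuTable")) abundances(x) else as.matrix(x)
  feats <- colnames(m)
  n <- nrow(m)
  membership <- seq_along(feats)
  if (n >= 5L && ncol(m) >= 2L) {
    constant <- apply(m, 2L, function(col) min(col) == max(col))
    cm <- suppressWarnings(cor(m, method = "spearman"))
    cm[constant, ] <- NA
    cm[, constant] <- NA
    adj <- !is.na(cm) & cm >= threshold - tol
    diag(adj) <- FALSE
    pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(pairs) > 0L) {
      keep <- vapply(seq_len(nrow(pairs)), function(i) {
        spearmanP(cm[pairs[i, 1L], pairs[i, 2L]], n) < alpha
      }, logical(1L))
      pairs <- pairs[keep, , drop = FALSE]
    }
    if (nrow(pairs) > 0L) {
      g <- igraph::graph_from_edgelist(
        cbind(feats[pairs[, 1L]], feats[pairs[, 2L]]), directed = FALSE)
      g <- igraph::add_vertices(
        g, length(setdiff(feats, igraph::V(g)$name)),
        name = setdiff(feats, igraph::V(g)$name))
      comp <- igraph::components(g)$membership
      membership <- as.integer(comp[feats])
    }
  }
  # renumber groups in order of first appearance
  membership <- as.integer(factor(membership, levels = unique(membership)))
  names(membership) <- feats
  new("CorrelationGroups", featureIds = feats, membership = membership)
}

#' Grouped permutation importance on held-out data
#'
#' For each correlation group, the test rows of exactly that group's
#' columns are shuffled jointly (one row permutation applied to all member
#' columns, preserving within-group alignment), the model is rescored and
#' the AUROC drop from the unpermuted baseline recorded; this is repeated
#' `nPerms` times under derived seeds and summarized by the median.  With
#' all-singleton groups this is classic per-feature permutation importance.
#' Negative drops can occur by chance and are reported as is.
#'
#' @param model a [FittedModel-class].
#' @param x held-out test rows (matrix or [OtuTable-class]); must be
#'   disjoint from the training data for an honest importance estimate.
#' @param labels test labels (two-level factor).
#' @param groups a [CorrelationGroups-class] over the model's features.
#' @param nPerms number of permutations per group.
#' @param seed integer RNG seed.
#' @return data.frame, one row per group, ranked by descending median
#'   drop: `group`, `members`, `size`, `base_auc`, `perm_auc`
#'   (median permuted AUROC), `drop` (base - perm_auc), `rank`.
#' @export
permutationImportance <- function(model, x, labels, groups, nPerms = 30L,
                                  seed = 1L) {
  if (is(x, "OtuTable")) x <- abundances(x)
  labels <- checkLabels(labels, rownames(x))
  stopIfNot(nrow(x) >= 2L,
            "AUROC is undefined on fewer than two test samples")
  unknown <- setdiff(groups@featureIds, colnames(x))
  stopIfNot(length(unknown) == 0L,
            "group(s) reference unknown feature(s): ",
            paste(head(unknown, 5L), collapse = ", "))
  baseAuc <- auroc(decisionScores(model, x), labels)
  members <- groupMembers(groups)
  nTest <- nrow(x)

  rows <- withSeed(seed, {
    lapply(seq_along(members), function(gi) {
      cols <- members[[gi]]
      # stack nPerms permuted copies -> one scoring call per group
      big <- x[rep(seq_len(nTest), nPerms), , drop = FALSE]
      rownames(big) <- NULL
      for (pi in seq_len(nPerms)) {
        idx <- (pi - 1L) * nTest + seq_len(nTest)
        big[idx, cols] <- x[sample.int(nTest), cols, drop = FALSE]
      }
      colnames(big) <- colnames(x)
      sc <- decisionScores(model, big)
      permAucs <- vapply(seq_len(nPerms), function(pi) {
        idx <- (pi - 1L) * nTest + seq_len(nTest)
        auroc(sc[idx], labels)
      }, numeric(1L))
      data.frame(
        group = gi,
        members = paste(cols, collapse = ","),
        size = length(cols),
        base_auc = baseAuc,
        perm_auc = median(permAucs),
        drop = baseAuc - median(permAucs),
        stringsAsFactors = FALSE
      )
    })
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$drop, out$members), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Aggregate per-split permutation importances
#'
#' @param perSplit list of data.frames from [permutationImportance()], one
#'   per split, computed with the same groups.
#' @return data.frame per group: `members`, `size`, `median_drop`, `rank`
#'   (rank 1 = largest median drop; ties broken by member ids).
#' @export
aggregateImportance <- function(perSplit) {
  stopIfNot(length(perSplit) > 0L, "need at least one split's importances")
  all <- do.call(rbind, perSplit)
  agg <- lapply(split(all, all$members), function(d) {
    data.frame(members = d$members[1L], size = d$size[1L],
               median_drop = median(d$drop), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$median_drop, out$members), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Overlap between two top-N feature lists
#'
#' Used to quantify agreement between the two interpretation methods (e.g.
#' weight-rank top 20 versus permutation-importance top 20).
#'
#' @param a,b character vectors of feature ids from the same universe.
#' @return integer size of the intersection.
#' @export
compareTopFeatures <- function(a, b) {
  length(intersect(a, b))
}
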