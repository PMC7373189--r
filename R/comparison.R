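# Paired model comparison via the double-tailed empirical p-value on
# per-split AUROC differences.

#' Double-tailed empirical p-value for paired differences
#'
#' Under the null hypothesis that the distribution of per-split AUROC
#' differences is symmetric about zero, the p-value is
#' `2 x min(fraction of differences >= 0, fraction of differences <= 0)`,
#' capped at 1.  Zero differences count toward both tails, exactly as the
#' formula reads; the statistic's resolution is `2 / length(diffs)`, and a
#' reported 0 means "below that resolution".
#'
#' @param diffs nonempty numeric vector of paired differences
#'   (`auc_a - auc_b` per split).
#' @return list with `frac_ge0`, `frac_le0` and `p_value`.
#' @examples
#' empiricalPvalue(c(rep(1, 75), rep(-1, 25)))$p_value  # 0.5
#' @export
empiricalPvalue <- function(diffs) {
  stopIfNot(length(diffs) > 0L, "diffs must be nonempty")
  stopIfNot(all(is.finite(diffs)), "diffs must be finite")
  fracGe <- mean(diffs >= 0)
  fracLe <- mean(diffs <= 0)
  list(frac_ge0 = fracGe, frac_le0 = fracLe,
       p_value = min(1, 2 * min(fracGe, fracLe)))
}

#' Compare two models' AUROCs pairwise across data splits
#'
#' Differences are paired by `split_id` — both models must have run on the
#' identical set of splits (mismatches are an error, never silently
#' intersected) — and the empirical p-value of [empiricalPvalue()] applied.
#'
#' @param results benchmark table from [runBenchmark()].
#' @param a,b model names present in `results`.
#' @param metric which AUROC to compare (default held-out `"test_auc"`).
#' @return A `ComparisonResult`: list with `model_a`, `model_b`, `diffs`
#'   (named by split id), `frac_ge0`, `frac_le0`, `p_value`.
#' @export
compareModels <- function(results, a, b, metric = "test_auc") {
  if (is.list(results) && !is.data.frame(results)) {
    results <- results$results
  }
  stopIfNot(all(c(a, b) %in% results$model),
            "both models must appear in the results")
  ra <- results[results$model == a, ]
  rb <- results[results$model == b, ]
  if (!identical(sort(ra$split_id), sort(rb$split_id))) {
    stop("models '", a, "' and '", b,
         "' were not evaluated on identical split ids")
  }
  ra <- ra[order(ra$split_id), ]
  rb <- rb[order(rb$split_id), ]
  diffs <- setNames(ra[[metric]] - rb[[metric]], ra$split_id)
  ep <- empiricalPvalue(diffs)
  structure(c(list(model_a = a, model_b = b, diffs = diffs), ep),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  n <- length(x$diffs)
  pTxt <- if (x$p_value == 0) sprintf("< %g", 2 / n) else
    format(x$p_value)
  cat(sprintf(
    "ComparisonResult: %s vs %s over %d splits\n", x$model_a, x$model_b, n))
  cat(sprintf("  %.0f%% of splits favour %s; empirical P %s\n",
              100 * mean(x$diffs > 0), x$model_a, pTxt))
  invisible(x)
}

#' All pairwise model comparisons
#'
#' @param results benchmark table from [runBenchmark()].
#' @param metric which AUROC to compare.
#' @return data.frame, one row per unordered model pair: `model_a`,
#'   `model_b`, `median_diff`, `frac_ge0`, `frac_le0`, `p_value`.
#' @export
pairwiseComparisons <- function(results, metric = "test_auc") {
  if (is.list(results) && !is.data.frame(results)) {
    results <- results$results
  }
  mods <- unique(results$model)
  if (length(mods) < 2L) {
    stop("need at least two models to compare")
  }
  pairs <- utils::combn(mods, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    cmp <- compareModels(results, pairs[1L, i], pairs[2L, i],
                         metric = metric)
    data.frame(model_a = cmp$model_a, model_b = cmp$model_b,
               median_diff = median(cmp$diffs),
               frac_ge0 = cmp$frac_ge0, frac_le0 = cmp$frac_le0,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
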