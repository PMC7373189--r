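# Run configuration and end-to-end orchestration: preprocess -> benchmark
# -> summaries -> interpretation -> pairwise comparisons -> result bundle.

#' Build and validate a run configuration
#'
#' Defaults reproduce the benchmarking protocol: 100 stratified 80/20
#' splits, hyperparameters selected by 10x repeated stratified five-fold
#' cross-validation, all seven model families, permutation importance with
#' 30 permutations per group and correlation grouping at threshold 1.
#' Every random operation's seed is derived from `baseSeed` (split `s` uses
#' `baseSeed + s`), so a run is fully reproducible and any single split can
#' be re-derived in isolation.
#'
#' @param sharedPath,metadataPath input files (mothur `.shared` + tab-
#'   delimited metadata); alternatively supply `synthetic`.
#' @param synthetic optional named list of [generateSyntheticOtus()]
#'   arguments used instead of input files.
#' @param labelColumn metadata column holding a precomputed binary label;
#'   when `NULL` the `diagnosis` column is collapsed with
#'   [assignSrnLabels()].
#' @param models model families to benchmark.
#' @param nSplits,trainFraction,k,cvRepeats benchmark loop parameters.
#' @param grids optional per-model grid overrides.
#' @param nPerms permutations per correlation group.
#' @param correlationThreshold Spearman correlation required to group
#'   features (default perfect, 1).
#' @param rarefyDepth rarefaction depth; `NULL` = smallest sample total;
#'   `FALSE` skips rarefaction (e.g. for synthetic runs).
#' @param normalizeWithinTrain compute min-max statistics within each
#'   split's training rows instead of once globally.
#' @param topN top-feature list length for the interpretation tables.
#' @param baseSeed integer base seed.
#' @param outdir output directory for [runPipeline()].
#' @return A validated `RunConfig` list.
#' @export
runConfig <- function(sharedPath = NULL, metadataPath = NULL,
                      synthetic = NULL, labelColumn = NULL,
                      models = listModels(), nSplits = 100L,
                      trainFraction = 0.8, k = 5L, cvRepeats = 10L,
                      grids = NULL, nPerms = 30L,
                      correlationThreshold = 1, rarefyDepth = NULL,
                      normalizeWithinTrain = FALSE, topN = 20L,
                      baseSeed = 0L, outdir = "otubench-results") {
  stopIfNot(!is.null(synthetic) ||
              (!is.null(sharedPath) && !is.null(metadataPath)),
            "provide either input files or a synthetic spec")
  stopIfNot(trainFraction > 0 && trainFraction < 1,
            "trainFraction must lie strictly in (0, 1)")
  stopIfNot(nSplits >= 1, "nSplits must be positive")
  stopIfNot(k >= 2 && cvRepeats >= 1, "invalid CV scheme")
  stopIfNot(nPerms >= 1, "nPerms must be positive")
  stopIfNot(correlationThreshold > 0 && correlationThreshold <= 1,
            "correlationThreshold must lie in (0, 1]")
  unknown <- setdiff(models, listModels())
  stopIfNot(length(unknown) == 0L,
            "unknown model(s): ", paste(unknown, collapse = ", "))
  structure(list(
    sharedPath = sharedPath, metadataPath = metadataPath,
    synthetic = synthetic, labelColumn = labelColumn, models = models,
    nSplits = as.integer(nSplits), trainFraction = trainFraction,
    k = as.integer(k), cvRepeats = as.integer(cvRepeats), grids = grids,
    nPerms = as.integer(nPerms),
    correlationThreshold = correlationThreshold,
    rarefyDepth = rarefyDepth,
    normalizeWithinTrain = normalizeWithinTrain,
    topN = as.integer(topN), baseSeed = as.integer(baseSeed),
    outdir = outdir
  ), class = "RunConfig")
}

#' Read a YAML run configuration file
#'
#' @param path YAML file whose keys are [runConfig()] arguments.
#' @param ... overrides applied on top of the file.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  do.call(runConfig, modifyList(vals, list(...)))
}

.loadInputs <- function(config) {
  if (!is.null(config$synthetic)) {
    syn <- do.call(generateSyntheticOtus, config$synthetic)
    return(list(table = syn$table, labels = syn$labels,
                groundTruth = syn$groundTruth))
  }
  tab <- readShared(config$sharedPath)
  meta <- readSampleMetadata(config$metadataPath, config$labelColumn)
  meta <- meta[match(sampleIds(tab), meta$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop("metadata is missing sample(s) present in the shared file")
  }
  labels <- if (is.null(config$labelColumn)) {
    assignSrnLabels(setNames(meta$diagnosis, meta$sample_id))
  } else {
    checkLabels(setNames(factor(meta[[config$labelColumn]]),
                         meta$sample_id))
  }
  list(table = tab, labels = labels, groundTruth = NULL)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the complete benchmarking pipeline and write a result bundle
#'
#' Loads (or generates) the data, rarefies and min-max normalizes it,
#' runs the repeated-split benchmark, and writes tab-delimited results to
#' `config$outdir`: `results.tsv` (one row per split x model),
#' `summary.tsv` (per-model performance summary), `comparisons.tsv`
#' (pairwise empirical p-values, when more than one model ran),
#' `weight_ranks.tsv` (median signed weight ranks, linear models),
#' `permutation_importance.tsv` (grouped importance, aggregated over
#' splits) and `manifest.json` (config, seeds, versions).  Re-running the
#' same config produces identical files.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @return invisibly, a list with the in-memory results (`benchmark`,
#'   `summary`, `comparisons`, `weightRanks`, `importance`, `groups`,
#'   `table`, `labels`).
#' @export
runPipeline <- function(config) {
  stopIfNot(inherits(config, "RunConfig"),
            "config must come from runConfig()")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- .loadInputs(config)
  tab <- inputs$table
  inputs$labels <- checkLabels(inputs$labels, sampleIds(tab))

  if (tableStage(tab) == "counts" && !isFALSE(config$rarefyDepth)) {
    tab <- rarefy(tab, depth = config$rarefyDepth,
                  seed = config$baseSeed)
  }
  groups <- findPerfectGroups(tab,
                              threshold = config$correlationThreshold)
  if (!config$normalizeWithinTrain) tab <- minmaxNormalize(tab)

  bench <- runBenchmark(tab, inputs$labels, models = config$models,
                        nSplits = config$nSplits,
                        trainFraction = config$trainFraction,
                        k = config$k, cvRepeats = config$cvRepeats,
                        grids = config$grids, baseSeed = config$baseSeed,
                        normalizeWithinTrain = config$normalizeWithinTrain,
                        keepModels = TRUE)
  .writeTsv(bench$results, file.path(config$outdir, "results.tsv"))
  summ <- summarizePerformance(bench$results)
  .writeTsv(summ, file.path(config$outdir, "summary.tsv"))

  comparisons <- NULL
  if (length(config$models) >= 2L) {
    comparisons <- pairwiseComparisons(bench$results)
    .writeTsv(comparisons, file.path(config$outdir, "comparisons.tsv"))
  }

  # interpretation: weight ranks for the linear families that ran
  weightRanks <- list()
  linear <- intersect(config$models,
                      c("l2_logistic", "l1_svm_linear", "l2_svm_linear"))
  for (nm in linear) {
    weightRanks[[nm]] <- rankWeights(bench$models[[nm]],
                                     topN = config$topN)
  }
  if (length(weightRanks) > 0L) {
    wr <- do.call(rbind, lapply(names(weightRanks), function(nm) {
      data.frame(model = nm, weightRanks[[nm]]$aggregate,
                 stringsAsFactors = FALSE)
    }))
    .writeTsv(wr, file.path(config$outdir, "weight_ranks.tsv"))
  }

  # grouped permutation importance per model, aggregated over splits
  rawM <- abundances(tab)
  testMatrix <- function(s) {
    ids <- bench$splits[[s]]$test
    if (config$normalizeWithinTrain) {
      pars <- minmaxParams(rawM[bench$splits[[s]]$train, , drop = FALSE])
      abundances(minmaxNormalize(tab, params = pars))[ids, , drop = FALSE]
    } else {
      rawM[ids, , drop = FALSE]
    }
  }
  importance <- list()
  for (nm in config$models) {
    perSplit <- lapply(seq_len(config$nSplits), function(s) {
      ids <- bench$splits[[s]]$test
      permutationImportance(bench$models[[nm]][[s]], testMatrix(s),
                            inputs$labels[ids], groups,
                            nPerms = config$nPerms,
                            seed = config$baseSeed + s - 1L)
    })
    importance[[nm]] <- aggregateImportance(perSplit)
  }
  imp <- do.call(rbind, lapply(names(importance), function(nm) {
    data.frame(model = nm, importance[[nm]], stringsAsFactors = FALSE)
  }))
  .writeTsv(imp, file.path(config$outdir, "permutation_importance.tsv"))

  manifest <- list(
    package = "otubench",
    version = as.character(packageVersion("otubench")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config[!vapply(config, is.null, logical(1L))],
    n_groups = nGroups(groups),
    n_correlated_features = sum(groupSizes(groups)[groupSizes(groups) > 1])
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  invisible(list(benchmark = bench, summary = summ,
                 comparisons = comparisons, weightRanks = weightRanks,
                 importance = importance, groups = groups, table = tab,
                 labels = inputs$labels,
                 groundTruth = inputs$groundTruth))
}
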