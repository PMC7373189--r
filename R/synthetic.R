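# Synthetic labeled OTU tables with the statistical structure the pipeline
# assumes: many sparse heavy-tailed features, few informative ones, and
# blocks of perfectly rank-correlated features.

#' Generate a synthetic labeled OTU count table
#'
#' Counts for each sample are allocated multinomially (at a per-sample read
#' depth drawn uniformly from \[0.8, 1.2\] x `depthMean`) over a log-normal
#' baseline mean profile, giving non-negative, sparse, heavy-tailed
#' abundances.  `nInformative` features carry class signal: their expected
#' abundance is multiplied by `effectSize` in cases.  Each entry of
#' `blockSizes` expands one source feature into a block of exact monotone
#' copies (parent times distinct positive integers), guaranteeing pairwise
#' Spearman rho = 1 within the block; block parents are taken from the
#' informative features first so collinearity interacts with the class
#' signal.  `sparsity` zeroes non-block entries independently at the given
#' probability.  Everything is reproducible from `seed`.
#'
#' Defaults mirror the colorectal-cancer screening study the pipeline was
#' designed around: 490 samples, 6,920 OTUs, a 229/490 case fraction,
#' 144 blocks of 3 (432 perfectly correlated OTUs) and a mean depth of
#' 10,000 reads.
#'
#' @param nSamples,nFeatures table dimensions.
#' @param nInformative number of class-informative source features.
#' @param effectSize multiplicative fold-change of informative feature means
#'   in cases (1 = no signal).
#' @param caseFraction fraction of samples in the positive (SRN) class;
#'   exactly `round(caseFraction * nSamples)` cases are produced.
#' @param blockSizes integer vector; each entry is the size of one block of
#'   perfectly rank-correlated features (a size-k block occupies k feature
#'   columns).  `NULL` (default) scales the study's correlated fraction to
#'   the table width: blocks of 3 covering about 432/6920 of the features
#'   (144 blocks at the default width).  Use `integer(0)` for no blocks.
#' @param sparsity probability in \[0, 1) that a non-block count is zeroed.
#' @param depthMean mean sequencing depth per sample.
#' @param blockNoise standard deviation of multiplicative log-normal noise
#'   applied to block copies; 0 (default) keeps within-block correlation
#'   exactly 1.
#' @param seed integer RNG seed.
#'
#' @return A list with elements `table` (an [OtuTable-class], stage
#'   `"counts"`), `labels` (factor `healthy`/`SRN` named by sample id) and
#'   `groundTruth` (list with `informative` feature ids — block copies of
#'   informative parents included — and `blocks`, a list of member id
#'   vectors).
#' @examples
#' syn <- generateSyntheticOtus(nSamples = 40, nFeatures = 30,
#'                              nInformative = 3, effectSize = 6, seed = 1)
#' syn$table
#' table(syn$labels)
#' @export
generateSyntheticOtus <- function(nSamples = 490L,
                                  nFeatures = 6920L,
                                  nInformative = 50L,
                                  effectSize = 4,
                                  caseFraction = 229 / 490,
                                  blockSizes = NULL,
                                  sparsity = 0.5,
                                  depthMean = 10000L,
                                  blockNoise = 0,
                                  seed = 1L) {
  stopIfNot(nSamples >= 2 && nFeatures >= 1, "need >= 2 samples, >= 1 feature")
  stopIfNot(nInformative >= 0 && nInformative <= nFeatures,
            "nInformative must lie in [0, nFeatures]")
  stopIfNot(effectSize > 0, "effectSize must be positive")
  stopIfNot(caseFraction > 0 && caseFraction < 1,
            "caseFraction must lie in (0, 1)")
  stopIfNot(sparsity >= 0 && sparsity < 1, "sparsity must lie in [0, 1)")
  stopIfNot(depthMean >= 1, "depthMean must be positive")
  if (is.null(blockSizes)) {
    # study proportion: 432 of 6,920 OTUs inside blocks of 3
    blockSizes <- rep(3L, floor(nFeatures * (432 / 6920) / 3))
  }
  blockSizes <- as.integer(blockSizes)
  stopIfNot(all(blockSizes >= 1), "block sizes must be positive")
  stopIfNot(sum(blockSizes) <= nFeatures,
            "blocks cannot occupy more than nFeatures columns")

  nBlocks <- length(blockSizes)
  # one source feature per block plus the free (unreplicated) features
  nSource <- nFeatures - sum(blockSizes) + nBlocks
  stopIfNot(nInformative <= nSource,
            "nInformative exceeds the number of source features (",
            nSource, ") left after block replication")

  withSeed(seed, {
    sampleNames <- sprintf("S%0*d", nchar(nSamples), seq_len(nSamples))
    nCases <- round(caseFraction * nSamples)
    stopIfNot(nCases >= 1 && nCases < nSamples,
              "caseFraction leaves an empty class at this nSamples")
    labels <- factor(rep("healthy", nSamples), levels = c("healthy", "SRN"))
    labels[sample.int(nSamples, nCases)] <- "SRN"
    names(labels) <- sampleNames

    # source features: blocks parents first, then free features; informative
    # ids drawn from the front so block parents carry signal first
    baseline <- exp(rnorm(nSource, mean = 0, sd = 1.5))
    informativeSrc <- seq_len(nInformative)
    isCase <- labels == "SRN"

    counts <- matrix(0, nSamples, nSource)
    lambdaCtrl <- baseline
    lambdaCase <- baseline
    lambdaCase[informativeSrc] <- lambdaCase[informativeSrc] * effectSize
    depths <- round(runif(nSamples, 0.8, 1.2) * depthMean)
    for (i in seq_len(nSamples)) {
      lam <- if (isCase[i]) lambdaCase else lambdaCtrl
      counts[i, ] <- rmultinom(1L, depths[i], lam / sum(lam))
    }

    # expand blocks into exact monotone copies of their parent
    out <- matrix(0, nSamples, nFeatures)
    featNames <- sprintf("Otu%0*d", max(4L, nchar(nFeatures)),
                         seq_len(nFeatures))
    colIdx <- 0L
    blocks <- vector("list", nBlocks)
    sourceCol <- integer(nFeatures)  # source index backing each column
    if (nBlocks > 0L) {
      for (b in seq_len(nBlocks)) {
        parent <- counts[, b]
        mult <- seq_len(blockSizes[b])  # distinct positive integers
        for (jm in mult) {
          colIdx <- colIdx + 1L
          copy <- parent * jm
          if (blockNoise > 0) {
            copy <- copy * exp(rnorm(nSamples, 0, blockNoise))
          }
          out[, colIdx] <- copy
          sourceCol[colIdx] <- b
        }
        blocks[[b]] <- featNames[(colIdx - blockSizes[b] + 1L):colIdx]
      }
    }
    freeSrc <- setdiff(seq_len(nSource), seq_len(nBlocks))
    for (s in freeSrc) {
      colIdx <- colIdx + 1L
      out[, colIdx] <- counts[, s]
      sourceCol[colIdx] <- s
    }

    # seeded zeroing of non-block entries
    if (sparsity > 0) {
      freeCols <- which(sourceCol %in% freeSrc)
      if (length(freeCols) > 0L) {
        mask <- matrix(rbinom(nSamples * length(freeCols), 1L,
                              1 - sparsity),
                       nSamples, length(freeCols))
        out[, freeCols] <- out[, freeCols] * mask
      }
    }

    dimnames(out) <- list(sampleNames, featNames)
    informative <- featNames[sourceCol %in% informativeSrc]
    list(
      table = OtuTable(out, stage = "counts"),
      labels = labels,
      groundTruth = list(informative = informative, blocks = blocks)
    )
  })
}

#' Write a synthetic data set as shared + metadata files
#'
#' Convenience for exercising the file-based pipeline end to end: writes the
#' count table in mothur `.shared` format and a tab-delimited metadata file
#' with `sample_id` and `label` columns.
#'
#' @param syn result of [generateSyntheticOtus()].
#' @param sharedPath,metadataPath output paths.
#' @return invisible list of the two paths.
#' @export
writeSyntheticData <- function(syn, sharedPath, metadataPath) {
  writeShared(syn$table, sharedPath)
  meta <- data.frame(sample_id = names(syn$labels),
                     label = as.character(syn$labels))
  write.table(meta, metadataPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(shared = sharedPath, metadata = metadataPath))
}
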