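# Reading/writing mothur shared tables, sample metadata, and the
# preprocessing chain (SRN labels, rarefaction, min-max normalization).

#' Read a mothur `.shared` OTU count table
#'
#' A `shared` file is tab-delimited with header columns `label`, `Group`
#' (sample id), `numOtus`, then one column per OTU.  The `numOtus` column is
#' checked against the actual number of OTU columns.
#'
#' @param path path to the shared file.
#' @return An [OtuTable-class] at stage `"counts"`, one row per `Group`.
#' @export
readShared <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  required <- c("label", "Group", "numOtus")
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0L) {
    stop("not a shared file: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  otuCols <- setdiff(names(dt), required)
  if (length(otuCols) == 0L) stop("shared file contains no OTU columns")
  if (anyDuplicated(dt$Group)) {
    stop("duplicate Group (sample) ids in shared file: ",
         paste(unique(dt$Group[duplicated(dt$Group)]), collapse = ", "))
  }
  if (any(dt$numOtus != length(otuCols))) {
    stop("numOtus column (", dt$numOtus[1L], ") does not match the ",
         length(otuCols), " OTU columns present")
  }
  m <- as.matrix(dt[otuCols])
  if (!is.numeric(m) || anyNA(m)) {
    stop("OTU counts must be numeric and complete")
  }
  if (any(m < 0)) stop("OTU counts must be non-negative")
  rownames(m) <- as.character(dt$Group)
  OtuTable(m, stage = "counts")
}

#' Write an [OtuTable-class] as a mothur `.shared` file
#'
#' @param x an [OtuTable-class] (any stage; counts round-trip losslessly).
#' @param path output path.
#' @param label value for the mothur `label` column (OTU definition cutoff).
#' @return `path`, invisibly.
#' @export
writeShared <- function(x, path, label = "0.03") {
  m <- abundances(x)
  out <- data.frame(label = label, Group = rownames(m),
                    numOtus = ncol(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited sample metadata table
#'
#' Expects a header with a `sample_id` column and either a `diagnosis`
#' column (four-level colonoscopy outcome, see [assignSrnLabels()]) or a
#' precomputed binary label column named by `labelColumn`.
#'
#' @param path path to the metadata file.
#' @param labelColumn optional name of a precomputed binary label column.
#' @return A data.frame with `sample_id` plus `diagnosis` and/or the label
#'   column.
#' @export
readSampleMetadata <- function(path, labelColumn = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  if (!"sample_id" %in% names(dt)) {
    stop("metadata must contain a 'sample_id' column")
  }
  want <- if (is.null(labelColumn)) "diagnosis" else labelColumn
  if (!want %in% names(dt)) {
    stop("metadata must contain a '", want, "' column")
  }
  if (anyDuplicated(dt$sample_id)) stop("duplicate sample_id in metadata")
  dt
}

.diagnosisLevels <- c("normal", "nonadvanced_adenoma",
                      "advanced_adenoma", "carcinoma")

#' Collapse colonoscopy diagnoses to the healthy / SRN binary classes
#'
#' Screen relevant neoplasia (SRN) comprises advanced adenomas and
#' carcinomas; normal colons and nonadvanced adenomas form the healthy
#' class.  Applied to the study cohort (172 normal, 89 nonadvanced adenoma,
#' 109 advanced adenoma, 120 carcinoma) this yields 261 healthy and 229 SRN.
#'
#' @param diagnosis character/factor of diagnoses, one of `"normal"`,
#'   `"nonadvanced_adenoma"`, `"advanced_adenoma"`, `"carcinoma"`.
#' @param sampleIds optional sample ids; defaults to `names(diagnosis)`.
#' @return A factor with levels `c("healthy", "SRN")` (SRN = positive
#'   class), named by sample id when ids are available.
#' @examples
#' assignSrnLabels(c(a = "normal", b = "carcinoma", c = "advanced_adenoma"))
#' @export
assignSrnLabels <- function(diagnosis, sampleIds = names(diagnosis)) {
  force(sampleIds)
  diagnosis <- as.character(diagnosis)
  bad <- setdiff(unique(diagnosis), .diagnosisLevels)
  if (length(bad) > 0L) {
    stop("unknown diagnosis categor", if (length(bad) > 1L) "ies: " else "y: ",
         paste(bad, collapse = ", "))
  }
  lab <- ifelse(diagnosis %in% c("advanced_adenoma", "carcinoma"),
                "SRN", "healthy")
  labels <- factor(lab, levels = c("healthy", "SRN"))
  if (!is.null(sampleIds)) names(labels) <- sampleIds
  labels
}

#' Rarefy each sample to a common read depth
#'
#' Each sample's counts are replaced by a without-replacement draw of
#' exactly `depth` reads from its observed reads (multivariate
#' hypergeometric), so that library-size differences do not masquerade as
#' biology.  Performed once per sample under `seed`.
#'
#' @param x an [OtuTable-class] at stage `"counts"`.
#' @param depth target reads per sample; defaults to the smallest sample
#'   total (the study's choice).
#' @param seed integer RNG seed.
#' @return An [OtuTable-class] at stage `"rarefied"`; all row sums equal
#'   `depth`.
#' @export
rarefy <- function(x, depth = NULL, seed = 1L) {
  stopIfNot(tableStage(x) == "counts",
            "rarefy() expects a counts-stage table, got stage '",
            tableStage(x), "'")
  m <- abundances(x)
  totals <- rowSums(m)
  if (is.null(depth)) depth <- min(totals)
  stopIfNot(depth > 0 && depth == round(depth),
            "depth must be a positive integer")
  short <- totals < depth
  if (any(short)) {
    stop("sample(s) with fewer than depth=", depth, " reads: ",
         paste(rownames(m)[short], collapse = ", "),
         "; drop them explicitly before rarefying")
  }
  # vegan heuristically warns when the smallest nonzero count exceeds 1;
  # our precondition (row totals >= depth, integer counts) already holds
  r <- withSeed(seed, withCallingHandlers(
    vegan::rrarefy(m, sample = depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  dimnames(r) <- dimnames(m)
  OtuTable(r, stage = "rarefied")
}

#' Per-OTU min-max statistics
#'
#' @param x an [OtuTable-class] or samples-by-features matrix.
#' @return list with numeric vectors `min` and `max` per feature.
#' @export
minmaxParams <- function(x) {
  m <- if (is(x, "OtuTable")) abundances(x) else as.matrix(x)
  list(min = apply(m, 2L, min), max = apply(m, 2L, max))
}

#' Min-max normalize each OTU across samples
#'
#' Each OTU column is mapped by `(x - min) / (max - min)` so its highest
#' abundance becomes 1 and its lowest 0.  Columns that are constant across
#' samples cannot satisfy that and are mapped to all zeros, keeping them
#' inert.  When `params` (from [minmaxParams()] on a training subset) is
#' supplied, those statistics are used instead and the result is clipped to
#' \[0, 1\] so the stage invariant holds for unseen samples.
#'
#' @param x an [OtuTable-class] at stage `"counts"` or `"rarefied"` (already
#'   normalized input is returned unchanged up to the idempotent map).
#' @param params optional list from [minmaxParams()].
#' @return An [OtuTable-class] at stage `"normalized"`.
#' @export
minmaxNormalize <- function(x, params = NULL) {
  m <- abundances(x)
  if (is.null(params)) params <- minmaxParams(m)
  stopIfNot(length(params$min) == ncol(m) && length(params$max) == ncol(m),
            "min-max parameters do not match the feature count")
  rng <- params$max - params$min
  scale <- ifelse(rng > 0, 1 / rng, 0)
  norm <- sweep(m, 2L, params$min, "-")
  norm <- sweep(norm, 2L, scale, "*")
  norm[, rng == 0] <- 0
  norm <- pmin(pmax(norm, 0), 1)
  OtuTable(norm, stage = "normalized")
}
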