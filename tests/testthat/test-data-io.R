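test_that("shared files round-trip losslessly, zero rows included", {
  path <- writeToyShared()
  tab <- readShared(path)
  expect_s4_class(tab, "OtuTable")
  expect_equal(dim(abundances(tab)), c(3L, 4L))
  expect_equal(tableStage(tab), "counts")
  expect_equal(unname(rowSums(abundances(tab))["sampleB"]), 0)

  out <- tempfile(fileext = ".shared")
  writeShared(tab, out)
  expect_equal(abundances(readShared(out)), abundances(tab))
})

test_that("malformed shared files are rejected with clear errors", {
  expect_error(readShared(writeToyShared(numOtus = 5)), "numOtus")

  counts <- matrix(1:4, 2, 2,
                   dimnames = list(c("s1", "s1"), c("Otu1", "Otu2")))
  expect_error(readShared(writeToyShared(counts)), "duplicate Group")

  counts <- matrix(c(1, -2, 3, 4), 2, 2,
                   dimnames = list(c("s1", "s2"), c("Otu1", "Otu2")))
  expect_error(readShared(writeToyShared(counts)), "non-negative")

  noLabel <- tempfile(fileext = ".shared")
  write.table(data.frame(Group = "s1", numOtus = 1, Otu1 = 3), noLabel,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readShared(noLabel), "missing column")
})

test_that("diagnoses collapse to healthy/SRN as a pure function", {
  lab <- assignSrnLabels(c(a = "normal", b = "nonadvanced_adenoma",
                           c = "advanced_adenoma", d = "carcinoma"))
  expect_equal(as.character(lab), c("healthy", "healthy", "SRN", "SRN"))
  expect_equal(levels(lab), c("healthy", "SRN"))
  expect_equal(names(lab), letters[1:4])

  expect_length(assignSrnLabels(character(0)), 0L)
  expect_equal(table(assignSrnLabels("carcinoma", "x"))[["SRN"]], 1L)
  expect_error(assignSrnLabels("polyp"), "unknown diagnosis")
})

test_that("rarefaction conserves depth, never exceeds originals, and is seeded", {
  m <- matrix(c(4, 0, 6,
                10, 5, 10), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("Otu", 1:3)))
  tab <- OtuTable(m)
  r <- rarefy(tab, depth = 10, seed = 1)
  expect_equal(tableStage(r), "rarefied")
  expect_equal(unname(rowSums(abundances(r))), c(10, 10))
  expect_equal(abundances(r)["s1", ], m["s1", ])  # depth equals total
  expect_true(all(abundances(r) <= m))

  expect_identical(abundances(rarefy(tab, 10, seed = 5)),
                   abundances(rarefy(tab, 10, seed = 5)))

  big <- OtuTable(matrix(c(100, 100), 1, 2,
                         dimnames = list("s", c("a", "b"))))
  draws <- vapply(1:40, function(s) abundances(rarefy(big, 50, seed = s))[1, 1],
                  numeric(1))
  expect_gt(length(unique(draws)), 1L)
  # hypergeometric marginal mean: depth * c_i / total = 25
  expect_equal(mean(draws), 25, tolerance = 0.08)

  expect_error(rarefy(tab, depth = 12), "s1")
  expect_error(rarefy(r, 5), "counts-stage")
})

test_that("min-max normalization maps columns to [0,1], constants to zero", {
  m <- cbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 0, 8))
  rownames(m) <- paste0("s", 1:3)
  norm <- abundances(minmaxNormalize(OtuTable(m)))
  expect_equal(unname(norm[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(norm[, "b"]), c(0, 0, 0))
  expect_equal(unname(norm[, "c"]), c(0, 0, 1))

  # idempotent and rank-preserving
  again <- abundances(minmaxNormalize(OtuTable(norm, stage = "normalized")))
  expect_equal(again, norm)
  expect_equal(apply(norm[, c("a", "c")], 2, rank),
               apply(m[, c("a", "c")], 2, rank))
})

test_that("train-only normalization clips unseen samples into [0,1]", {
  train <- OtuTable(cbind(Otu1 = c(1, 3)) |>
                      (\(m) {rownames(m) <- c("s1", "s2"); m})())
  test <- OtuTable(cbind(Otu1 = c(0, 5)) |>
                     (\(m) {rownames(m) <- c("t1", "t2"); m})())
  pars <- minmaxParams(train)
  norm <- abundances(minmaxNormalize(test, params = pars))
  expect_equal(unname(norm[, 1]), c(0, 1))
})

test_that("metadata reader enforces required columns", {
  path <- tempfile()
  write.table(data.frame(sample_id = c("s1", "s2"),
                         diagnosis = c("normal", "carcinoma")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- readSampleMetadata(path)
  expect_equal(md$diagnosis, c("normal", "carcinoma"))
  expect_error(readSampleMetadata(path, labelColumn = "dx"), "'dx' column")
})
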