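test_that("matched sampling preserves region lengths and is seed-driven", {
  g <- generateGenome(c(5000L, 3000L), seed = 90)
  fg <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(11, 501, 21), width = c(100, 250, 40)))
  reps <- sampleMatchedRegions(fg, g, nReps = 10L, seed = 4)
  expect_length(reps, 10L)
  for (r in reps) {
    expect_equal(GenomicRanges::width(r), GenomicRanges::width(fg))
    checkPassed <- tryCatch({
      motifZ:::checkPeaksAgainstSizes(r, genomeSizes(g)); TRUE
    }, error = function(e) FALSE)
    expect_true(checkPassed)
  }
  reps2 <- sampleMatchedRegions(fg, g, nReps = 10L, seed = 4)
  expect_identical(lapply(reps, as.data.frame),
                   lapply(reps2, as.data.frame))
  reps3 <- sampleMatchedRegions(fg, g, nReps = 10L, seed = 5)
  expect_false(identical(lapply(reps, as.data.frame),
                         lapply(reps3, as.data.frame)))
  expect_error(sampleMatchedRegions(fg, g, nReps = 1L), "nReps")
})

test_that("adding replicates never perturbs earlier ones", {
  g <- generateGenome(2000L, seed = 91)
  fg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, width = 50))
  r10 <- sampleMatchedRegions(fg, g, nReps = 10L, seed = 6)
  r20 <- sampleMatchedRegions(fg, g, nReps = 20L, seed = 6)
  expect_identical(lapply(r10, as.data.frame),
                   lapply(r20[1:10], as.data.frame))
})

test_that("sampling is proportional to valid placements per chromosome", {
  L <- 2000L
  g <- generateGenome(c(L, 9L * L), seed = 92,
                      chromNames = c("small", "big"))
  fg <- GenomicRanges::GRanges("big", IRanges::IRanges(1, width = 50))
  fg <- rep(fg, 100)
  reps <- sampleMatchedRegions(fg, g, nReps = 100L, seed = 7)
  all <- do.call(c, reps)
  nSmall <- sum(as.character(GenomicRanges::seqnames(all)) == "small")
  expected <- (L - 49) / ((L - 49) + (9 * L - 49))
  pv <- binom.test(nSmall, 10000L, p = expected)$p.value
  expect_gt(pv, 1e-6)
})

test_that("exclusion redraws overlapping regions", {
  g <- generateGenome(2000L, seed = 93)
  fg <- rep(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, width = 20)),
            30)
  excl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1500))
  reps <- sampleMatchedRegions(fg, g, nReps = 5L, exclude = excl, seed = 8)
  for (r in reps)
    expect_equal(length(GenomicRanges::findOverlaps(r, excl)), 0L)
  # impossible exclusion exhausts rejection sampling
  exclAll <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000))
  expect_error(
    sampleMatchedRegions(fg, g, nReps = 2L, exclude = exclAll, seed = 9),
    "exhausted")
})

test_that("null mean and sigma follow the sample (n-1) convention", {
  nd <- NullDistribution("m", c(2, 4, 6))
  expect_equal(nullMu(nd), 4)
  expect_equal(nullSigma(nd), 2)  # sample SD, not population 1.633
  ndc <- NullDistribution("m", rep(5, 10))
  expect_equal(nullSigma(ndc), 0)
  expect_error(NullDistribution("m", 3), "at least 2")
})

test_that("batched null building equals replicate-by-replicate scanning", {
  g <- generateGenome(c(3000L, 3000L), seed = 94)
  m <- randomMotif(95, width = 6)
  t <- scoreThreshold(m, 0.01)
  fg <- generatePeaks(g, nPeaks = 20L, peakLength = 100L, seed = 96)
  reps <- sampleMatchedRegions(fg, g, nReps = 8L, seed = 97)
  nd <- buildNull(reps, g, m, t)
  perRep <- vapply(reps, function(r)
    nrow(scanRegions(g, r, m, t)), numeric(1))
  expect_equal(replicateCounts(nd), perRep)
  expect_equal(nullMu(nd), mean(perRep))
  expect_equal(nullSigma(nd), sd(perRep))
})

test_that("a motif absent from the genome gives an all-zero null", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("AC", 500)))
  m <- MotifMatrix("ggg", consensusCounts("GGGGG"), pseudocountTotal = 0)
  fg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, width = 100))
  reps <- sampleMatchedRegions(rep(fg, 5), g, nReps = 4L, seed = 10)
  nd <- buildNull(reps, g, m, maxScore(m))
  expect_equal(replicateCounts(nd), rep(0, 4))
})

test_that("z-score, degeneracy and exact reconstruction behave as defined", {
  nd <- NullDistribution("m", c(2, 4, 6))
  zs <- zScore(8, nd)
  expect_equal(zs$z, 2)            # (8 - 4) / 2
  expect_false(zs$degenerate)
  expect_equal(zScore(4, nd)$z, 0)  # x = mu centers to zero
  # exactness: z * sigma + mu reconstructs x
  for (x in c(0, 3, 7.5, 100)) {
    zz <- zScore(x, nd)
    expect_equal(zz$z * zz$sigma + zz$mu, x)
  }
  degen <- zScore(9, NullDistribution("m", rep(5, 100)))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$z))
})

test_that("empirical p-values use the add-one permutation formula", {
  nd100 <- NullDistribution("m", seq_len(100))
  expect_equal(empiricalPvalue(101, nd100), 1 / 101)  # above all counts
  expect_equal(empiricalPvalue(0, nd100), 1)          # below all counts
  expect_equal(empiricalPvalue(8, NullDistribution("m", c(2, 4, 6))),
               1 / 4)
})

test_that("BH adjustment is step-up with input-order return", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  p <- c(0.04, 0.001, 0.9)
  expect_equal(bhAdjust(p), p.adjust(p, "BH"))
  expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bhAdjust(c(0.5, 1.2)), "\\(0, 1\\]")
})
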