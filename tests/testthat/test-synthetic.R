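test_that("genome generation is deterministic and honours GC content", {
  g1 <- generateGenome(1000L, gcContent = 0.5, seed = 7)
  g2 <- generateGenome(1000L, gcContent = 0.5, seed = 7)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- generateGenome(1000L, gcContent = 0.5, seed = 8)
  expect_false(identical(as.character(g1), as.character(g3)))

  # binomial concentration: 100 kb at GC 0.9 stays within 0.89-0.91
  g <- generateGenome(100000L, gcContent = 0.9, seed = 1)
  comp <- Biostrings::alphabetFrequency(g[[1]])[c("C", "G")]
  expect_gt(sum(comp) / 100000, 0.89)
  expect_lt(sum(comp) / 100000, 0.91)

  expect_error(generateGenome(0L, 0.5, 1), ">= 1")
  expect_error(generateGenome(100L, 1.2, 1), "gcContent")
})

test_that("peak placement is uniform over valid genomic positions", {
  g <- generateGenome(c(2000L, 1500L), seed = 2)
  p <- generatePeaks(g, nPeaks = 200L, peakLength = 100L, seed = 3)
  expect_length(p, 200L)
  expect_true(all(GenomicRanges::start(p) >= 1L))
  sizes <- genomeSizes(g)
  expect_true(all(GenomicRanges::end(p) <=
                    sizes[as.character(GenomicRanges::seqnames(p))]))
  expect_true(all(p$summitOffset == 50L))

  # forced placement: peak length equals the single chromosome
  g1 <- generateGenome(1000L, seed = 4)
  p1 <- generatePeaks(g1, nPeaks = 20L, peakLength = 1000L, seed = 5)
  expect_true(all(GenomicRanges::start(p1) == 1L &
                    GenomicRanges::end(p1) == 1000L))

  # chromosomes of lengths L and 9L: small-chromosome fraction ~ 0.1
  L <- 2000L
  g2 <- generateGenome(c(L, 9L * L), seed = 6,
                       chromNames = c("small", "big"))
  p2 <- generatePeaks(g2, nPeaks = 10000L, peakLength = 50L, seed = 7)
  nSmall <- sum(as.character(GenomicRanges::seqnames(p2)) == "small")
  pv <- binom.test(nSmall, 10000L,
                   p = (L - 49) / (L - 49 + 9 * L - 49))$p.value
  expect_gt(pv, 1e-6)

  expect_error(generatePeaks(g, 0L, 100L, 1), "positive")
  expect_error(generatePeaks(g, 10L, 5000L, 1), "peakLength")
})

test_that("motif planting edits only peaks and records a faithful truth table", {
  g <- generateGenome(c(5000L, 5000L), seed = 10)
  # non-overlapping peaks: overlapping ones could overwrite each
  # other's instances, which is allowed but not what is probed here
  p <- tiledPeaks(g, nPeaks = 50L, peakLength = 60L)
  motif <- MotifMatrix("cons", consensusCounts("TTGACCAA"),
                       pseudocountTotal = 0)

  # probability 0: identity
  sim0 <- plantMotifs(g, p, motif, plantingProbability = 0, seed = 12)
  expect_identical(as.character(sim0$genome), as.character(g))
  expect_equal(nrow(sim0$truth), 0L)

  # probability 1 with a consensus-only matrix: every peak carries the
  # consensus or its reverse complement as an exact substring
  sim1 <- plantMotifs(g, p, motif, plantingProbability = 1, seed = 13)
  expect_equal(nrow(sim1$truth), 50L)
  for (r in seq_along(p)) {
    chr <- as.character(GenomicRanges::seqnames(p))[r]
    sq <- as.character(Biostrings::subseq(
      sim1$genome[[chr]], GenomicRanges::start(p)[r],
      GenomicRanges::end(p)[r]))
    expect_true(grepl("TTGACCAA", sq) || grepl("TTGGTCAA", sq))
  }
  # planted offsets place the exact recorded sequence
  for (k in seq_len(5)) {
    row <- sim1$truth[k, ]
    abs0 <- GenomicRanges::start(p)[row$region_index] - 1L + row$offset
    got <- as.character(Biostrings::subseq(sim1$genome[[row$chrom]],
                                           abs0 + 1L, abs0 + 8L))
    want <- if (row$strand == "+") row$instance else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(row$instance)))
    expect_identical(got, want)
  }

  # determinism
  simA <- plantMotifs(g, p, motif, 0.5, seed = 14)
  simB <- plantMotifs(g, p, motif, 0.5, seed = 14)
  expect_identical(as.character(simA$genome), as.character(simB$genome))
  expect_identical(simA$truth, simB$truth)
})

test_that("planting conserves total length and confines edits to peaks", {
  g <- generateGenome(c(4000L), seed = 20)
  p <- generatePeaks(g, nPeaks = 10L, peakLength = 50L, seed = 21)
  m <- randomMotif(22, width = 8)
  sim <- plantMotifs(g, p, m, 0.8, seed = 23)
  expect_identical(genomeSizes(sim$genome), genomeSizes(g))
  # positions outside any peak are untouched
  outside <- GenomicRanges::gaps(GenomicRanges::reduce(p))
  outside <- outside[GenomicRanges::strand(outside) == "*"]
  for (r in seq_along(outside)) {
    s <- GenomicRanges::start(outside)[r]
    e <- GenomicRanges::end(outside)[r]
    expect_identical(
      as.character(Biostrings::subseq(sim$genome[[1]], s, e)),
      as.character(Biostrings::subseq(g[[1]], s, e)))
  }
  # realized planted fraction within 5 binomial SDs of 0.8 * 10
  expect_lt(abs(nrow(sim$truth) - 8), 5 * sqrt(10 * 0.8 * 0.2) + 1e-9)

  expect_error(plantMotifs(g, p, randomMotif(1, width = 60), 1, 1),
               "width")
})
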