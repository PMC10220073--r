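asGenome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

test_that("scanner agrees exactly with the naive per-window oracle", {
  set.seed(301)
  for (k in 1:6) {
    g <- randomGenome(300 + k, lengths = sample(200:2000, 2))
    win <- wholeChromRanges(g)
    m <- randomMotif(330 + k)
    t <- scoreThreshold(m, 0.01)
    got <- scanRegions(g, win, m, t, bothStrands = TRUE)
    want <- naiveScanOracle(g, win, m, t, bothStrands = TRUE)
    expect_identical(nrow(got), nrow(want))
    expect_equal(got$region_index, want$region_index)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_identical(got$score, want$score)  # bit-for-bit
  }
})

test_that("planted consensus sites are recovered at maximum score", {
  g <- generateGenome(c(3000L, 3000L), seed = 40)
  p <- tiledPeaks(g, nPeaks = 30L, peakLength = 80L)  # no overlaps
  m <- MotifMatrix("cons", consensusCounts("GATTACAT"),
                   pseudocountTotal = 0)
  sim <- plantMotifs(g, p, m, plantingProbability = 1, seed = 42)
  hits <- scanRegions(sim$genome, p, m, maxScore(m))
  # every planted (region, offset, strand) appears among the hits
  found <- paste(hits$region_index, hits$offset, hits$strand)
  planted <- paste(sim$truth$region_index, sim$truth$offset,
                   sim$truth$strand)
  expect_true(all(planted %in% found))
  expect_true(all(abs(hits$score - maxScore(m)) < 1e-9))
  # occurrence count is at least the number of planted instances
  occ <- occurrenceFrequency(hits, p, "cons", "sim")
  expect_gte(occ$x, nrow(sim$truth))
})

test_that("windows containing N are skipped, not scored", {
  g <- asGenome(c(c1 = paste(rep("N", 50), collapse = "")))
  m <- randomMotif(51, width = 4)
  hits <- scanRegions(g, wholeChromRanges(g), m, minScore(m) - 1)
  expect_equal(nrow(hits), 0L)
  # an N in the middle removes exactly the windows covering it
  g2 <- asGenome(c(c1 = "AAAANAAAA"))
  m2 <- MotifMatrix("a4", consensusCounts("AAAA"), pseudocountTotal = 0)
  hits2 <- scanRegions(g2, wholeChromRanges(g2), m2, maxScore(m2),
                       bothStrands = FALSE)
  expect_equal(hits2$offset, c(0L, 5L))
})

test_that("palindromic motifs hit both strands at each matching offset", {
  m <- MotifMatrix("pal", consensusCounts("ACGT"), pseudocountTotal = 0)
  g <- asGenome(c(c1 = "TTACGTTT"))
  hits <- scanRegions(g, wholeChromRanges(g), m, maxScore(m),
                      bothStrands = TRUE)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$offset, c(2L, 2L))
  expect_setequal(hits$strand, c("+", "-"))
})

test_that("strand scanning is reverse-complement symmetric", {
  g <- randomGenome(61, lengths = 500L)
  m <- randomMotif(62, width = 7)
  t <- scoreThreshold(m, 0.02)
  win <- wholeChromRanges(g)
  fwd <- scanRegions(g, win, m, t, bothStrands = TRUE)
  grc <- asGenome(c(chr1 = as.character(
    Biostrings::reverseComplement(g[[1]]))))
  rev <- scanRegions(grc, wholeChromRanges(grc), m, t, bothStrands = TRUE)
  # a + hit at offset o maps to a - hit at L - w - o on the RC sequence
  L <- 500L; w <- 7L
  mapOff <- function(df) {
    data.frame(offset = L - w - df$offset,
               strand = ifelse(df$strand == "+", "-", "+"),
               score = df$score)
  }
  a <- mapOff(fwd); a <- a[order(a$offset, a$strand), ]
  b <- rev[, c("offset", "strand", "score")]
  b <- b[order(b$offset, b$strand), ]
  expect_equal(a$offset, b$offset)
  expect_equal(a$strand, b$strand)
  expect_equal(a$score, b$score, tolerance = 1e-9)
})

test_that("raising the threshold never increases the occurrence count", {
  g <- randomGenome(71, lengths = 2000L)
  m <- randomMotif(72, width = 6)
  win <- wholeChromRanges(g)
  xs <- vapply(c(minScore(m), quantile(logOdds(m), 0.5) * 6,
                 scoreThreshold(m, 0.05), scoreThreshold(m, 1e-3),
                 maxScore(m)),
               function(t) nrow(scanRegions(g, win, m, t)), numeric(1))
  expect_true(all(diff(xs) <= 0))
})

test_that("regions shorter than the motif yield zero hits without error", {
  g <- asGenome(c(c1 = "ACGTACGTAC"))
  m <- randomMotif(81, width = 8)
  short <- GenomicRanges::GRanges("c1", IRanges::IRanges(2, 5))
  expect_equal(nrow(scanRegions(g, short, m, minScore(m))), 0L)
})

test_that("occurrence statistics count hits and hit-bearing regions", {
  win <- GenomicRanges::GRanges(rep("c", 10),
                                IRanges::IRanges(1:10 * 100, width = 50))
  hits <- data.frame(region_index = c(2L, 2L, 2L, 7L),
                     offset = c(0L, 3L, 9L, 1L),
                     strand = c("+", "-", "+", "+"),
                     score = c(5, 6, 7, 8))
  occ <- occurrenceFrequency(hits, win, "m", "s")
  expect_equal(occ$x, 4L)
  expect_equal(occ$regions_with_hit, 2L)
  expect_equal(occ$n_regions, 10L)
  occ0 <- occurrenceFrequency(hits[0, ], win, "m", "s")
  expect_equal(occ0$x, 0L)
  expect_equal(occ0$regions_with_hit, 0L)
})

test_that("hit export writes absolute BED6 coordinates", {
  g <- asGenome(c(c1 = "TTACGTTT"))
  m <- MotifMatrix("pal", consensusCounts("ACGT"), pseudocountTotal = 0)
  win <- GenomicRanges::GRanges("c1", IRanges::IRanges(2, 8))  # 0-based [1,8)
  hits <- scanRegions(g, win, m, maxScore(m))
  f <- tempfile(fileext = ".bed")
  writeHitsBed(hits, win, m, f)
  bed <- read.table(f, sep = "\t")
  expect_equal(bed$V2, c(2L, 2L))  # absolute 0-based start
  expect_equal(bed$V3, c(6L, 6L))
  expect_equal(bed$V4, rep("pal", 2))
})
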