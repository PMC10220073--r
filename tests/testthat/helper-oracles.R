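# Independent oracles and small builders shared across the test files.
# The oracles deliberately avoid the package's vectorized scan/DP code
# paths: they score every window on its own, straight from the log-odds
# definition, or enumerate all 4^w sequences.

BASES <- c("A", "C", "G", "T")

# 4 x width count matrix with a single allowed base per column
consensusCounts <- function(consensus) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
  cnt <- matrix(0, nrow = 4, ncol = length(bases),
                dimnames = list(BASES, NULL))
  for (i in seq_along(bases)) cnt[bases[i], i] <- 10
  cnt
}

randomMotif <- function(seed, width = NULL, id = paste0("rnd", seed)) {
  set.seed(seed)
  if (is.null(width)) width <- sample(2:8, 1)
  cnt <- matrix(stats::runif(4 * width, 0, 20), nrow = 4,
                dimnames = list(BASES, NULL))
  MotifMatrix(id, cnt)
}

randomGenome <- function(seed, lengths, gc = 0.5) {
  generateGenome(lengths, gcContent = gc, seed = seed)
}

wholeChromRanges <- function(genome) {
  sizes <- genomeSizes(genome)
  GenomicRanges::GRanges(names(sizes),
                         IRanges::IRanges(start = 1L, width = sizes))
}

# Naive per-window re-scorer: for every offset and strand, sum the
# log-odds entries of the window's bases one by one; skip windows with
# any non-ACGT character.
naiveScanOracle <- function(genome, windows, motif, threshold,
                            bothStrands = TRUE) {
  lo <- logOdds(motif)
  w <- motifWidth(motif)
  loRC <- lo[4:1, w:1, drop = FALSE]
  rownames(loRC) <- BASES
  cols <- seq_len(w)
  rows <- list()
  for (r in seq_along(windows)) {
    chr <- as.character(GenomicRanges::seqnames(windows))[r]
    sq <- as.character(Biostrings::subseq(
      genome[[chr]], GenomicRanges::start(windows)[r],
      GenomicRanges::end(windows)[r]))
    L <- nchar(sq)
    if (L < w) next
    codes <- match(strsplit(sq, "", fixed = TRUE)[[1]], BASES)
    for (o in 0:(L - w)) {
      win <- codes[(o + 1):(o + w)]
      if (anyNA(win)) next
      sc <- 0
      for (i in cols) sc <- sc + lo[win[i], i]
      if (sc >= threshold)
        rows[[length(rows) + 1L]] <-
          data.frame(region_index = r, offset = o, strand = "+",
                     score = sc)
      if (bothStrands) {
        sc <- 0
        for (i in cols) sc <- sc + loRC[win[i], i]
        if (sc >= threshold)
          rows[[length(rows) + 1L]] <-
            data.frame(region_index = r, offset = o, strand = "-",
                       score = sc)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(region_index = integer(), offset = integer(),
                      strand = character(), score = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(out$region_index, out$offset, out$strand), ]
  rownames(out) <- NULL
  out
}

# Brute-force threshold: enumerate all 4^w windows, their exact scores
# and background probabilities, group them on the same 1e-3-bit lattice
# the scanner's match definition declares, and take the smallest exact
# score in the qualifying (tail <= alpha) group.
enumThresholdOracle <- function(motif, alpha) {
  lo <- logOdds(motif)
  bg <- motifBackground(motif)
  w <- motifWidth(motif)
  li <- round(lo * 1000)
  li[!is.finite(li) | li < -30000] <- -30000
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(grid))
  bins <- numeric(nrow(grid))
  pr <- rep(1, nrow(grid))
  for (i in seq_len(w)) {
    sc <- sc + lo[grid[, i] + (i - 1) * 4L]
    bins <- bins + li[grid[, i] + (i - 1) * 4L]
    pr <- pr * bg[grid[, i]]
  }
  binProb <- tapply(pr, bins, sum)
  binScore <- as.numeric(names(binProb))
  ord <- order(binScore, decreasing = TRUE)
  tailp <- cumsum(binProb[ord])
  ok <- tailp <= alpha + 1e-9
  if (!any(ok)) return(maxScore(motif) + 1e-3)
  okBins <- binScore[ord][ok]
  min(sc[bins %in% okBins])
}

# Non-overlapping fixed-length regions tiled along the first
# chromosome(s), with centred summits; for planting-fidelity tests
# where a later edit must not overwrite an earlier one.
tiledPeaks <- function(genome, nPeaks, peakLength, gap = 20L) {
  sizes <- genomeSizes(genome)
  step <- peakLength + gap
  starts <- integer(); chroms <- character()
  for (ch in names(sizes)) {
    s <- seq(1L, sizes[[ch]] - peakLength + 1L, by = step)
    starts <- c(starts, s)
    chroms <- c(chroms, rep(ch, length(s)))
    if (length(starts) >= nPeaks) break
  }
  stopifnot(length(starts) >= nPeaks)
  GenomicRanges::GRanges(
    chroms[1:nPeaks],
    IRanges::IRanges(start = starts[1:nPeaks], width = peakLength),
    summitOffset = peakLength %/% 2L)
}

extdata <- function(f) system.file("extdata", f, package = "motifZ")
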