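#' @include AllClasses.R motif-matrix.R io-peaks.R
NULL

#' Simulate a multi-chromosome genome with controlled GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1 - gc)/2 — the homogeneous-composition background
#' the length-matched null sampling assumes. Deterministic for a fixed
#' seed.
#'
#' @param chromLengths integer vector of chromosome lengths (>= 1).
#' @param gcContent GC fraction, strictly inside (0, 1). Default 0.5.
#' @param seed integer RNG seed.
#' @param chromNames optional names; default chr1, chr2, ...
#' @return A [Biostrings::DNAStringSet].
#' @export
generateGenome <- function(chromLengths, gcContent = 0.5, seed = 1L,
                           chromNames = NULL) {
  chromLengths <- as.integer(chromLengths)
  if (any(chromLengths < 1L))
    stop("chromosome lengths must be >= 1")
  if (gcContent <= 0 || gcContent >= 1)
    stop("gcContent must be strictly inside (0, 1)")
  if (is.null(chromNames))
    chromNames <- paste0("chr", seq_along(chromLengths))
  prob <- c((1 - gcContent) / 2, gcContent / 2,
            gcContent / 2, (1 - gcContent) / 2)
  seqs <- withSeed_(as.integer(seed), {
    lapply(chromLengths, function(L)
      paste(sample(DNA_BASES_, L, replace = TRUE, prob = prob),
            collapse = ""))
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- chromNames
  out
}

#' Simulate a peak set over a genome
#'
#' Peaks of fixed length are placed uniformly over all valid genomic
#' positions: the chromosome is chosen with probability proportional to
#' its number of valid start positions (length - peakLength + 1) and the
#' start uniformly among them, so density is homogeneous genome-wide.
#' Peaks may overlap. Each peak carries `summitOffset = peakLength %/% 2`
#' (a centred summit, as for a symmetric binding-site signal).
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param nPeaks number of peaks (> 0).
#' @param peakLength peak width in bases (<= min chromosome length).
#' @param seed integer RNG seed.
#' @return A [GenomicRanges::GRanges] with `name`, `score`,
#'   `summitOffset` metadata columns.
#' @export
generatePeaks <- function(genome, nPeaks, peakLength, seed = 1L) {
  sizes <- genomeSizes(genome)
  nPeaks <- as.integer(nPeaks)
  peakLength <- as.integer(peakLength)
  if (nPeaks <= 0L) stop("nPeaks must be positive")
  if (peakLength < 1L || peakLength > min(sizes))
    stop("peakLength must be in [1, min chromosome length]")
  valid <- sizes - peakLength + 1L
  draw <- withSeed_(as.integer(seed), {
    chromIdx <- sample.int(length(sizes), nPeaks, replace = TRUE,
                           prob = valid)
    start0 <- floor(stats::runif(nPeaks) * valid[chromIdx])
    list(chromIdx = chromIdx, start0 = start0)
  })
  gr <- GenomicRanges::GRanges(
    seqnames = names(sizes)[draw$chromIdx],
    ranges = IRanges::IRanges(start = as.integer(draw$start0) + 1L,
                              width = peakLength),
    name = sprintf("peak_%d", seq_len(nPeaks)),
    score = 0,
    summitOffset = peakLength %/% 2L)
  S4Vectors::metadata(gr)$label <- "simulated"
  gr
}

#' Plant motif instances into a fraction of peaks
#'
#' Each peak independently receives, with probability
#' `plantingProbability`, one motif instance: the instance sequence is
#' sampled column-by-column from the motif's (pseudocounted) base
#' probabilities — not the consensus — so degenerate matches exercise
#' score thresholds downstream; it is written at a uniformly chosen
#' offset on a uniformly chosen strand (reverse-complemented for minus),
#' overwriting the background bases in place so all coordinates and
#' lengths are preserved. At most one instance per peak. Every edit is
#' recorded in the returned truth table.
#'
#' @param genome a [Biostrings::DNAStringSet] (not modified in place).
#' @param peaks a [GenomicRanges::GRanges] of regions to plant into.
#' @param motif a [MotifMatrix-class]; width must fit every peak.
#' @param plantingProbability probability in \[0, 1\] that a peak gets
#'   an instance.
#' @param seed integer RNG seed.
#' @return list with elements `genome` (edited copy), `truth`
#'   (data.frame: region_index, chrom, offset (0-based, within region),
#'   strand, motif_id, instance), `plantingProbability`, `seed`.
#' @export
plantMotifs <- function(genome, peaks, motif, plantingProbability,
                        seed = 1L) {
  stopifnot(methods::is(motif, "MotifMatrix"))
  if (plantingProbability < 0 || plantingProbability > 1)
    stop("plantingProbability must be in [0, 1]")
  sizes <- genomeSizes(genome)
  checkPeaksAgainstSizes(peaks, sizes)
  w <- motifWidth(motif)
  lens <- GenomicRanges::width(peaks)
  if (any(lens < w))
    stop("motif width ", w, " exceeds some region length (min ",
         min(lens), ")")
  n <- length(peaks)
  prob <- motifProbabilities(motif)
  draw <- withSeed_(as.integer(seed), {
    planted <- stats::runif(n) < plantingProbability
    idx <- which(planted)
    offs <- floor(stats::runif(length(idx)) * (lens[idx] - w + 1L))
    strands <- sample(c("+", "-"), length(idx), replace = TRUE)
    inst <- vapply(seq_along(idx), function(j) {
      bases <- vapply(seq_len(w), function(i)
        sample(DNA_BASES_, 1L, prob = prob[, i]), character(1))
      paste(bases, collapse = "")
    }, character(1))
    list(idx = idx, offs = as.integer(offs), strands = strands,
         inst = inst)
  })
  seqs <- as.character(genome)
  chroms <- as.character(GenomicRanges::seqnames(peaks))
  start0 <- GenomicRanges::start(peaks) - 1L
  written <- character(length(draw$idx))
  for (j in seq_along(draw$idx)) {
    i <- draw$idx[j]
    s <- draw$inst[j]
    if (draw$strands[j] == "-") s <- revComp_(s)
    written[j] <- s
    pos0 <- start0[i] + draw$offs[j]
    substr(seqs[[chroms[i]]], pos0 + 1L, pos0 + w) <- s
  }
  edited <- Biostrings::DNAStringSet(unname(seqs))
  names(edited) <- names(genome)
  truth <- data.frame(
    region_index = draw$idx,
    chrom = chroms[draw$idx],
    offset = draw$offs,
    strand = draw$strands,
    motif_id = rep(motifId(motif), length(draw$idx)),
    instance = draw$inst,
    stringsAsFactors = FALSE)
  list(genome = edited, truth = truth,
       plantingProbability = plantingProbability,
       seed = as.integer(seed))
}

revComp_ <- function(s) {
  paste(rev(COMPLEMENT_[strsplit(s, "", fixed = TRUE)[[1]]]),
        collapse = "")
}

#' Write a planting truth table as TSV
#'
#' Offsets in the file are 0-based within-region positions, matching
#' the hit offsets reported by [scanRegions()].
#'
#' @param truth the `truth` data.frame from [plantMotifs()].
#' @param path output TSV.
#' @export
writeTruthTable <- function(truth, path) {
  utils::write.table(
    truth[, c("region_index", "chrom", "offset", "strand", "motif_id")],
    file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
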