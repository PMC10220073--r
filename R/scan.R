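#' @include AllClasses.R motif-matrix.R threshold.R windows.R
NULL

#' Scan regions for motif matches with a log-odds PWM scanner
#'
#' Every offset o with o + width <= region length is scored on the plus
#' strand as the sum of per-position log-odds entries over the window's
#' bases, and, when `bothStrands`, against the reverse-complement
#' matrix for the minus strand. Windows containing any N are skipped
#' (no score is fabricated for masked sequence). Each (offset, strand)
#' whose score reaches `threshold` is one hit; overlapping hits all
#' count. Regions shorter than the motif simply yield no hits.
#'
#' Internally all region sequences are concatenated with N spacers and
#' scored with vectorized lattice lookups, which is algebraically (and
#' floating-point) identical to scoring each window independently
#' left-to-right.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param windows a [GenomicRanges::GRanges] of regions to scan
#'   (typically from [summitWindows()]).
#' @param motif a [MotifMatrix-class].
#' @param threshold score threshold in bits, usually from
#'   [scoreThreshold()].
#' @param bothStrands scan the minus strand too (default TRUE; motif
#'   occurrence in double-stranded DNA).
#' @return data.frame of hits: `region_index` (1-based index into
#'   `windows`), `offset` (0-based match start within the region),
#'   `strand` ("+"/"-"), `score` (bits), ordered by region, offset,
#'   strand.
#' @export
scanRegions <- function(genome, windows, motif, threshold,
                        bothStrands = TRUE) {
  stopifnot(methods::is(motif, "MotifMatrix"))
  sizes <- genomeSizes(genome)
  emptyHits <- data.frame(region_index = integer(), offset = integer(),
                          strand = character(), score = numeric())
  if (length(windows) == 0L) return(emptyHits)
  checkPeaksAgainstSizes(windows, sizes)
  w <- motifWidth(motif)
  seqs <- extractRegionSeqs_(genome, windows)
  lens <- nchar(seqs)
  n <- length(seqs)
  sep <- strrep("N", w)
  big <- paste(seqs, collapse = sep)
  codes <- BASE_CODE_[utf8ToInt(big)]
  startIdx <- cumsum(c(1L, lens[-n] + w))  # 1-based region starts in big
  lo <- logOdds(motif)
  hits <- list(
    scanStrand_(codes, lo, threshold, startIdx, lens, "+"))
  if (bothStrands) {
    loRC <- lo[rev(seq_len(4L)), rev(seq_len(w)), drop = FALSE]
    rownames(loRC) <- DNA_BASES_
    hits[[2L]] <- scanStrand_(codes, loRC, threshold, startIdx, lens, "-")
  }
  out <- do.call(rbind, hits)
  if (nrow(out) == 0L) return(emptyHits)
  out <- out[order(out$region_index, out$offset, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# integer codes A=1 C=2 G=3 T=4, everything else (N) NA
BASE_CODE_ <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A")] <- 1L
  v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L
  v[utf8ToInt("T")] <- 4L
  v
})

scanStrand_ <- function(codes, lo, threshold, startIdx, lens, strand) {
  w <- ncol(lo)
  npos <- length(codes) - w + 1L
  if (npos < 1L)
    return(data.frame(region_index = integer(), offset = integer(),
                      strand = character(), score = numeric()))
  s <- lo[cbind(codes[seq_len(npos)], 1L)]
  for (i in seq_len(w - 1L)) {
    s <- s + lo[cbind(codes[(1L + i):(npos + i)], i + 1L)]
  }
  pos <- which(!is.na(s) & s >= threshold)
  if (length(pos) == 0L)
    return(data.frame(region_index = integer(), offset = integer(),
                      strand = character(), score = numeric()))
  region <- findInterval(pos, startIdx)
  offset <- pos - startIdx[region]
  # windows that start inside a separator or straddle one contain N and
  # were already excluded by the NA filter; remaining hits are in-region
  data.frame(region_index = region, offset = as.integer(offset),
             strand = strand, score = s[pos])
}

extractRegionSeqs_ <- function(genome, regions) {
  chrom <- as.character(GenomicRanges::seqnames(regions))
  out <- character(length(regions))
  for (ch in unique(chrom)) {
    ii <- which(chrom == ch)
    v <- Biostrings::Views(genome[[ch]],
                           start = GenomicRanges::start(regions)[ii],
                           end = GenomicRanges::end(regions)[ii])
    out[ii] <- as.character(v)
  }
  out
}

#' Summarize motif hits into an occurrence statistic
#'
#' x is the total number of motif occurrences over all regions in the
#' set — the observed value entering the enrichment Z-score. The number
#' of distinct hit-bearing regions is carried alongside as a secondary
#' descriptive column.
#'
#' @param hits data.frame from [scanRegions()].
#' @param windows the scanned regions ([GenomicRanges::GRanges]).
#' @param motifId motif identifier for the row.
#' @param setLabel foreground set label for the row.
#' @return one-row data.frame: motif_id, set_label, n_regions, x,
#'   regions_with_hit.
#' @export
occurrenceFrequency <- function(hits, windows, motifId, setLabel) {
  data.frame(
    motif_id = motifId,
    set_label = setLabel,
    n_regions = length(windows),
    x = nrow(hits),
    regions_with_hit = length(unique(hits$region_index)),
    stringsAsFactors = FALSE)
}

#' Export motif hits as BED6
#'
#' Hit coordinates are converted back to absolute 0-based half-open
#' genomic intervals; the BED score column is the bit score times 100,
#' rounded.
#'
#' @param hits data.frame from [scanRegions()].
#' @param windows the scanned regions the hits refer to.
#' @param motif the scanned [MotifMatrix-class] (for id and width).
#' @param path output BED file.
#' @export
writeHitsBed <- function(hits, windows, motif, path) {
  w <- motifWidth(motif)
  chrom <- as.character(GenomicRanges::seqnames(windows))[hits$region_index]
  start0 <- GenomicRanges::start(windows)[hits$region_index] - 1L +
    hits$offset
  df <- data.frame(chrom, start0, start0 + w, motifId(motif),
                   round(hits$score * 100), hits$strand)
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
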