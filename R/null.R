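#' @include AllClasses.R null-distribution.R scan.R
NULL

#' Sample length-matched random genomic regions
#'
#' The backbone of the empirical null: for each replicate and each
#' foreground region, one random region of identical length is drawn
#' from the genome — chromosome chosen with probability proportional to
#' its number of valid placements (length - region length + 1), start
#' uniform among them. Draws overlapping an optional exclusion set
#' (e.g. assembly gaps, or the foreground itself) are rejected and
#' redrawn, up to 1000 attempts per region. Replicates are mutually
#' independent; replicate i uses a deterministic RNG substream derived
#' from (seed, i), so increasing `nReps` never perturbs earlier
#' replicates.
#'
#' @param foreground a [GenomicRanges::GRanges]; only the lengths and
#'   their order matter.
#' @param genome a [Biostrings::DNAStringSet] (or a named sizes vector).
#' @param nReps number of replicate sets (>= 2). Default 100.
#' @param exclude optional [GenomicRanges::GRanges]; sampled regions
#'   overlapping it are redrawn.
#' @param seed integer RNG seed.
#' @return a list of `nReps` [GenomicRanges::GRanges] objects, each
#'   parallel to `foreground`.
#' @export
sampleMatchedRegions <- function(foreground, genome, nReps = 100L,
                                 exclude = NULL, seed = 1L) {
  nReps <- as.integer(nReps)
  if (nReps < 2L) stop("nReps must be >= 2 for an empirical null")
  sizes <- if (is.numeric(genome)) genome else genomeSizes(genome)
  lens <- GenomicRanges::width(foreground)
  if (any(lens > max(sizes)))
    stop("some foreground region is longer than every chromosome")
  lapply(seq_len(nReps), function(i) {
    withSeed_(subSeed_(seed, i),
              sampleOneReplicate_(lens, sizes, exclude))
  })
}

subSeed_ <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1e6 * 69069 + i * 7919) %% 2147483647)
}

sampleOneReplicate_ <- function(lens, sizes, exclude) {
  n <- length(lens)
  chromIdx <- integer(n)
  start0 <- integer(n)
  for (len in unique(lens)) {
    ii <- which(lens == len)
    valid <- pmax(as.numeric(sizes) - len + 1, 0)
    if (sum(valid) == 0)
      stop("no chromosome can hold a region of length ", len)
    chromIdx[ii] <- sample.int(length(sizes), length(ii),
                               replace = TRUE, prob = valid)
    start0[ii] <- floor(stats::runif(length(ii)) * valid[chromIdx[ii]])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = names(sizes)[chromIdx],
    ranges = IRanges::IRanges(start = start0 + 1L, width = lens))
  if (!is.null(exclude) && length(exclude) > 0L) {
    for (attempt in seq_len(1000L)) {
      bad <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr, exclude, ignore.strand = TRUE)))
      if (length(bad) == 0L) break
      if (attempt == 1000L)
        stop("rejection sampling exhausted after 1000 attempts for ",
             length(bad), " region(s); is the exclusion set too dense?")
      valid <- pmax(as.numeric(sizes) - lens[bad] + 1, 0)
      for (j in bad) {
        v <- pmax(as.numeric(sizes) - lens[j] + 1, 0)
        ci <- sample.int(length(sizes), 1L, prob = v)
        s0 <- floor(stats::runif(1L) * v[ci])
        gr[j] <- GenomicRanges::GRanges(
          names(sizes)[ci], IRanges::IRanges(start = s0 + 1L,
                                             width = lens[j]))
      }
    }
  }
  gr
}

#' Build the empirical null distribution of a motif's occurrence count
#'
#' Each replicate set of random regions is scanned exactly as the
#' foreground windows were (same motif, threshold and strand setting;
#' no summit re-windowing — the replicates already have the foreground
#' window lengths) and the per-replicate occurrence counts give the
#' null mean and sample standard deviation. All replicates are scanned
#' in one batch for speed; the result is identical to scanning them
#' one by one.
#'
#' @param replicateSets list of [GenomicRanges::GRanges] from
#'   [sampleMatchedRegions()].
#' @param genome a [Biostrings::DNAStringSet].
#' @param motif a [MotifMatrix-class].
#' @param threshold score threshold in bits (same as the foreground
#'   scan).
#' @param bothStrands same strand setting as the foreground scan.
#' @return a [NullDistribution-class].
#' @export
buildNull <- function(replicateSets, genome, motif, threshold,
                      bothStrands = TRUE) {
  nReps <- length(replicateSets)
  if (nReps < 2L) stop("need at least 2 replicate sets")
  sizesPer <- vapply(replicateSets, length, integer(1))
  combined <- do.call(c, lapply(replicateSets, function(g) {
    S4Vectors::mcols(g) <- NULL
    g
  }))
  hits <- scanRegions(genome, combined, motif, threshold,
                      bothStrands = bothStrands)
  rep_of_region <- rep(seq_len(nReps), sizesPer)
  counts <- tabulate(rep_of_region[hits$region_index], nbins = nReps)
  NullDistribution(motifId(motif), counts)
}

#' Enrichment Z-score against an empirical null
#'
#' z = (x - mu) / sigma with mu and sigma the mean and sample standard
#' deviation of the null replicate counts. When sigma = 0 the statistic
#' is undefined; the result is flagged degenerate and z is NA rather
#' than dividing by zero.
#'
#' @param x observed occurrence count (the `x` column of
#'   [occurrenceFrequency()]).
#' @param null a [NullDistribution-class].
#' @return list with `x`, `mu`, `sigma`, `z` (NA when degenerate) and
#'   `degenerate` (logical).
#' @examples
#' zScore(8, NullDistribution("m", c(2, 4, 6)))$z  # (8 - 4) / 2 = 2
#' @export
zScore <- function(x, null) {
  stopifnot(methods::is(null, "NullDistribution"))
  mu <- nullMu(null)
  sigma <- nullSigma(null)
  degenerate <- sigma == 0
  list(x = x, mu = mu, sigma = sigma,
       z = if (degenerate) NA_real_ else (x - mu) / sigma,
       degenerate = degenerate)
}

#' Empirical p-value of an observed count under the null
#'
#' The add-one permutation p-value p = (1 + #\{replicates with count >=
#' x\}) / (nReps + 1); never zero, at most 1. A distribution-free
#' complement to the Z-score that does not assume a normal null.
#'
#' @inheritParams zScore
#' @return p in (0, 1].
#' @export
empiricalPvalue <- function(x, null) {
  stopifnot(methods::is(null, "NullDistribution"))
  counts <- replicateCounts(null)
  (1 + sum(counts >= x)) / (length(counts) + 1)
}

#' Benjamini-Hochberg adjustment across motifs
#'
#' Standard step-up FDR adjustment, applied across the motifs of one
#' foreground set (each peak-set analysis is its own family).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
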