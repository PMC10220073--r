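#' @include AllClasses.R io-peaks.R
NULL

#' Extract fixed-width windows around peak summits
#'
#' Each peak is reduced to the window of `window` bases centred on its
#' summit: in 0-based half-open terms `[summit - window/2,
#' summit + window/2)`, clipped to the chromosome. The summit is the
#' narrowPeak point-source (`summitOffset` metadata column) when
#' present, else the region midpoint (integer division) — the only
#' principled fallback for plain BED input. Windows touching a
#' chromosome edge are clipped rather than dropped, so `n_regions` is
#' never silently reduced; duplicate windows (identical chromosome,
#' start and end) are collapsed to one, keeping input order of first
#' occurrence. Clip and collapse counts and the number of midpoint
#' fallbacks are recorded in `metadata()` of the result.
#'
#' @param peaks a [GenomicRanges::GRanges], optionally with a
#'   `summitOffset` metadata column (0-based offset from region start).
#' @param window total window width in bases; even, >= 2. Default 200.
#' @param sizes named chromosome lengths ([genomeSizes()] or
#'   [readChromSizes()]).
#' @return A [GenomicRanges::GRanges] of windows; `metadata()` holds
#'   `collapsed`, `clipped` and `midpointFallback` counts.
#' @examples
#' # a peak at 0-based [500, 900) with summit offset 200 and a 200-bp
#' # window yields the 0-based window [600, 800)
#' @export
summitWindows <- function(peaks, window = 200L, sizes) {
  window <- as.integer(window)
  if (window < 2L || window %% 2L != 0L)
    stop("window must be an even integer >= 2")
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  missing <- setdiff(unique(chrom), names(sizes))
  if (length(missing))
    stop("chromosome(s) absent from sizes: ",
         paste(missing, collapse = ", "))
  start0 <- GenomicRanges::start(peaks) - 1L
  len <- GenomicRanges::width(peaks)
  mc <- S4Vectors::mcols(peaks)
  so <- if ("summitOffset" %in% names(mc)) mc$summitOffset
        else rep(NA_integer_, length(peaks))
  fallback <- is.na(so)
  summit0 <- start0 + ifelse(fallback, len %/% 2L, so)
  half <- window %/% 2L
  w0 <- pmax(summit0 - half, 0L)
  w1 <- pmin(summit0 + half, as.integer(sizes[chrom]))
  clipped <- sum(w1 - w0 < window)
  key <- paste(chrom, w0, w1, sep = ":")
  first <- !duplicated(key)
  collapsed <- sum(!first)
  out <- GenomicRanges::GRanges(
    seqnames = chrom[first],
    ranges = IRanges::IRanges(start = as.integer(w0[first]) + 1L,
                              end = as.integer(w1[first])))
  S4Vectors::metadata(out) <- list(
    collapsed = collapsed,
    clipped = clipped,
    midpointFallback = sum(fallback),
    window = window)
  out
}
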