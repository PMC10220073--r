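#' @include AllClasses.R
NULL

#' Read peak calls from BED or ENCODE narrowPeak into a GRanges
#'
#' File coordinates are BED-convention 0-based half-open and are
#' converted to the 1-based closed GRanges convention on the way in
#' ([writePeaks()] inverts the conversion, so a narrowPeak record
#' round-trips unchanged). For narrowPeak the 10th column (point-source
#' peak offset) becomes the metadata column `summitOffset`: the 0-based
#' offset of the summit from the region start, `NA` when the file holds
#' the sentinel -1.
#'
#' @param path tab-separated peak file.
#' @param dialect `"bed"` (>= 3 columns) or `"narrowPeak"` (exactly 10).
#' @param label free-text provenance label attached as
#'   `metadata(gr)$label` (defaults to the file name).
#' @return A [GenomicRanges::GRanges] with metadata columns `name`,
#'   `score` and `summitOffset`.
#' @export
readPeaks <- function(path, dialect = c("narrowPeak", "bed"),
                      label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no peak records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  need <- if (dialect == "narrowPeak") 10L else 3L
  bad <- which(ncols < need)
  if (length(bad))
    stop(sprintf("%s line %d: expected >= %d tab-separated columns, got %d",
                 path, lineno[bad[1L]], need, ncols[bad[1L]]))
  if (dialect == "narrowPeak" && any(ncols != 10L)) {
    b <- which(ncols != 10L)[1L]
    stop(sprintf("%s line %d: narrowPeak requires exactly 10 columns, got %d",
                 path, lineno[b], ncols[b]))
  }
  getcol <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[[i]] else NA_character_, character(1))
  chrom <- getcol(1L)
  start0 <- suppressWarnings(as.numeric(getcol(2L)))
  end0 <- suppressWarnings(as.numeric(getcol(3L)))
  badRow <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("%s line %d: %s", path, lineno[i[1L]], what))
  }
  badRow(is.na(start0) | is.na(end0) |
           start0 != floor(start0) | end0 != floor(end0),
         "non-integer coordinates")
  badRow(start0 < 0, "negative start coordinate")
  badRow(start0 >= end0, "start >= end")
  name <- if (max(ncols) >= 4L) getcol(4L) else NA_character_
  score <- if (max(ncols) >= 5L)
    suppressWarnings(as.numeric(getcol(5L))) else NA_real_
  summit <- rep(NA_integer_, length(chrom))
  if (dialect == "narrowPeak") {
    sm <- suppressWarnings(as.numeric(getcol(10L)))
    badRow(is.na(sm) | sm != floor(sm), "non-integer summit offset")
    badRow(sm != -1 & (sm < 0 | sm >= end0 - start0),
           "summit offset outside the region")
    summit <- ifelse(sm == -1, NA_integer_, as.integer(sm))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start0) + 1L,
                              end = as.integer(end0)),
    name = name, score = score, summitOffset = summit)
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Write a GRanges peak set as BED or narrowPeak
#'
#' Inverse of [readPeaks()]: GRanges 1-based closed coordinates go out
#' as 0-based half-open, `summitOffset` `NA` goes out as the narrowPeak
#' sentinel -1.
#'
#' @param peaks a [GenomicRanges::GRanges]; metadata columns `name`,
#'   `score`, `summitOffset` are used when present.
#' @param path output file.
#' @param dialect `"narrowPeak"` (10 columns) or `"bed"` (6 columns).
#' @export
writePeaks <- function(peaks, path, dialect = c("narrowPeak", "bed")) {
  dialect <- match.arg(dialect)
  n <- length(peaks)
  mc <- S4Vectors::mcols(peaks)
  nm <- if ("name" %in% names(mc) && !all(is.na(mc$name)))
    as.character(mc$name) else sprintf("peak_%d", seq_len(n))
  nm[is.na(nm)] <- "."
  sc <- if ("score" %in% names(mc)) mc$score else rep(0, n)
  sc[is.na(sc)] <- 0
  start0 <- GenomicRanges::start(peaks) - 1L
  end0 <- GenomicRanges::end(peaks)
  if (dialect == "bed") {
    df <- data.frame(as.character(GenomicRanges::seqnames(peaks)),
                     start0, end0, nm, sc, ".")
  } else {
    summit <- if ("summitOffset" %in% names(mc))
      ifelse(is.na(mc$summitOffset), -1L, as.integer(mc$summitOffset))
    else rep(-1L, n)
    df <- data.frame(as.character(GenomicRanges::seqnames(peaks)),
                     start0, end0, nm, sc, ".", 0, -1, -1, summit)
  }
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Check that every peak lies inside its chromosome; used by the scanning
# and sampling stages before touching sequence.
checkPeaksAgainstSizes <- function(peaks, sizes) {
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  missing <- setdiff(unique(chrom), names(sizes))
  if (length(missing))
    stop("chromosome(s) absent from genome: ",
         paste(missing, collapse = ", "))
  over <- GenomicRanges::end(peaks) > sizes[chrom]
  if (any(over))
    stop(sum(over), " region(s) extend beyond their chromosome end")
  invisible(TRUE)
}
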