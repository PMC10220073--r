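#' @include AllClasses.R
NULL

#' Read a genome FASTA into a DNAStringSet
#'
#' Sequences are uppercased and any character outside A/C/G/T/N
#' (IUPAC ambiguity codes, soft-mask leftovers, stray symbols) is
#' replaced by N; the total number of substitutions is reported in a
#' warning so masked or ambiguous assemblies are usable without
#' silently inventing scores for them (the scanner skips N windows).
#'
#' @param path FASTA file, plain or line-wrapped, multi-record.
#' @return A [Biostrings::DNAStringSet] with unique names; chromosome
#'   sizes are `width()` of the result.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    stop("empty FASTA file: ", path)
  if (!startsWith(first, ">"))
    stop("not FASTA: first line does not start with '>' in ", path,
         " (got: ", substr(first, 1, 40), ")")
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stop("no FASTA records in ", path)
  # headers: keep the first whitespace-delimited token as the name
  nm <- sub("\\s.*$", "", names(raw))
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate FASTA header(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(raw))
  nonacgtn <- sum(vapply(seqs, function(s)
    nchar(gsub("[ACGTN]", "", s)), numeric(1)))
  if (nonacgtn > 0) {
    seqs <- vapply(seqs, function(s)
      gsub("[^ACGTN]", "N", s), character(1))
    warning(sprintf("%d non-ACGTN character(s) replaced by N", nonacgtn))
  }
  out <- Biostrings::DNAStringSet(unname(seqs))
  names(out) <- nm
  out
}

#' Write a genome to FASTA
#'
#' @param genome a [Biostrings::DNAStringSet] with names.
#' @param path output file.
#' @param width line-wrap width.
#' @export
writeGenome <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(genome, filepath = path, width = width)
  invisible(path)
}

#' Chromosome sizes of a genome
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @return named integer vector of sequence lengths.
#' @export
genomeSizes <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Read / write a two-column chrom.sizes table (name, length)
#'
#' @param path TSV file with columns name and length, no header.
#' @return named integer vector.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "length"),
                          colClasses = c("character", "integer"))
  if (anyDuplicated(df$name))
    stop("duplicate chromosome name in ", path)
  if (any(df$length <= 0))
    stop("non-positive chromosome length in ", path)
  stats::setNames(df$length, df$name)
}

#' @rdname readChromSizes
#' @param sizes named integer vector of chromosome lengths.
#' @export
writeChromSizes <- function(sizes, path) {
  utils::write.table(
    data.frame(name = names(sizes), length = as.integer(sizes)),
    file = path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}
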