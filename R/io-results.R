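#' @include AllClasses.R null-distribution.R
NULL

#' Write / read an enrichment result table as TSV
#'
#' Fixed 13-column layout (motif_id, set_label, n_regions, x, mu, sigma,
#' z, p_empirical, q_bh, n_reps, window, threshold_pvalue, seed); floats
#' are printed with 6 significant digits, so a written table read back
#' with [readResults()] reproduces the original up to that precision.
#' Run metadata carried in the object is recoverable from the metadata
#' columns (n_reps, window, threshold_pvalue, seed).
#'
#' @param x a [MotifEnrichment-class].
#' @param path output TSV path.
#' @export
writeResults <- function(x, path) {
  stopifnot(methods::is(x, "MotifEnrichment"))
  df <- x@results[, RESULT_COLUMNS_, drop = FALSE]
  fmt <- df
  for (col in c("x", "mu", "sigma", "z", "p_empirical", "q_bh",
                "threshold_pvalue")) {
    v <- df[[col]]
    fmt[[col]] <- ifelse(is.na(v), "NA", sprintf("%.6g", v))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(RESULT_COLUMNS_, collapse = "\t"), con)
  if (nrow(fmt) > 0L) {
    body <- do.call(paste, c(lapply(fmt, as.character), list(sep = "\t")))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname writeResults
#' @return `readResults` returns a [MotifEnrichment-class] rebuilt from
#'   the file.
#' @export
readResults <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(
                            motif_id = "character",
                            set_label = "character",
                            n_regions = "integer",
                            x = "numeric", mu = "numeric",
                            sigma = "numeric", z = "numeric",
                            p_empirical = "numeric", q_bh = "numeric",
                            n_reps = "integer", window = "integer",
                            threshold_pvalue = "numeric",
                            seed = "integer"),
                          na.strings = "NA")
  if (!identical(names(df), RESULT_COLUMNS_))
    stop("unexpected result-table columns in ", path)
  meta <- if (nrow(df) > 0L)
    list(n_reps = df$n_reps[1L], window = df$window[1L],
         threshold_pvalue = df$threshold_pvalue[1L], seed = df$seed[1L])
  else list()
  methods::new("MotifEnrichment", results = df, metadata = meta)
}

#' Export null replicate counts for audit
#'
#' @param nulls named list of [NullDistribution-class] objects.
#' @param path output TSV (motif_id, replicate_index, count).
#' @export
writeNullCounts <- function(nulls, path) {
  rows <- lapply(nulls, function(nd)
    data.frame(motif_id = motifId(nd),
               replicate_index = seq_along(replicateCounts(nd)),
               count = replicateCounts(nd)))
  df <- do.call(rbind, rows)
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
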