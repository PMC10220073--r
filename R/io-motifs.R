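#' @include AllClasses.R motif-matrix.R
NULL

#' Read motif matrices from JASPAR PFM or MEME minimal files
#'
#' JASPAR PFM: records start with `>ID NAME`, followed by four count
#' rows in A, C, G, T order, either bare numbers or the bracketed
#' `A [ 1 2 3 ]` style. MEME minimal: `MOTIF` blocks with a
#' `letter-probability matrix` whose probability rows are converted to
#' counts by multiplying by the stated `nsites` (100 when absent), so
#' both formats share one internal count representation.
#'
#' @param path motif file.
#' @param format `"jaspar_pfm"` or `"meme_minimal"`.
#' @param background numeric(4) background probabilities (A,C,G,T). The
#'   default `NULL` uses the background stated in a MEME file when
#'   present, else uniform.
#' @param pseudocountTotal total pseudocount per column (default 0.1).
#' @return list of [MotifMatrix-class] objects, named by motif id.
#' @export
readMotifs <- function(path, format = c("jaspar_pfm", "meme_minimal"),
                       background = NULL, pseudocountTotal = 0.1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  motifs <- switch(format,
    jaspar_pfm = parseJaspar(lines, background, pseudocountTotal, path),
    meme_minimal = parseMemeMinimal(lines, background, pseudocountTotal, path))
  if (length(motifs) == 0L) stop("no motifs found in ", path)
  stats::setNames(motifs, vapply(motifs, motifId, character(1)))
}

parseJaspar <- function(lines, background, pseudocountTotal, path) {
  if (is.null(background)) background <- rep(0.25, 4)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no JASPAR '>' headers in ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  lapply(seq_along(hdr), function(k) {
    head_ <- sub("^>\\s*", "", lines[hdr[k]])
    toks <- strsplit(trimws(head_), "\\s+")[[1]]
    id <- toks[1L]
    name <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else ""
    body <- lines[seq(hdr[k] + 1L, ends[k])]
    body <- body[nzchar(trimws(body))]
    if (length(body) < 4L)
      stop("motif ", id, ": expected 4 base rows, got ", length(body))
    body <- body[1:4]
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ \t]*[ACGTacgt][ \t:|]*", "", ln)
      ln <- gsub("[][]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (anyNA(vals))
        stop("motif ", id, ": non-numeric count row: ", ln)
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("motif ", id, ": base rows have unequal lengths (",
           paste(lens, collapse = ", "), ")")
    cnt <- do.call(rbind, rows)
    rownames(cnt) <- DNA_BASES_
    if (any(cnt < 0))
      stop("motif ", id, ": negative count")
    MotifMatrix(id, cnt, background = background,
                pseudocountTotal = pseudocountTotal, motifName = name)
  })
}

parseMemeMinimal <- function(lines, background, pseudocountTotal, path) {
  fileBg <- NULL
  bgLine <- grep("^Background letter frequencies", lines)
  if (length(bgLine)) {
    toks <- strsplit(trimws(lines[bgLine[1L] + 1L]), "\\s+")[[1]]
    if (length(toks) >= 8L) {
      vals <- suppressWarnings(as.numeric(toks[c(2, 4, 6, 8)]))
      if (!anyNA(vals) && identical(toupper(toks[c(1, 3, 5, 7)]), DNA_BASES_))
        fileBg <- vals
    }
  }
  if (is.null(background))
    background <- if (is.null(fileBg)) rep(0.25, 4) else fileBg
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) stop("no MOTIF blocks in ", path)
  lapply(starts, function(s) {
    toks <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    id <- toks[2L]
    name <- if (length(toks) > 2L) paste(toks[-(1:2)], collapse = " ") else ""
    rel <- grep("letter-probability matrix", lines[s:length(lines)])[1L]
    if (is.na(rel))
      stop("motif ", id, ": missing letter-probability matrix header")
    hdrLine <- lines[s + rel - 1L]
    getAttr <- function(key, default) {
      m <- regmatches(hdrLine,
                      regexpr(paste0(key, "=\\s*[0-9.eE+-]+"), hdrLine))
      if (length(m)) as.numeric(sub(paste0(key, "=\\s*"), "", m)) else default
    }
    w <- getAttr("w", NA_real_)
    nsites <- getAttr("nsites", 100)
    i <- s + rel
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (!nzchar(ln) || grepl("^(MOTIF|URL)", ln)) break
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (anyNA(vals) || length(vals) != 4L) break
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    if (length(rows) == 0L)
      stop("motif ", id, ": empty probability matrix")
    if (!is.na(w) && length(rows) != w)
      stop("motif ", id, ": matrix has ", length(rows),
           " rows but header says w=", w)
    probs <- do.call(cbind, rows)  # 4 x width, rows A,C,G,T
    if (any(probs < 0))
      stop("motif ", id, ": negative probability")
    cnt <- probs * nsites
    rownames(cnt) <- DNA_BASES_
    MotifMatrix(id, cnt, background = background,
                pseudocountTotal = pseudocountTotal, motifName = name)
  })
}

#' Write motifs as a JASPAR PFM file
#'
#' @param motifs list of [MotifMatrix-class] objects.
#' @param path output file.
#' @export
writeMotifsJaspar <- function(motifs, path) {
  if (methods::is(motifs, "MotifMatrix")) motifs <- list(motifs)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    nm <- if (nzchar(m@motifName)) paste0(" ", m@motifName) else ""
    writeLines(paste0(">", motifId(m), nm), con)
    cnt <- motifCounts(m)
    for (b in seq_len(4L)) {
      writeLines(sprintf("%s  [ %s ]", DNA_BASES_[b],
                         paste(format(cnt[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}
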