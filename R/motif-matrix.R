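#' @include AllClasses.R AllGenerics.R
NULL

DNA_BASES_ <- c("A", "C", "G", "T")
COMPLEMENT_ <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct a MotifMatrix from a position frequency matrix
#'
#' Builds the motif object and derives its log-odds score matrix against
#' the background model. The total pseudocount is distributed across
#' bases in proportion to their background frequency before the odds
#' ratio is taken, the common practice in PWM scanners; with
#' `pseudocountTotal = 0` a zero count yields a -Inf log-odds entry
#' (the base is forbidden at that position).
#'
#' @param motifId identifier string.
#' @param counts 4 x width matrix of nonnegative base counts. Rows may be
#'   named A,C,G,T in any order (they are reordered); unnamed rows are
#'   taken to be in A,C,G,T order.
#' @param background numeric(4) base probabilities (A,C,G,T), summing
#'   to 1. Default uniform.
#' @param pseudocountTotal total pseudocount added per column,
#'   distributed by background frequency. Default 0.1.
#' @param motifName optional display name.
#'
#' @return A [MotifMatrix-class] object.
#'
#' @examples
#' pfm <- matrix(c(4, 0, 0, 0,
#'                 0, 4, 0, 0), nrow = 4,
#'               dimnames = list(c("A", "C", "G", "T"), NULL))
#' m <- MotifMatrix("toy", pfm, pseudocountTotal = 0)
#' logOdds(m)[1, 1]  # log2((4/4)/0.25) = 2 bits
#' @export
MotifMatrix <- function(motifId, counts,
                        background = rep(0.25, 4),
                        pseudocountTotal = 0.1,
                        motifName = "") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("counts must have 4 rows (A, C, G, T)")
  if (is.null(rownames(counts))) {
    rownames(counts) <- DNA_BASES_
  } else {
    if (!setequal(rownames(counts), DNA_BASES_))
      stop("counts rownames must be A, C, G, T")
    counts <- counts[DNA_BASES_, , drop = FALSE]
  }
  storage.mode(counts) <- "double"
  background <- as.numeric(background)
  lo <- computeLogOdds(counts, background, pseudocountTotal)
  methods::new("MotifMatrix",
    motifId = as.character(motifId),
    motifName = as.character(motifName),
    counts = counts,
    background = background,
    pseudocountTotal = as.numeric(pseudocountTotal),
    logOdds = lo
  )
}

computeLogOdds <- function(counts, background, pseudocountTotal) {
  w <- ncol(counts)
  tot <- colSums(counts) + pseudocountTotal
  prob <- (counts + pseudocountTotal * background) /
    rep(tot, each = 4L)
  lo <- log2(prob / background)
  dimnames(lo) <- dimnames(counts)
  lo
}

#' Per-column base probabilities of a motif
#'
#' The pseudocounted emission probabilities used both for log-odds
#' scoring and for sampling motif instances in the synthetic-data
#' generator.
#'
#' @param x a [MotifMatrix-class].
#' @return 4 x width matrix of probabilities (columns sum to 1).
#' @export
motifProbabilities <- function(x) {
  stopifnot(methods::is(x, "MotifMatrix"))
  tot <- colSums(x@counts) + x@pseudocountTotal
  p <- (x@counts + x@pseudocountTotal * x@background) /
    rep(tot, each = 4L)
  dimnames(p) <- dimnames(x@counts)
  p
}

#' @describeIn MotifMatrix-class motif identifier
#' @param x a MotifMatrix
#' @export
setMethod("motifId", "MotifMatrix", function(x) x@motifId)

#' @describeIn MotifMatrix-class motif width in bases
#' @export
setMethod("motifWidth", "MotifMatrix", function(x) ncol(x@counts))

#' @describeIn MotifMatrix-class the 4 x width count matrix
#' @export
setMethod("motifCounts", "MotifMatrix", function(x) x@counts)

#' @describeIn MotifMatrix-class background base probabilities (A,C,G,T)
#' @export
setMethod("motifBackground", "MotifMatrix", function(x) x@background)

#' @describeIn MotifMatrix-class the derived 4 x width log-odds matrix (bits)
#' @export
setMethod("logOdds", "MotifMatrix", function(x) x@logOdds)

#' @describeIn MotifMatrix-class best achievable window score (bits)
#' @export
setMethod("maxScore", "MotifMatrix",
          function(x) sum(apply(x@logOdds, 2L, max)))

#' @describeIn MotifMatrix-class worst achievable window score (bits)
#' @export
setMethod("minScore", "MotifMatrix",
          function(x) sum(apply(x@logOdds, 2L, min)))

#' @describeIn MotifMatrix-class reverse complement: complement the base
#'   rows and reverse the column order, for minus-strand scanning
#' @importMethodsFrom Biostrings reverseComplement
#' @export
setMethod("reverseComplement", "MotifMatrix", function(x, ...) {
  rc <- x@counts[rev(seq_len(4L)), rev(seq_len(ncol(x@counts))), drop = FALSE]
  rownames(rc) <- DNA_BASES_
  bg <- x@background[rev(seq_len(4L))]
  MotifMatrix(x@motifId, rc, background = bg,
              pseudocountTotal = x@pseudocountTotal,
              motifName = x@motifName)
})

#' @describeIn MotifMatrix-class permute the column order (a decoy motif
#'   with identical base composition and information content); `seed`
#'   makes the permutation reproducible
#' @param seed integer seed for the permutation
#' @export
setMethod("shuffleColumns", "MotifMatrix", function(x, seed) {
  w <- ncol(x@counts)
  perm <- withSeed_(as.integer(seed), sample.int(w))
  # force a derangement-ish shuffle: retry while identity and w > 1
  k <- 0L
  while (w > 1L && identical(perm, seq_len(w)) && k < 100L) {
    k <- k + 1L
    perm <- withSeed_(as.integer(seed) + k, sample.int(w))
  }
  MotifMatrix(paste0(x@motifId, "_shuffled"),
              x@counts[, perm, drop = FALSE],
              background = x@background,
              pseudocountTotal = x@pseudocountTotal,
              motifName = x@motifName)
})

#' @describeIn MotifMatrix-class majority-base consensus string
#' @importMethodsFrom Biostrings consensusString
#' @export
setMethod("consensusString", "MotifMatrix", function(x, ...) {
  paste(DNA_BASES_[apply(x@counts, 2L, which.max)], collapse = "")
})

setMethod("show", "MotifMatrix", function(object) {
  cat(sprintf("MotifMatrix %s%s: width %d, max score %.2f bits\n",
              object@motifId,
              if (nzchar(object@motifName))
                paste0(" (", object@motifName, ")") else "",
              ncol(object@counts), maxScore(object)))
  cat(sprintf("  consensus %s, pseudocount %.3g, background %s\n",
              consensusString(object), object@pseudocountTotal,
              paste(sprintf("%.3g", object@background), collapse = "/")))
})

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
withSeed_ <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
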