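#' MotifMatrix: a position frequency matrix with derived log-odds scores
#'
#' A transcription-factor binding motif held as per-position base counts
#' (rows A, C, G, T; one column per motif position), together with the
#' background base distribution and a total pseudocount. The log-odds
#' score matrix is derived deterministically from these three pieces:
#'
#' \deqn{LO[b,i] = \log_2\frac{(n_{b,i} + c\,\pi_b)/(N_i + c)}{\pi_b}}
#'
#' where \eqn{n_{b,i}} is the count of base b at position i, \eqn{N_i}
#' the column total, \eqn{\pi_b} the background probability and c the
#' total pseudocount (distributed by background frequency). Scores are
#' in bits; a window's score is the sum of its per-position entries.
#'
#' @slot motifId single identifier string.
#' @slot motifName optional human-readable name ("" when absent).
#' @slot counts 4 x width numeric matrix, rownames A,C,G,T, nonnegative.
#' @slot background numeric(4) probabilities summing to 1 (A,C,G,T).
#' @slot pseudocountTotal single nonnegative numeric.
#' @slot logOdds 4 x width numeric matrix of log2 odds (bits); entries are
#'   -Inf where a base has zero probability after pseudocounting.
#'
#' @seealso [MotifMatrix()] for the user constructor, [scoreThreshold()],
#'   [scanRegions()].
#' @export
setClass("MotifMatrix",
  representation(
    motifId = "character",
    motifName = "character",
    counts = "matrix",
    background = "numeric",
    pseudocountTotal = "numeric",
    logOdds = "matrix"
  )
)

setValidity("MotifMatrix", function(object) {
  msg <- character()
  if (length(object@motifId) != 1L || !nzchar(object@motifId))
    msg <- c(msg, "motifId must be a single non-empty string")
  cnt <- object@counts
  if (nrow(cnt) != 4L || ncol(cnt) < 1L)
    msg <- c(msg, "counts must be a 4 x width matrix with width >= 1")
  if (!identical(rownames(cnt), DNA_BASES_))
    msg <- c(msg, "counts rownames must be A, C, G, T")
  if (any(!is.finite(cnt)) || any(cnt < 0))
    msg <- c(msg, "counts must be finite and nonnegative")
  bg <- object@background
  if (length(bg) != 4L || any(bg <= 0) || abs(sum(bg) - 1) > 1e-6)
    msg <- c(msg, "background must be 4 positive probabilities summing to 1")
  if (length(object@pseudocountTotal) != 1L || object@pseudocountTotal < 0)
    msg <- c(msg, "pseudocountTotal must be a single nonnegative number")
  if (ncol(cnt) >= 1L) {
    tot <- colSums(cnt) + object@pseudocountTotal
    if (any(tot <= 0))
      msg <- c(msg, "each counts column total must be positive after pseudocount addition")
  }
  if (!identical(dim(object@logOdds), dim(cnt)))
    msg <- c(msg, "logOdds must have the same dimensions as counts")
  if (length(msg)) msg else TRUE
})

#' NullDistribution: the empirical null of a motif's occurrence count
#'
#' Holds the per-replicate occurrence counts of one motif over repeated
#' sets of length-matched random genomic regions, together with their
#' mean \eqn{\mu} and sample standard deviation \eqn{\sigma}
#' (denominator n - 1). These are the null parameters of the enrichment
#' Z-score \eqn{z = (x - \mu)/\sigma}.
#'
#' @slot motifId motif identifier the null was built for.
#' @slot counts numeric vector of per-replicate occurrence counts
#'   (length >= 2).
#' @slot mu mean of `counts`.
#' @slot sigma sample standard deviation of `counts` (n - 1 denominator).
#'
#' @seealso [NullDistribution()], [buildNull()], [zScore()].
#' @export
setClass("NullDistribution",
  representation(
    motifId = "character",
    counts = "numeric",
    mu = "numeric",
    sigma = "numeric"
  )
)

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (length(object@counts) < 2L)
    msg <- c(msg, "need at least 2 replicate counts")
  if (any(!is.finite(object@counts)))
    msg <- c(msg, "replicate counts must be finite")
  if (length(object@counts) >= 2L) {
    if (abs(object@mu - mean(object@counts)) > 1e-8)
      msg <- c(msg, "mu must equal mean(counts)")
    if (abs(object@sigma - stats::sd(object@counts)) > 1e-8)
      msg <- c(msg, "sigma must equal sd(counts) (n-1 denominator)")
  }
  if (length(msg)) msg else TRUE
})

#' MotifEnrichment: per-motif enrichment results with run metadata
#'
#' One row per motif per foreground peak set: the observed occurrence
#' count x, the empirical null mean and standard deviation, the Z-score,
#' a distribution-free empirical p-value and a Benjamini-Hochberg
#' adjusted q-value. Run metadata (seed, replicate count, window width,
#' score threshold p-value) travels with the table and round-trips
#' through [writeResults()]/[readResults()].
#'
#' @slot results data.frame with columns motif_id, set_label, n_regions,
#'   x, mu, sigma, z, p_empirical, q_bh, n_reps, window, threshold_pvalue,
#'   seed. `z` is NA for degenerate motifs (sigma = 0).
#' @slot metadata named list of run provenance (resolved configuration,
#'   collapse/clip counts, degenerate motif ids, ...).
#'
#' @seealso [runEnrichment()], [writeResults()].
#' @export
setClass("MotifEnrichment",
  representation(
    results = "data.frame",
    metadata = "list"
  )
)

RESULT_COLUMNS_ <- c(
  "motif_id", "set_label", "n_regions", "x", "mu", "sigma", "z",
  "p_empirical", "q_bh", "n_reps", "window", "threshold_pvalue", "seed"
)

setValidity("MotifEnrichment", function(object) {
  if (!all(RESULT_COLUMNS_ %in% names(object@results)))
    return(paste("results must contain columns:",
                 paste(RESULT_COLUMNS_, collapse = ", ")))
  TRUE
})
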