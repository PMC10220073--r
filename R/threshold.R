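#' @include AllClasses.R motif-matrix.R
NULL

# Lattice resolution for the exact score-distribution DP: log-odds are
# rounded to 1e-3 bits. -Inf entries (zero probability under a zero
# pseudocount) are clamped to -30 bits on the lattice only; they can
# never participate in a practically useful threshold but must retain
# their probability mass for large alpha.
LATTICE_ <- 1000
LATTICE_FLOOR_ <- -30 * LATTICE_

#' Exact score threshold for a match p-value
#'
#' Computes the smallest achievable log-odds score t such that a random
#' window drawn from the background model scores >= t with probability
#' at most `alpha` — the "match at p-value < alpha" definition used by
#' standard PWM scanners, here computed exactly rather than estimated.
#' The full null score distribution is obtained by dynamic programming:
#' log-odds entries are rounded to a 1e-3-bit lattice and the
#' distribution is convolved position by position under the background
#' base probabilities, so runtime is linear in width times score span
#' regardless of 4^width.
#'
#' @param motif a [MotifMatrix-class].
#' @param alpha match p-value in (0, 1). Default 1e-4, the conventional
#'   scanner default.
#' @return threshold in bits — always a score some window actually
#'   achieves (the DP carries the minimum exact score reaching each
#'   lattice bin, so discretization never returns an unattainable
#'   cutoff). If even the single best score has probability > alpha,
#'   the maximum achievable score plus one lattice step is returned, so
#'   nothing matches.
#' @examples
#' # width-1 motif with log-odds (2, -1, -1, -1) and uniform background:
#' # only A reaches score 2, with probability 0.25, so alpha = 0.25
#' # gives threshold 2.
#' @export
scoreThreshold <- function(motif, alpha = 1e-4) {
  stopifnot(methods::is(motif, "MotifMatrix"))
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must be strictly inside (0, 1)")
  d <- scoreDistribution_(motif)
  tail <- rev(cumsum(rev(d$prob)))
  ok <- d$prob > 0 & tail <= alpha + 1e-9
  if (!any(ok))
    return(maxScore(motif) + 1 / LATTICE_)
  min(d$minExact[ok])
}

# Exact lattice score distribution of a background-random window.
# Returns integer lattice scores, their probabilities, and the minimum
# exact (unrounded) log-odds sum among sequences landing in each bin —
# accumulated in the same left-to-right column order the scanner uses,
# so the value is bit-for-bit a score the scanner can produce.
scoreDistribution_ <- function(motif) {
  Li <- latticeLogOdds_(motif)
  lo <- logOdds(motif)
  bg <- motifBackground(motif)
  w <- ncol(Li)
  colMin <- apply(Li, 2L, min)
  colMax <- apply(Li, 2L, max)
  span <- sum(colMax - colMin)
  p <- numeric(span + 1L)
  p[1L] <- 1
  mn <- rep(Inf, span + 1L)
  mn[1L] <- 0
  hi <- 0L  # current occupied range is 1..(hi+1)
  for (i in seq_len(w)) {
    shifts <- Li[, i] - colMin[i]
    newHi <- hi + max(shifts)
    q <- numeric(newHi + 1L)
    m2 <- rep(Inf, newHi + 1L)
    idx <- seq_len(hi + 1L)
    for (b in seq_len(4L)) {
      sh <- shifts[b]
      q[idx + sh] <- q[idx + sh] + p[idx] * bg[b]
      cand <- mn[idx] + lo[b, i]
      cand[is.nan(cand)] <- Inf  # unreachable state + (-Inf) entry
      m2[idx + sh] <- pmin(m2[idx + sh], cand)
    }
    p <- q
    mn <- m2
    hi <- newHi
  }
  base <- sum(colMin)
  list(score = base + 0:hi, prob = p, minExact = mn)
}

latticeLogOdds_ <- function(motif) {
  lo <- logOdds(motif)
  Li <- round(lo * LATTICE_)
  Li[!is.finite(Li)] <- LATTICE_FLOOR_
  Li[Li < LATTICE_FLOOR_] <- LATTICE_FLOOR_
  storage.mode(Li) <- "integer"
  Li
}

#' Exact p-value of a score under the background model
#'
#' The complement of [scoreThreshold()]: P(random window score >= s),
#' from the same lattice DP.
#'
#' @param motif a [MotifMatrix-class].
#' @param score score in bits.
#' @return the exact tail probability on the lattice.
#' @export
scorePvalue <- function(motif, score) {
  d <- scoreDistribution_(motif)
  s <- round(score * LATTICE_)
  sum(d$prob[d$score >= s - 0.5])
}
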