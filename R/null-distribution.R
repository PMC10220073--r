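#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a NullDistribution from replicate occurrence counts
#'
#' @param motifId motif identifier.
#' @param counts numeric vector (length >= 2) of occurrence counts, one
#'   per random-region replicate.
#' @return A [NullDistribution-class] with mu = mean and sigma = sample
#'   standard deviation (n - 1 denominator).
#' @examples
#' nd <- NullDistribution("toy", c(2, 4, 6))
#' nullMu(nd)     # 4
#' nullSigma(nd)  # 2
#' @export
NullDistribution <- function(motifId, counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L)
    stop("an empirical null needs at least 2 replicate counts")
  methods::new("NullDistribution",
    motifId = as.character(motifId),
    counts = counts,
    mu = mean(counts),
    sigma = stats::sd(counts)
  )
}

#' @describeIn NullDistribution-class motif identifier
#' @param x a NullDistribution
#' @export
setMethod("motifId", "NullDistribution", function(x) x@motifId)

#' @describeIn NullDistribution-class per-replicate occurrence counts
#' @export
setMethod("replicateCounts", "NullDistribution", function(x) x@counts)

#' @describeIn NullDistribution-class null mean of the occurrence count
#' @export
setMethod("nullMu", "NullDistribution", function(x) x@mu)

#' @describeIn NullDistribution-class null sample standard deviation
#' @export
setMethod("nullSigma", "NullDistribution", function(x) x@sigma)

#' @describeIn NullDistribution-class number of replicates
#' @export
setMethod("nReplicates", "NullDistribution", function(x) length(x@counts))

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution %s: %d replicates, mu = %.3f, sigma = %.3f\n",
    object@motifId, length(object@counts), object@mu, object@sigma))
})

#' @describeIn MotifEnrichment-class the per-motif results data.frame
#' @param x a MotifEnrichment
#' @export
setMethod("enrichTable", "MotifEnrichment", function(x) x@results)

#' @describeIn MotifEnrichment-class named list of run provenance
#' @export
setMethod("runMetadata", "MotifEnrichment", function(x) x@metadata)

setMethod("show", "MotifEnrichment", function(object) {
  r <- object@results
  cat(sprintf("MotifEnrichment: %d motif(s) x %d set(s)\n",
              length(unique(r$motif_id)),
              length(unique(r$set_label))))
  ord <- order(-abs(ifelse(is.na(r$z), 0, r$z)))
  top <- utils::head(r[ord, c("motif_id", "set_label", "x", "mu",
                              "sigma", "z", "p_empirical", "q_bh")], 5L)
  print(top, row.names = FALSE, digits = 4)
})
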