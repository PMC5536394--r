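#' Accessors for StudyCatalog and related classes
#'
#' @param x a \code{StudyCatalog} (or subclass), \code{PoissonBinomialModel},
#'   \code{ReplicationAudit} or \code{DecileFit}.
#' @return \code{catalogLoci}: the loci \code{GRanges}; \code{catalogPapers}:
#'   the papers \code{DataFrame}; \code{nLoci}/\code{nPapers}: counts;
#'   \code{catalogTruth}: the truth \code{DataFrame} of a
#'   \code{SyntheticCatalog}.
#' @examples
#' cat <- simulateCatalog(simulationConfig(nPapers = 3, seed = 1))
#' nLoci(cat); nPapers(cat)
#' head(catalogTruth(cat))
#' @name catalog-accessors
NULL

#' @rdname catalog-accessors
#' @export
catalogLoci <- function(x) x@loci

#' @rdname catalog-accessors
#' @export
catalogPapers <- function(x) x@papers

#' @rdname catalog-accessors
#' @export
nLoci <- function(x) length(x@loci)

#' @rdname catalog-accessors
#' @export
nPapers <- function(x) nrow(x@papers)

#' @rdname catalog-accessors
#' @export
catalogTruth <- function(x) {
    stopifnot(is(x, "SyntheticCatalog"))
    x@truth
}

#' @rdname catalog-accessors
#' @export
pbProbs <- function(x) x@probs

#' @rdname catalog-accessors
#' @export
pbPMF <- function(x) x@pmf

#' @rdname catalog-accessors
#' @export
paperFits <- function(x) x@paperFits

#' @rdname catalog-accessors
#' @export
decileTable <- function(x) x@table

setMethod("show", "ThresholdSpec", function(object) {
    cat(sprintf("ThresholdSpec: alpha = %g (two-tailed), cutoff c = %.6f\n",
                object@alpha, object@cutoff))
})

setMethod("show", "StudyCatalog", function(object) {
    cat(sprintf("%s with %d papers, %d loci\n",
                class(object), nPapers(object), nLoci(object)))
    p <- object@papers
    cat(sprintf("  same-ancestry papers: %d; per-locus-N papers: %d\n",
                sum(p$same_ancestry), sum(p$per_locus_n)))
    if ("beta_hat" %in% colnames(mcols(object@loci)))
        cat("  Winner's-Curse-corrected effects present\n")
})

setMethod("show", "PoissonBinomialModel", function(object) {
    cat(sprintf(
        "PoissonBinomialModel on %d trials: mean %.3f, sd %.3f\n",
        length(object@probs), pbMean(object), sqrt(pbVariance(object))))
})

setMethod("show", "ReplicationAudit", function(object) {
    cat(sprintf(
        "ReplicationAudit (%s threshold, %s effects)\n",
        object@alphaRule,
        if (object@corrected) "WC-corrected" else "raw discovery"))
    cat(sprintf("  pooled: predicted %.1f, observed %d of %d loci (p = %.3g)\n",
                object@predicted, object@observed,
                length(object@model@probs), object@pvalue))
    st <- table(factor(object@paperFits$status,
                       levels = c("within", "above", "below")))
    cat(sprintf("  papers: %d within / %d above / %d below 95%% interval\n",
                st[["within"]], st[["above"]], st[["below"]]))
})

setMethod("show", "DecileFit", function(object) {
    cat(sprintf(
        "DecileFit (%s effects): chi-square %.2f on 9 df, p = %.3g\n",
        if (object@corrected) "WC-corrected" else "raw discovery",
        object@chi2, object@pvalue))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d papers, discovery alpha %g, seed %d\n",
        object@nPapers, object@discoveryAlpha, as.integer(object@seed)))
    if (object@ancestryShift < 1)
        cat(sprintf("  cross-ancestry attenuation: %.2f\n",
                    object@ancestryShift))
    if (object@nMaxMisreport)
        cat("  maximum-N misreporting enabled\n")
})
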