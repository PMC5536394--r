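#' @import methods
#' @importFrom stats dnorm pnorm qnorm pchisq qchisq rnorm runif rpois
#'   uniroot setNames complete.cases
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start
NULL

## Required per-locus metadata columns of the loci GRanges, in canonical order.
.LOCUS_COLS <- c("variant_id", "disc_beta", "disc_se", "disc_freq", "disc_n",
                 "rep_beta", "rep_se", "rep_freq", "rep_n", "paper_id")

## Required per-paper columns of the papers DataFrame.
.PAPER_COLS <- c("paper_id", "discovery_alpha", "same_ancestry",
                 "per_locus_n", "trait_variance")

#' Discovery-threshold specification
#'
#' Couples a two-tailed discovery p-value threshold \code{alpha} with the
#' corresponding standard-normal cutoff \code{cutoff} on the absolute test
#' statistic, \eqn{c = \Phi^{-1}(1 - \alpha/2)}. A variant is ascertained when
#' \eqn{|\beta_{obs}/s| \ge c}.
#'
#' @slot alpha numeric, two-tailed discovery threshold in (0, 1).
#' @slot cutoff numeric, standard-normal quantile for \code{alpha}.
#' @exportClass ThresholdSpec
setClass("ThresholdSpec",
    representation(alpha = "numeric", cutoff = "numeric"))

setValidity("ThresholdSpec", function(object) {
    msg <- NULL
    if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
        object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "'alpha' must be a single value in (0, 1)")
    if (length(object@cutoff) != 1L || !is.finite(object@cutoff) ||
        object@cutoff <= 0)
        msg <- c(msg, "'cutoff' must be a single positive value")
    if (is.null(msg)) {
        ## alpha -> cutoff must round-trip to ~12 significant digits
        expected <- qnorm(object@alpha / 2, lower.tail = FALSE)
        if (abs(object@cutoff - expected) > 1e-12 * max(1, expected))
            msg <- c(msg, "'cutoff' does not match qnorm(1 - alpha/2)")
    }
    if (is.null(msg)) TRUE else msg
})

#' @param alpha two-tailed discovery p-value threshold in (0, 1).
#' @return \code{thresholdSpec} returns a \code{ThresholdSpec} object.
#' @examples
#' thresholdSpec(5e-8)  # genome-wide significance, cutoff ~ 5.4513
#' @rdname ThresholdSpec-class
#' @export
thresholdSpec <- function(alpha) {
    new("ThresholdSpec", alpha = alpha, cutoff = qnorm(alpha / 2, lower.tail = FALSE))
}

#' Catalog of two-stage GWAS summary statistics
#'
#' Container for a collection of publications ("papers"), each contributing a
#' set of independent loci with discovery- and replication-stage summary
#' statistics. Loci are held as a \code{GRanges} (one range per variant) whose
#' metadata columns carry the per-stage effect estimate, standard error,
#' allele frequency and sample size; per-paper metadata (discovery threshold,
#' ancestry / sample-size reporting flags, trait variance) live in a
#' \code{DataFrame}.
#'
#' Every locus must satisfy the ascertainment condition of its paper:
#' \eqn{|\beta_{obs}/s| \ge \Phi^{-1}(1-\alpha_x/2)}. Records violating it are
#' rejected at load time (see \code{\link{readPaperTable}}), since the
#' Winner's Curse model conditions on discovery significance.
#'
#' @slot loci \code{GRanges} with metadata columns \code{variant_id},
#'   \code{disc_beta}, \code{disc_se}, \code{disc_freq}, \code{disc_n},
#'   \code{rep_beta}, \code{rep_se}, \code{rep_freq}, \code{rep_n},
#'   \code{paper_id} (and optionally Winner's-Curse columns \code{beta_hat},
#'   \code{wc_bias}, \code{wc_converged} added by \code{\link{correctCatalog}}).
#' @slot papers \code{DataFrame} with columns \code{paper_id},
#'   \code{discovery_alpha}, \code{same_ancestry}, \code{per_locus_n},
#'   \code{trait_variance} and optionally \code{journal}.
#' @seealso \code{\link{readPaperTable}}, \code{\link{pruneLoci}},
#'   \code{\link{subsetCatalog}}, \code{\link{auditCatalog}}
#' @exportClass StudyCatalog
setClass("StudyCatalog",
    representation(loci = "GRanges", papers = "DataFrame"))

.validateCatalog <- function(object) {
    msg <- NULL
    mc <- mcols(object@loci)
    missing_cols <- setdiff(.LOCUS_COLS, colnames(mc))
    if (length(missing_cols))
        return(paste("loci are missing metadata columns:",
                     paste(missing_cols, collapse = ", ")))
    missing_pc <- setdiff(.PAPER_COLS, colnames(object@papers))
    if (length(missing_pc))
        return(paste("papers are missing columns:",
                     paste(missing_pc, collapse = ", ")))
    pid <- object@papers$paper_id
    if (anyDuplicated(pid))
        msg <- c(msg, "duplicated paper_id in papers table")
    if (!all(mc$paper_id %in% pid))
        msg <- c(msg, "loci reference paper_ids absent from the papers table")
    if (length(object@loci)) {
        if (!all(mc$disc_se > 0) || !all(mc$rep_se > 0))
            msg <- c(msg, "standard errors must be strictly positive")
        bad_f <- !(mc$disc_freq > 0 & mc$disc_freq < 1 &
                   mc$rep_freq > 0 & mc$rep_freq < 1)
        if (any(bad_f))
            msg <- c(msg, "allele frequencies must lie strictly inside (0, 1)")
        if (!all(mc$disc_n > 0) || !all(mc$rep_n > 0))
            msg <- c(msg, "sample sizes must be positive")
        alpha <- object@papers$discovery_alpha[match(mc$paper_id, pid)]
        cutoff <- qnorm(alpha / 2, lower.tail = FALSE)
        z <- abs(mc$disc_beta / mc$disc_se)
        ## small tolerance: simulated loci sit exactly at the boundary
        if (any(z < cutoff * (1 - 1e-9)))
            msg <- c(msg, paste0(
                "loci below their paper's discovery cutoff (e.g. ",
                mc$variant_id[which(z < cutoff * (1 - 1e-9))[1L]],
                "); the ascertainment assumption is violated"))
    }
    if (any(!is.finite(object@papers$discovery_alpha)) ||
        any(object@papers$discovery_alpha <= 0) ||
        any(object@papers$discovery_alpha > 0.05))
        msg <- c(msg, "discovery_alpha must lie in (0, 0.05]")
    if (any(object@papers$trait_variance <= 0))
        msg <- c(msg, "trait_variance must be positive")
    if (is.null(msg)) TRUE else msg
}

setValidity("StudyCatalog", .validateCatalog)

#' @param loci GRanges of loci (see slot description).
#' @param papers DataFrame (or data.frame) of per-paper metadata.
#' @return \code{StudyCatalog} returns a validated \code{StudyCatalog}.
#' @rdname StudyCatalog-class
#' @export
StudyCatalog <- function(loci, papers) {
    if (is.data.frame(papers))
        papers <- DataFrame(papers)
    if (is.null(papers$trait_variance))
        papers$trait_variance <- rep(1, nrow(papers))
    new("StudyCatalog", loci = loci, papers = papers)
}

#' Synthetic catalog with ground truth
#'
#' A \code{\link{StudyCatalog}} produced by \code{\link{simulateCatalog}},
#' carrying a truth table aligned 1:1 with the loci: the simulated true
#' effect, the effect operating in the replication sample (after any
#' cross-ancestry attenuation), and the effective per-locus replication
#' sample size (which differs from the reported \code{rep_n} when maximum-N
#' misreporting is emulated).
#'
#' @slot truth \code{DataFrame} with columns \code{variant_id},
#'   \code{paper_id}, \code{beta_true}, \code{beta_rep_true},
#'   \code{effective_rep_n}.
#' @exportClass SyntheticCatalog
setClass("SyntheticCatalog",
    contains = "StudyCatalog",
    representation(truth = "DataFrame"))

setValidity("SyntheticCatalog", function(object) {
    if (nrow(object@truth) != length(object@loci))
        return("truth table is not aligned 1:1 with catalog loci")
    if (!identical(object@truth$variant_id,
                   mcols(object@loci)$variant_id))
        return("truth table variant_ids do not match catalog loci")
    TRUE
})

#' Exact Poisson-binomial distribution
#'
#' Distribution of the number of successes among independent Bernoulli trials
#' with heterogeneous success probabilities; here, the predicted count of
#' replicating loci given each locus's power to replicate. The PMF is exact,
#' computed by iterative convolution (no normal approximation).
#'
#' @slot probs numeric vector of per-trial success probabilities in [0, 1].
#' @slot pmf numeric vector of length \code{length(probs) + 1}; \code{pmf[k+1]}
#'   is P(K = k).
#' @seealso \code{\link{pbBuild}}, \code{\link{pbTwoTailedTest}},
#'   \code{\link{pbInterval}}
#' @exportClass PoissonBinomialModel
setClass("PoissonBinomialModel",
    representation(probs = "numeric", pmf = "numeric"))

setValidity("PoissonBinomialModel", function(object) {
    msg <- NULL
    if (!length(object@probs))
        msg <- c(msg, "'probs' must be non-empty")
    if (any(object@probs < 0 | object@probs > 1))
        msg <- c(msg, "'probs' must lie in [0, 1]")
    if (length(object@pmf) != length(object@probs) + 1L)
        msg <- c(msg, "'pmf' must have length length(probs) + 1")
    if (abs(sum(object@pmf) - 1) > 1e-10)
        msg <- c(msg, "'pmf' must sum to 1 within 1e-10")
    if (is.null(msg)) TRUE else msg
})

#' Catalog-level replication audit result
#'
#' Result of \code{\link{auditCatalog}}: per-paper predicted and observed
#' replication counts with 95\% Poisson-binomial intervals and fit status,
#' plus a pooled exact two-tailed Poisson-binomial test over all loci.
#'
#' @slot paperFits \code{DataFrame}, one row per paper: \code{paper_id},
#'   \code{n_loci}, \code{predicted}, \code{observed}, \code{lo}, \code{hi},
#'   \code{status} (\code{"within"}, \code{"above"}, \code{"below"}),
#'   \code{p}.
#' @slot predicted numeric, pooled predicted replication count.
#' @slot observed integer, pooled observed replication count.
#' @slot pvalue numeric, pooled two-tailed Poisson-binomial p-value.
#' @slot alphaRule character, \code{"nominal"} or \code{"bonferroni"}.
#' @slot corrected logical, whether Winner's-Curse-corrected effects were used.
#' @slot model the pooled \code{PoissonBinomialModel}.
#' @exportClass ReplicationAudit
setClass("ReplicationAudit",
    representation(paperFits = "DataFrame", predicted = "numeric",
                   observed = "integer", pvalue = "numeric",
                   alphaRule = "character", corrected = "logical",
                   model = "PoissonBinomialModel"))

#' Decile goodness-of-fit of replication p-values
#'
#' Result of \code{\link{decileAnalysis}}: loci sorted by observed one-tailed
#' replication p-value and split into ten equal-count bins; the expected
#' fraction of loci per bin is the mean over all loci of the probability of
#' the locus's replication p-value landing in the bin, derived from its power
#' curve; a chi-square statistic with Poisson-binomial bin variances
#' summarises the fit.
#'
#' @slot table \code{DataFrame} with columns \code{bin}, \code{lower},
#'   \code{upper} (p-value boundaries), \code{observed_frac},
#'   \code{expected_frac}, \code{expected_count}, \code{observed_count},
#'   \code{var_count}.
#' @slot chi2 numeric chi-square statistic (9 df).
#' @slot pvalue numeric goodness-of-fit p-value.
#' @slot corrected logical.
#' @exportClass DecileFit
setClass("DecileFit",
    representation(table = "DataFrame", chi2 = "numeric",
                   pvalue = "numeric", corrected = "logical"))

#' Configuration of the synthetic two-stage GWAS generator
#'
#' Defines the generative model for a multi-paper two-stage GWAS catalog:
#' per-locus true effects (trait-SD units per allele), minor allele
#' frequencies, discovery/replication sample sizes, the discovery
#' significance threshold whose ascertainment induces the Winner's Curse, and
#' the two reporting failure modes the audit is designed to detect
#' (maximum-N misreporting and cross-ancestry effect attenuation).
#'
#' @slot nPapers integer number of papers.
#' @slot lociPerPaper function(n) returning n per-paper locus counts (>= 1).
#' @slot discoveryAlpha numeric two-tailed discovery threshold.
#' @slot nDisc function(n) returning n discovery sample sizes.
#' @slot nRep function(n) returning n replication sample sizes.
#' @slot mafDist function(n) returning n allele frequencies in (0, 0.5).
#' @slot effectDist function(n) returning n true effects (trait-SD units).
#' @slot traitVariance numeric total trait variance (1 = standardized trait).
#' @slot ancestryShift numeric multiplier in (0, 1] applied to true effects in
#'   the replication stage; < 1 emulates cross-ancestry LD decay.
#' @slot nMaxMisreport logical; if TRUE, per-locus missingness
#'   ~ Uniform(0, 0.5) reduces the effective replication N while the catalog
#'   reports the paper's maximum N.
#' @slot seed integer RNG seed (mandatory).
#' @seealso \code{\link{simulateCatalog}}
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(nPapers = "numeric", lociPerPaper = "function",
                   discoveryAlpha = "numeric", nDisc = "function",
                   nRep = "function", mafDist = "function",
                   effectDist = "function", traitVariance = "numeric",
                   ancestryShift = "numeric", nMaxMisreport = "logical",
                   seed = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    if (length(object@seed) != 1L || !is.finite(object@seed))
        msg <- c(msg, "'seed' is mandatory and must be a single finite number")
    if (object@nPapers < 1)
        msg <- c(msg, "'nPapers' must be >= 1")
    if (object@discoveryAlpha <= 0 || object@discoveryAlpha > 0.05)
        msg <- c(msg, "'discoveryAlpha' must lie in (0, 0.05]")
    if (object@ancestryShift <= 0 || object@ancestryShift > 1)
        msg <- c(msg, "'ancestryShift' must lie in (0, 1]")
    if (object@traitVariance <= 0)
        msg <- c(msg, "'traitVariance' must be positive")
    if (is.null(msg)) TRUE else msg
})
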