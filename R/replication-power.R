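## Per-locus replication p-values and power under the additive model.

#' Noncentrality parameter of the replication association test
#'
#' Under the additive model for a standardized quantitative trait, a variant
#' with per-allele effect \eqn{\beta} and allele frequency \eqn{f} explains
#' variance \eqn{2\beta^2 f(1-f)}; in a replication sample of size \eqn{N}
#' the association chi-square statistic (1 df) is noncentral with
#' \deqn{ncp = N \frac{2\beta^2 f(1-f)}{\sigma^2 - 2\beta^2 f(1-f)},}
#' the ratio of explained to residual variance scaled by \eqn{N}.
#'
#' @param beta effect estimate (raw or Winner's-Curse-corrected), trait-SD
#'   units per allele. Vectorized.
#' @param n replication sample size (positive real; non-integral sizes from
#'   imputed studies are allowed).
#' @param f replication allele frequency in (0, 1).
#' @param traitVariance total trait variance (default 1).
#' @return non-negative numeric vector; 0 iff \code{beta == 0}.
#' @examples
#' noncentrality(0.1, 1000, 0.5)  # 1000 * 0.005 / 0.995
#' @export
noncentrality <- function(beta, n, f, traitVariance = 1) {
    if (any(n <= 0)) stop("'n' must be positive")
    if (any(f <= 0 | f >= 1)) stop("'f' must lie in (0, 1)")
    explained <- 2 * beta^2 * f * (1 - f)
    if (any(explained >= traitVariance))
        stop("explained variance >= trait variance; invalid effect/frequency")
    n * explained / (traitVariance - explained)
}

#' Power to replicate at a significance threshold
#'
#' \deqn{power(\alpha, ncp) = 1 - F_{\chi^2_1(ncp)}\big(Q_{\chi^2_1}(1-\alpha)\big):}
#' the probability that the replication association statistic exceeds the
#' central chi-square critical value for threshold \code{alpha}, under the
#' noncentral alternative. At \code{ncp = 0} the power equals \code{alpha};
#' at \code{alpha = 1} it equals 1.
#'
#' @param ncp noncentrality parameter(s) (see \code{\link{noncentrality}});
#'   alternatively supply \code{beta}, \code{n}, \code{f},
#'   \code{traitVariance} and leave \code{ncp} missing.
#' @param alpha replication significance threshold(s) in (0, 1].
#' @param beta,n,f,traitVariance used to compute \code{ncp} when it is not
#'   given directly.
#' @return numeric vector of powers in [0, 1].
#' @examples
#' powerToReplicate(ncp = 5.02512, alpha = 0.05)
#' powerToReplicate(alpha = 0.05, beta = 0.1, n = 1000, f = 0.5)
#' @export
powerToReplicate <- function(ncp, alpha, beta, n, f, traitVariance = 1) {
    if (missing(ncp))
        ncp <- noncentrality(beta, n, f, traitVariance)
    if (any(ncp < 0)) stop("'ncp' must be non-negative")
    if (any(alpha <= 0 | alpha > 1)) stop("'alpha' must lie in (0, 1]")
    nn <- max(length(ncp), length(alpha))
    ncp <- rep_len(ncp, nn)
    alpha <- rep_len(alpha, nn)
    crit <- qchisq(alpha, df = 1, lower.tail = FALSE)
    pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Probability of one-tailed replication success
#'
#' Replication success is counted as a one-tailed replication p-value (see
#' \code{\link{replicationPvalue}}) falling below a threshold \code{alpha},
#' i.e. the signed replication statistic exceeding \eqn{z_{1-\alpha}}. For a
#' predicted effect \eqn{\beta} (whose sign matches discovery), the
#' probability of that event is
#' \deqn{P = \Phi\big(\sqrt{ncp} - z_{1-\alpha}\big),}
#' with \eqn{ncp} as in \code{\link{noncentrality}}. This is the exact
#' counterpart of the success event the audit counts; it differs from the
#' two-sided \code{\link{powerToReplicate}} only in using the one-tailed
#' critical value and dropping the (negligible) wrong-direction tail. All
#' catalog-level predictions use this form so that predicted and observed
#' counts refer to the same event.
#'
#' @param beta effect estimate (raw or corrected); only its magnitude enters.
#' @param n replication sample size.
#' @param f replication allele frequency.
#' @param alpha one-tailed replication threshold in (0, 1].
#' @param traitVariance total trait variance (default 1).
#' @return success probabilities in [0, 1]; equals \code{alpha} at
#'   \code{beta = 0}, and 1 at \code{alpha = 1}.
#' @export
replicationSuccessProb <- function(beta, n, f, alpha, traitVariance = 1) {
    if (any(alpha <= 0 | alpha > 1)) stop("'alpha' must lie in (0, 1]")
    ncp <- noncentrality(beta, n, f, traitVariance)
    pnorm(sqrt(ncp) - qnorm(alpha, lower.tail = FALSE))
}

#' One-tailed replication p-value aligned to the discovery direction
#'
#' Replication success requires the replication estimate to land on the same
#' side as the discovery estimate:
#' \eqn{p = 1 - \Phi\big(\mathrm{sign}(\beta_{disc})\,\beta_{rep}/s_{rep}\big)}.
#' A sign-discordant replication therefore yields \eqn{p > 0.5}.
#'
#' @param discBeta discovery effect(s); must be nonzero (the direction is
#'   undefined otherwise).
#' @param repBeta replication effect(s).
#' @param repSe replication standard error(s), > 0.
#' @return numeric vector of one-tailed p-values in (0, 1).
#' @examples
#' replicationPvalue(0.3, 0, 0.1)        # 0.5 at the null boundary
#' replicationPvalue(0.3, 0.1645, 0.1)   # ~0.05
#' @export
replicationPvalue <- function(discBeta, repBeta, repSe) {
    if (any(repSe <= 0)) stop("'repSe' must be > 0")
    if (any(discBeta == 0))
        stop("'discBeta' of 0: replication direction undefined")
    pnorm(sign(discBeta) * repBeta / repSe, lower.tail = FALSE)
}

## Per-paper replication alpha under a rule.
.alphaRep <- function(catalog, alphaRule = c("nominal", "bonferroni"),
                      alphaBase = 0.05) {
    alphaRule <- match.arg(alphaRule)
    pid <- mcols(catalogLoci(catalog))$paper_id
    if (alphaRule == "nominal") {
        rep(alphaBase, length(pid))
    } else {
        m_x <- table(pid)
        alphaBase / as.numeric(m_x[pid])
    }
}

## Per-locus power at a vector of replication alphas (one per locus).
.lociPower <- function(catalog, alphaRep, useCorrection = TRUE) {
    loci <- catalogLoci(catalog)
    mc <- mcols(loci)
    papers <- catalogPapers(catalog)
    tv <- papers$trait_variance[match(mc$paper_id, papers$paper_id)]
    beta <- if (useCorrection) {
        if (is.null(mc$beta_hat))
            stop("corrected effects absent; run correctCatalog() first")
        mc$beta_hat
    } else {
        mc$disc_beta
    }
    replicationSuccessProb(beta, mc$rep_n, mc$rep_freq, alphaRep, tv)
}

#' Predicted replication count per paper
#'
#' The predicted number of replications in a paper is the sum over its loci
#' of the power to replicate at the chosen threshold; it lies in
#' \eqn{[0, M_x]}.
#'
#' @param catalog a \code{StudyCatalog} (run \code{\link{correctCatalog}}
#'   first when \code{useCorrection = TRUE}).
#' @param alphaRule \code{"nominal"} (replication p < 0.05) or
#'   \code{"bonferroni"} (p < 0.05 / \eqn{M_x}, the paper's locus count).
#' @param useCorrection use Winner's-Curse-corrected effects (default) or
#'   raw discovery effects.
#' @param alphaBase base replication threshold (default 0.05).
#' @return a \code{data.frame} with columns \code{paper_id}, \code{n_loci},
#'   \code{predicted}.
#' @export
predictedReplications <- function(catalog,
                                  alphaRule = c("nominal", "bonferroni"),
                                  useCorrection = TRUE, alphaBase = 0.05) {
    alphaRule <- match.arg(alphaRule)
    alphaRep <- .alphaRep(catalog, alphaRule, alphaBase)
    pw <- .lociPower(catalog, alphaRep, useCorrection)
    pid <- mcols(catalogLoci(catalog))$paper_id
    agg <- tapply(pw, pid, sum)
    ids <- catalogPapers(catalog)$paper_id
    data.frame(paper_id = ids,
               n_loci = as.integer(table(pid)[ids]),
               predicted = as.numeric(agg[ids]))
}
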