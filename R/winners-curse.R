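## Conditional-MLE correction of the Winner's Curse from summary statistics.

#' Expected ascertainment bias of a thresholded effect estimate
#'
#' For a variant with true standardized effect \code{betaTrue} and standard
#' error \code{se}, ascertained by a two-tailed significance threshold with
#' standard-normal cutoff \code{cutoff}, the expected value of the observed
#' estimate under the truncated-normal likelihood is
#' \deqn{E[\beta_{obs}] = \beta_{true} + s\,\frac{\phi(z-c) - \phi(-z-c)}
#'   {\Phi(z-c) + \Phi(-z-c)},\qquad z = \beta_{true}/s,}
#' whose second term this function returns. The denominator is the selection
#' probability \eqn{P(|Z| > c \mid \beta_{true})}. The bias vanishes at
#' \eqn{z = 0} (by symmetry) and decays to zero as the statistic moves far
#' beyond the cutoff; it is largest just above the threshold.
#'
#' The computation is carried out in log space, so it is finite and accurate
#' even when the selection probability underflows (e.g. \eqn{z = 0} with a
#' genome-wide cutoff).
#'
#' @param betaTrue true effect(s), trait-SD units per allele (vectorized).
#' @param se standard error(s) of the observed estimate, > 0.
#' @param cutoff standard-normal threshold cutoff \eqn{c > 0} (see
#'   \code{\link{thresholdSpec}}).
#' @return numeric vector of expected biases, same sign as \code{betaTrue}.
#' @examples
#' expectedBias(0, 0.1, 5.45)           # 0 by symmetry
#' expectedBias(0.196, 0.1, 1.96)       # maximal curse at the threshold
#' @seealso \code{\link{correctEffect}}
#' @export
expectedBias <- function(betaTrue, se, cutoff) {
    if (any(se <= 0)) stop("'se' must be > 0")
    if (any(cutoff <= 0)) stop("'cutoff' must be > 0")
    n <- max(length(betaTrue), length(se), length(cutoff))
    betaTrue <- rep_len(betaTrue, n)
    se <- rep_len(se, n)
    cutoff <- rep_len(cutoff, n)
    z <- betaTrue / se
    sgn <- sign(z)
    az <- abs(z)
    ## For z >= 0: a = z - c dominates both numerator and denominator;
    ## factor it out and work with log ratios so underflow cannot occur.
    a <- az - cutoff
    b <- -az - cutoff
    la <- dnorm(a, log = TRUE)
    lb <- dnorm(b, log = TRUE)
    lA <- pnorm(a, log.p = TRUE)
    lB <- pnorm(b, log.p = TRUE)
    bias <- sgn * se * exp(la - lA) *
        (1 - exp(lb - la)) / (1 + exp(lB - lA))
    bias[az == 0] <- 0
    bias
}

#' Winner's-Curse-corrected effect estimate
#'
#' Conditional maximum-likelihood debiasing of an ascertained effect
#' estimate: solves \eqn{b + \mathrm{bias}(b, s, c) = \beta_{obs}} for the
#' underlying effect \eqn{b} by Brent's method on the bracket
#' \eqn{[0, \beta_{obs}]} (for positive \eqn{\beta_{obs}}; negative estimates
#' are handled by sign reflection). The bracket is guaranteed: at 0 the
#' objective equals \eqn{-\beta_{obs} < 0} and at \eqn{\beta_{obs}} it equals
#' the (positive) expected bias. Observed statistics exactly at the cutoff
#' are allowed — this is the maximal-bias case.
#'
#' @param betaObs observed discovery effect(s) (vectorized).
#' @param se standard error(s), > 0.
#' @param threshold a \code{\link{ThresholdSpec}}, or a numeric cutoff
#'   \eqn{c}.
#' @param tol convergence tolerance; the root satisfies
#'   \eqn{|b + \mathrm{bias}(b) - \beta_{obs}| < tol \cdot s}.
#' @param variantId optional labels used in error messages.
#' @return a \code{data.frame} with columns \code{beta_obs}, \code{se},
#'   \code{beta_true_hat}, \code{bias} (\eqn{= \beta_{obs} - \hat\beta}),
#'   \code{converged}. The corrected estimate shares the sign of
#'   \code{betaObs} and is never larger in magnitude.
#' @examples
#' ts <- thresholdSpec(5e-8)
#' correctEffect(ts@cutoff * 0.1, 0.1, ts)   # observed exactly at the cutoff
#' correctEffect(1.0, 0.01, ts)              # z = 100: negligible correction
#' @export
correctEffect <- function(betaObs, se, threshold, tol = 1e-8,
                          variantId = NULL) {
    cutoff <- if (is(threshold, "ThresholdSpec")) threshold@cutoff
              else as.numeric(threshold)
    if (any(se <= 0)) stop("'se' must be > 0")
    n <- max(length(betaObs), length(se), length(cutoff))
    betaObs <- rep_len(betaObs, n)
    se <- rep_len(se, n)
    cutoff <- rep_len(cutoff, n)
    if (is.null(variantId)) variantId <- as.character(seq_len(n))
    z <- abs(betaObs) / se
    low <- z < cutoff * (1 - 1e-9)
    if (any(low))
        stop("observed statistic below the ascertainment cutoff for: ",
             paste(variantId[low], collapse = ", "))
    hat <- numeric(n)
    conv <- logical(n)
    for (i in seq_len(n)) {
        b_obs <- abs(betaObs[i])
        g <- function(b) b + expectedBias(b, se[i], cutoff[i]) - b_obs
        ## g(0) = -b_obs < 0, g(b_obs) = bias(b_obs) > 0
        r <- uniroot(g, lower = 0, upper = b_obs,
                     tol = min(tol * se[i], 1e-10 * b_obs + 1e-14))
        hat_i <- r$root
        conv[i] <- abs(g(hat_i)) < tol * se[i]
        if (!conv[i])
            warning("correction did not converge for ", variantId[i])
        hat[i] <- sign(betaObs[i]) * hat_i
    }
    data.frame(beta_obs = betaObs, se = se, beta_true_hat = hat,
               bias = betaObs - hat, converged = conv)
}

#' Append Winner's-Curse-corrected effects to a catalog
#'
#' Applies \code{\link{correctEffect}} to every locus, using each paper's own
#' discovery threshold, and stores the results in the loci metadata columns
#' \code{beta_hat}, \code{wc_bias} and \code{wc_converged}.
#'
#' @param catalog a \code{StudyCatalog}.
#' @param tol passed to \code{\link{correctEffect}}.
#' @return the catalog with corrected-effect columns appended.
#' @examples
#' cat <- simulateCatalog(simulationConfig(nPapers = 2, seed = 3))
#' cat <- correctCatalog(cat)
#' summary(abs(mcols(catalogLoci(cat))$beta_hat) <=
#'         abs(mcols(catalogLoci(cat))$disc_beta))
#' @export
correctCatalog <- function(catalog, tol = 1e-8) {
    stopifnot(is(catalog, "StudyCatalog"))
    loci <- catalogLoci(catalog)
    papers <- catalogPapers(catalog)
    mc <- mcols(loci)
    alpha <- papers$discovery_alpha[match(mc$paper_id, papers$paper_id)]
    res <- correctEffect(mc$disc_beta, mc$disc_se,
                         threshold = qnorm(alpha / 2, lower.tail = FALSE), tol = tol,
                         variantId = mc$variant_id)
    mcols(loci)$beta_hat <- res$beta_true_hat
    mcols(loci)$wc_bias <- res$bias
    mcols(loci)$wc_converged <- res$converged
    out <- catalog
    out@loci <- loci
    out
}
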