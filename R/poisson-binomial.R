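## Exact Poisson-binomial distribution and tests.

#' Build an exact Poisson-binomial model
#'
#' Computes the exact PMF of the sum of independent Bernoulli trials with
#' success probabilities \code{probs} by iterative convolution (dynamic
#' programming over trials), avoiding the normal approximation — important
#' here because many loci have power numerically 0 or 1.
#'
#' @param probs numeric vector of per-trial success probabilities in [0, 1].
#' @return a \code{\link{PoissonBinomialModel}}.
#' @examples
#' pbPMF(pbBuild(c(0.1, 0.5, 0.9)))
#' @export
pbBuild <- function(probs) {
    if (!length(probs)) stop("'probs' must be non-empty")
    if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
        stop("'probs' must lie in [0, 1]")
    pmf <- 1
    for (p in probs)
        pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
    new("PoissonBinomialModel", probs = as.numeric(probs), pmf = pmf)
}

#' Moments and CDF of a Poisson-binomial model
#'
#' @param model a \code{PoissonBinomialModel}.
#' @param k count(s) at which to evaluate the CDF, \eqn{P(K \le k)}.
#' @return \code{pbMean}: \eqn{\sum p_i}; \code{pbVariance}:
#'   \eqn{\sum p_i(1-p_i)}; \code{pbCDF}: cumulative probabilities.
#' @export
pbMean <- function(model) sum(model@probs)

#' @rdname pbMean
#' @export
pbVariance <- function(model) sum(model@probs * (1 - model@probs))

#' @rdname pbMean
#' @export
pbCDF <- function(model, k) {
    cdf <- cumsum(model@pmf)
    n <- length(model@probs)
    k <- pmin(pmax(floor(k), -1), n)
    ifelse(k < 0, 0, cdf[k + 1])
}

#' Exact two-tailed Poisson-binomial test
#'
#' Adaptation of the small-sample two-tailed exact binomial test to the
#' Poisson binomial: the p-value is the total mass of all outcomes no more
#' likely than the observed one,
#' \eqn{p = \sum_k \mathrm{pmf}[k] \cdot 1\{\mathrm{pmf}[k] \le
#' \mathrm{pmf}[obs](1+10^{-7})\}}, with a small relative slack guarding
#' floating-point ties.
#'
#' @param model a \code{PoissonBinomialModel}.
#' @param observed observed success count in \eqn{[0, n]}.
#' @return p-value in (0, 1].
#' @examples
#' pbTwoTailedTest(pbBuild(rep(0.5, 10)), 0)  # 2/1024
#' @export
pbTwoTailedTest <- function(model, observed) {
    n <- length(model@probs)
    observed <- as.integer(observed)
    if (observed < 0L || observed > n)
        stop("'observed' must lie in [0, ", n, "]")
    d_obs <- model@pmf[observed + 1L]
    p <- sum(model@pmf[model@pmf <= d_obs * (1 + 1e-7)])
    min(p, 1)
}

#' Central Poisson-binomial prediction interval
#'
#' Smallest central interval \eqn{[lo, hi]} with
#' \eqn{F(hi) - F(lo - 1) \ge} \code{level}: \code{lo} is the largest count
#' whose lower tail \eqn{F(lo - 1)} does not exceed \eqn{(1-level)/2}, and
#' \code{hi} the smallest count bringing the covered mass to \code{level}.
#' The interval always contains the mode.
#'
#' @param model a \code{PoissonBinomialModel}.
#' @param level coverage level (default 0.95).
#' @return integer vector \code{c(lo, hi)}.
#' @export
pbInterval <- function(model, level = 0.95) {
    stopifnot(level > 0, level < 1)
    cdf <- cumsum(model@pmf)
    n <- length(model@probs)
    tail <- (1 - level) / 2
    ## lo = largest k with P(K <= k-1) <= tail  (k = 0 always qualifies)
    below <- which(cdf <= tail + 1e-12)
    lo <- if (length(below)) max(below) else 0L
    flo <- if (lo == 0L) 0 else cdf[lo]
    hi <- which(cdf >= flo + level - 1e-12)[1L] - 1L
    if (is.na(hi)) hi <- n
    c(lo = as.integer(lo), hi = as.integer(hi))
}
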