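## Independent oracles and small fixture builders used across test files.

## Exact Poisson-binomial PMF by enumeration over all 2^n outcomes (n <= ~15).
pbEnumOracle <- function(probs) {
    n <- length(probs)
    pmf <- numeric(n + 1)
    for (m in 0:(2^n - 1)) {
        bits <- as.integer(intToBits(m))[seq_len(n)]
        pr <- prod(ifelse(bits == 1, probs, 1 - probs))
        k <- sum(bits)
        pmf[k + 1] <- pmf[k + 1] + pr
    }
    pmf
}

## Ascertainment bias through an independent normal implementation (erfc).
biasErfcOracle <- function(betaTrue, se, cutoff) {
    Phi <- function(x) 0.5 * pracma::erfc(-x / sqrt(2))
    phi <- function(x) exp(-x^2 / 2) / sqrt(2 * pi)
    z <- betaTrue / se
    se * (phi(z - cutoff) - phi(-z - cutoff)) /
        (Phi(z - cutoff) + Phi(-z - cutoff))
}

## Noncentral chi-square (1 df) survival via the Poisson-mixture series.
ncChisqSurvSeries <- function(crit, ncp, tolTail = 1e-14) {
    j <- 0:ceiling(ncp / 2 + 20 * sqrt(ncp / 2 + 1) + 50)
    w <- stats::dpois(j, ncp / 2)
    sum(w * stats::pchisq(crit, df = 1 + 2 * j, lower.tail = FALSE))
}

## AUC as the fraction of concordant (positive, negative) pairs, ties 0.5.
aucEnumOracle <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
}

## Hand-built two-paper catalog with ascertainment satisfied by construction.
toyCatalog <- function(alpha = 1e-5) {
    cutoff <- qnorm(alpha / 2, lower.tail = FALSE)
    mk <- function(pid, z, pos, chrom = "1") {
        n <- length(z)
        se <- rep(0.04, n)
        data.frame(variant_id = sprintf("%s_v%d", pid, seq_len(n)),
                   chrom = chrom, pos = pos,
                   disc_beta = z * se, disc_se = se,
                   disc_freq = rep(0.3, n), disc_n = rep(8000, n),
                   rep_beta = z * se * 0.8, rep_se = rep(0.05, n),
                   rep_freq = rep(0.3, n), rep_n = rep(4000, n),
                   paper_id = pid)
    }
    df <- rbind(mk("P1", c(5.0, 6.5, 9.0), c(1e6, 5e6, 9e6)),
                mk("P2", c(-4.8, 7.2), c(2e6, 80e6)))
    loci <- GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(df$pos, width = 1),
        variant_id = df$variant_id, disc_beta = df$disc_beta,
        disc_se = df$disc_se, disc_freq = df$disc_freq, disc_n = df$disc_n,
        rep_beta = df$rep_beta, rep_se = df$rep_se, rep_freq = df$rep_freq,
        rep_n = df$rep_n, paper_id = df$paper_id)
    papers <- S4Vectors::DataFrame(
        paper_id = c("P1", "P2"), discovery_alpha = alpha,
        same_ancestry = c(TRUE, FALSE), per_locus_n = c(TRUE, TRUE),
        trait_variance = 1)
    StudyCatalog(loci, papers)
}

## Write a per-paper variant table to a temp file; returns the path.
writePaperTable <- function(df, sep = "\t", ext = ".tsv") {
    path <- tempfile(fileext = ext)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    path
}

## A generator configuration with non-binding ascertainment: every candidate
## effect is strong relative to the lenient threshold, so selection barely
## truncates and corrected effects essentially equal observed ones. Used to
## check that the audit machinery itself is calibrated when per-locus
## success probabilities are accurate.
mildConfig <- function(seed, nPapers = 12,
                       lociPerPaper = function(n) 1L + rpois(n, 11)) {
    simulationConfig(
        nPapers = nPapers, lociPerPaper = lociPerPaper,
        discoveryAlpha = 0.05,
        effectDist = function(n) sign(runif(n, -1, 1)) * runif(n, 0.05, 0.3),
        seed = seed)
}
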