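## Catalog-level inference: Poisson-binomial fit tests, decile diagnostics,
## power-matched subsampling nulls, paired ROC comparison.

## Per-locus observed replication indicators and p-values under a rule.
.replicationObserved <- function(catalog, alphaRule, alphaBase = 0.05) {
    mc <- mcols(catalogLoci(catalog))
    alphaRep <- .alphaRep(catalog, alphaRule, alphaBase)
    repp <- replicationPvalue(mc$disc_beta, mc$rep_beta, mc$rep_se)
    list(pvalue = repp, alphaRep = alphaRep, replicated = repp < alphaRep)
}

#' Audit observed versus predicted replication across a catalog
#'
#' For each paper, compares the observed number of replicating loci (one-
#' tailed replication p-value below the paper's threshold) with the number
#' predicted by summing per-locus power to replicate, flagging the paper as
#' within / above / below its central 95\% Poisson-binomial interval. All
#' loci are then pooled into a single Poisson-binomial vector for an exact
#' two-tailed goodness-of-fit test of the catalog-wide replication count.
#'
#' @param catalog a \code{StudyCatalog}. When \code{useCorrection = TRUE} and
#'   corrected effects are absent, \code{\link{correctCatalog}} is applied
#'   first.
#' @param alphaRule \code{"nominal"} (p < \code{alphaBase}) or
#'   \code{"bonferroni"} (p < \code{alphaBase}/\eqn{M_x} per paper).
#' @param useCorrection predict power from Winner's-Curse-corrected effects
#'   (default) or raw discovery effects.
#' @param level per-paper interval coverage (default 0.95).
#' @param alphaBase base replication threshold (default 0.05).
#' @return a \code{\link{ReplicationAudit}}.
#' @examples
#' cat <- simulateCatalog(simulationConfig(nPapers = 5, seed = 11))
#' auditCatalog(cat, "nominal")
#' @export
auditCatalog <- function(catalog, alphaRule = c("nominal", "bonferroni"),
                         useCorrection = TRUE, level = 0.95,
                         alphaBase = 0.05) {
    alphaRule <- match.arg(alphaRule)
    stopifnot(is(catalog, "StudyCatalog"))
    if (useCorrection &&
        is.null(mcols(catalogLoci(catalog))$beta_hat))
        catalog <- correctCatalog(catalog)
    obs <- .replicationObserved(catalog, alphaRule, alphaBase)
    pw <- .lociPower(catalog, obs$alphaRep, useCorrection)
    pid <- mcols(catalogLoci(catalog))$paper_id
    ids <- catalogPapers(catalog)$paper_id
    fits <- lapply(ids, function(p) {
        sel <- pid == p
        model <- pbBuild(pw[sel])
        k <- sum(obs$replicated[sel])
        ci <- pbInterval(model, level)
        status <- if (k > ci[["hi"]]) "above"
                  else if (k < ci[["lo"]]) "below" else "within"
        DataFrame(paper_id = p, n_loci = sum(sel),
                  predicted = sum(pw[sel]), observed = k,
                  lo = ci[["lo"]], hi = ci[["hi"]], status = status,
                  p = pbTwoTailedTest(model, k))
    })
    fits <- do.call(rbind, fits)
    pooled <- pbBuild(pw)
    k_all <- sum(obs$replicated)
    new("ReplicationAudit", paperFits = fits,
        predicted = sum(pw), observed = as.integer(k_all),
        pvalue = pbTwoTailedTest(pooled, k_all),
        alphaRule = alphaRule, corrected = useCorrection, model = pooled)
}

#' Decile goodness-of-fit of replication p-values
#'
#' All loci are sorted by their observed one-tailed replication p-value and
#' partitioned into ten equal-count bins; by construction each bin holds 10\%
#' of loci. The expected fraction per bin is derived from each locus's power
#' curve: with bin boundaries \eqn{0 = e_0 < e_1 < \dots < e_{10} = 1} taken
#' from the observed p-value order statistics, locus \eqn{i} lands in bin
#' \eqn{j} with probability \eqn{q_{ij} = power_i(e_j) - power_i(e_{j-1})},
#' and the expected fraction is the mean of \eqn{q_{ij}} over all loci. Fit
#' is summarised by \eqn{\chi^2 = \sum_j (O_j - E_j)^2 / V_j} with
#' Poisson-binomial bin variances \eqn{V_j = \sum_i q_{ij}(1-q_{ij})},
#' referred to 9 df.
#'
#' When discovery effects are inflated (uncorrected), predicted power piles
#' up at small p-values, so the strongest-signal bin's expected fraction
#' exceeds 10\% and the fit rejects.
#'
#' @param catalog a \code{StudyCatalog} (corrected on the fly if needed and
#'   \code{useCorrection = TRUE}).
#' @param useCorrection use corrected (default) or raw effects.
#' @param nBins number of equal-count bins (default 10).
#' @return a \code{\link{DecileFit}}; bins are ordered by increasing
#'   replication p-value, so bin 1 holds the strongest signals.
#' @export
decileAnalysis <- function(catalog, useCorrection = TRUE, nBins = 10L) {
    stopifnot(is(catalog, "StudyCatalog"))
    if (useCorrection &&
        is.null(mcols(catalogLoci(catalog))$beta_hat))
        catalog <- correctCatalog(catalog)
    mc <- mcols(catalogLoci(catalog))
    n <- length(catalogLoci(catalog))
    if (n < nBins)
        stop("need at least ", nBins, " loci for a decile analysis")
    repp <- replicationPvalue(mc$disc_beta, mc$rep_beta, mc$rep_se)
    papers <- catalogPapers(catalog)
    tv <- papers$trait_variance[match(mc$paper_id, papers$paper_id)]
    beta <- if (useCorrection) mc$beta_hat else mc$disc_beta
    ncp <- noncentrality(beta, mc$rep_n, mc$rep_freq, tv)
    ord <- order(repp)
    bin_of <- integer(n)
    bin_of[ord] <- ceiling(seq_len(n) / (n / nBins))
    bin_n <- tabulate(bin_of, nBins)
    sorted <- repp[ord]
    upper <- c(sorted[cumsum(bin_n)][-nBins], 1)
    lower <- c(0, upper[-nBins])
    ## P(one-tailed replication p <= edge) for every locus at every boundary
    edges <- c(0, upper)
    pw_at <- vapply(edges, function(a) {
        if (a <= 0) rep(0, n)
        else pnorm(sqrt(ncp) - qnorm(a, lower.tail = FALSE))
    }, numeric(n))
    q <- pw_at[, -1, drop = FALSE] - pw_at[, -(nBins + 1), drop = FALSE]
    q <- pmax(q, 0)
    exp_count <- colSums(q)
    var_count <- colSums(q * (1 - q))
    chi2 <- sum((bin_n - exp_count)^2 / var_count)
    pval <- pchisq(chi2, df = nBins - 1, lower.tail = FALSE)
    tab <- DataFrame(bin = seq_len(nBins), lower = lower, upper = upper,
                     observed_frac = bin_n / n,
                     expected_frac = exp_count / n,
                     observed_count = bin_n, expected_count = exp_count,
                     var_count = var_count)
    new("DecileFit", table = tab, chi2 = chi2, pvalue = pval,
        corrected = useCorrection)
}

#' Power-matched subsampling null for fit improvement
#'
#' Tests whether the goodness-of-fit improvement seen in a subset of the
#' catalog exceeds what random subsetting would produce: random locus
#' subsets of the full catalog are drawn, matched to the subset's total
#' predicted power to replicate within a tolerance, and the pooled two-
#' tailed Poisson-binomial fit p-value is recomputed for each. The empirical
#' p-value is the fraction of matched draws whose fit p-value is at least as
#' large as the subset's (one-tailed: improvement at least as strong by
#' chance alone).
#'
#' @param full the full \code{StudyCatalog}.
#' @param subset a catalog whose loci are a subset of \code{full} (matched on
#'   \code{paper_id} + \code{variant_id}).
#' @param alphaRule,useCorrection,alphaBase as in \code{\link{auditCatalog}}.
#' @param nSims number of matched random subsets (default 10000).
#' @param tol relative tolerance on total predicted power (default 0.01);
#'   widened geometrically with a warning when matching fails.
#' @param seed RNG seed.
#' @return list with \code{p} (empirical p-value), \code{subset_p} (the
#'   subset's fit p-value), \code{target_power}, \code{sim_p} (vector of
#'   simulated fit p-values) and \code{sim_power}.
#' @export
matchedPowerSubsampleTest <- function(full, subset,
                                      alphaRule = c("nominal", "bonferroni"),
                                      useCorrection = TRUE, nSims = 10000L,
                                      tol = 0.01, seed, alphaBase = 0.05) {
    alphaRule <- match.arg(alphaRule)
    if (missing(seed)) stop("'seed' is required")
    if (useCorrection) {
        if (is.null(mcols(catalogLoci(full))$beta_hat))
            full <- correctCatalog(full)
        if (is.null(mcols(catalogLoci(subset))$beta_hat))
            subset <- correctCatalog(subset)
    }
    key <- function(x) {
        mc <- mcols(catalogLoci(x))
        paste(mc$paper_id, mc$variant_id, sep = "\r")
    }
    if (!all(key(subset) %in% key(full)))
        stop("'subset' contains loci absent from 'full'")
    obs <- .replicationObserved(full, alphaRule, alphaBase)
    pw <- .lociPower(full, obs$alphaRep, useCorrection)
    rep_ind <- obs$replicated
    sub_audit <- auditCatalog(subset, alphaRule, useCorrection,
                              alphaBase = alphaBase)
    p_sub <- sub_audit@pvalue
    target <- sub_audit@predicted
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    n <- length(pw)
    sim_p <- numeric(nSims)
    sim_power <- numeric(nSims)
    cur_tol <- tol
    s <- 1L
    while (s <= nSims) {
        found <- FALSE
        for (try in 1:50) {
            perm <- sample.int(n)
            cs <- cumsum(pw[perm])
            k <- which.min(abs(cs - target))
            if (abs(cs[k] - target) <= cur_tol * target) {
                found <- TRUE
                break
            }
        }
        if (!found) {
            cur_tol <- cur_tol * 2
            warning("power matching infeasible at tolerance; widened to ",
                    signif(cur_tol, 3))
            next
        }
        ## canonical order so convolution rounding matches the direct audit
        sel <- sort(perm[seq_len(k)])
        sim_power[s] <- cs[k]
        sim_p[s] <- pbTwoTailedTest(pbBuild(pw[sel]), sum(rep_ind[sel]))
        s <- s + 1L
    }
    list(p = mean(sim_p >= p_sub), subset_p = p_sub,
         target_power = target, sim_p = sim_p, sim_power = sim_power)
}

#' Paired ROC comparison of two replication predictors
#'
#' Computes the AUC of two per-locus scores (e.g. power to replicate from
#' corrected versus raw effects) against the binary replication outcome,
#' using the rank (Mann-Whitney) estimator with midranks for ties, and
#' DeLong's paired two-tailed test for the AUC difference.
#'
#' @param scoresA,scoresB numeric score vectors, paired per locus.
#' @param labels binary outcome vector (logical or 0/1), both classes
#'   present.
#' @return list with \code{auc_a}, \code{auc_b}, \code{p}.
#' @examples
#' aucCompare(c(1, 2, 3, 4), c(4, 3, 2, 1), c(0, 0, 1, 1))
#' @export
aucCompare <- function(scoresA, scoresB, labels) {
    labels <- as.integer(as.logical(labels))
    if (length(unique(labels)) < 2L)
        stop("'labels' must contain both classes")
    stopifnot(length(scoresA) == length(labels),
              length(scoresB) == length(labels))
    rocA <- pROC::roc(labels, scoresA, quiet = TRUE, direction = "<",
                      levels = c(0, 1))
    rocB <- pROC::roc(labels, scoresB, quiet = TRUE, direction = "<",
                      levels = c(0, 1))
    aucA <- as.numeric(pROC::auc(rocA))
    aucB <- as.numeric(pROC::auc(rocB))
    p <- if (isTRUE(all.equal(scoresA, scoresB))) {
        1
    } else {
        tst <- pROC::roc.test(rocA, rocB, method = "delong", paired = TRUE)
        pv <- as.numeric(tst$p.value)
        if (!is.finite(pv)) 1 else pv
    }
    list(auc_a = aucA, auc_b = aucB, p = p)
}
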