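## A catalog where every locus has saturated power and replicates.
saturatedCatalog <- function() {
    cat0 <- toyCatalog(alpha = 1e-5)
    loci <- catalogLoci(cat0)
    mc <- S4Vectors::mcols(loci)
    mc$disc_beta <- sign(mc$disc_beta) * 0.8
    mc$rep_beta <- sign(mc$disc_beta) * 0.8
    mc$rep_se <- 0.02
    S4Vectors::mcols(loci) <- mc
    StudyCatalog(loci, catalogPapers(cat0))
}

test_that("audit flags are trivially consistent when every locus replicates", {
    a <- auditCatalog(saturatedCatalog(), "nominal")
    expect_equal(a@observed, 5L)
    expect_equal(a@predicted, 5, tolerance = 1e-6)
    expect_equal(a@pvalue, 1, tolerance = 1e-6)
    expect_true(all(paperFits(a)$status == "within"))
    ## per-paper bookkeeping
    pf <- paperFits(a)
    expect_equal(sum(pf$observed), a@observed)
    expect_equal(sum(pf$predicted), a@predicted, tolerance = 1e-12)
    expect_true(all(pf$observed >= pf$lo & pf$observed <= pf$hi))
})

test_that("the pooled audit p-value ignores paper ordering", {
    cc <- correctCatalog(simulateCatalog(mildConfig(31, nPapers = 6)))
    a1 <- auditCatalog(cc, "nominal")
    perm <- rev(seq_len(nLoci(cc)))
    cc2 <- subsetLoci(cc, perm)
    a2 <- auditCatalog(cc2, "nominal")
    expect_equal(a1@pvalue, a2@pvalue, tolerance = 1e-9)
    expect_equal(a1@predicted, a2@predicted, tolerance = 1e-9)
    expect_identical(a1@observed, a2@observed)
})

test_that("audit p-values are calibrated when success probabilities are accurate", {
    ## catalogs with non-binding ascertainment: corrected effects track the
    ## truth closely, so the exact Poisson-binomial test should be uniform
    ps <- vapply(1:200, function(s) {
        auditCatalog(simulateCatalog(mildConfig(20000 + s)),
                     "nominal")@pvalue
    }, numeric(1))
    expect_gte(mean(ps >= 0.05), 0.94)
    ## validity of the exact discrete p: P(p <= a) <= a (+ MC slack); the
    ## minimum-likelihood two-tailed construction is conservative, never
    ## anti-conservative
    for (a in c(0.01, 0.05, 0.1, 0.25))
        expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 200))
    ## and p-values are genuinely spread over (0, 1), not clumped
    expect_gt(mean(ps > 0.5), 0.3)
})

test_that("per-paper 95% intervals cover at the nominal rate", {
    ## one large calibrated catalog: ~2.5% of papers flagged per side at most
    ## (discrete intervals over-cover, so the outside fraction is <= 5%)
    cc <- simulateCatalog(mildConfig(555, nPapers = 400,
                                     lociPerPaper = function(n)
                                         5L + rpois(n, 10)))
    a <- auditCatalog(cc, "nominal")
    frac_out <- mean(paperFits(a)$status != "within")
    se3 <- 3 * sqrt(0.05 * 0.95 / 400)
    expect_lte(frac_out, 0.05 + se3)
})

test_that("decile bookkeeping sums to the whole catalog", {
    cc <- correctCatalog(simulateCatalog(mildConfig(61)))
    d <- decileAnalysis(cc)
    tab <- decileTable(d)
    expect_equal(sum(tab$observed_frac), 1, tolerance = 1e-12)
    expect_equal(sum(tab$expected_frac), 1, tolerance = 1e-6)
    expect_equal(sum(tab$observed_count), nLoci(cc))
    expect_true(all(tab$upper > tab$lower))
    expect_equal(tab$upper[10], 1)
    expect_error(decileAnalysis(subsetLoci(cc, 1:5)), "10 loci")
})

test_that("inflated effects concentrate expected mass in the top decile", {
    ## curse-heavy study conditions, uncorrected: the strongest-signal bin
    ## is over-predicted and the fit rejects (and the corrected expectation
    ## for that bin is always below the raw one)
    cc <- simulateCatalog(simulationConfig(
        nPapers = 40, lociPerPaper = function(n) 1L + rpois(n, 14),
        seed = 21))
    cc <- correctCatalog(cc)
    d_raw <- decileAnalysis(cc, useCorrection = FALSE)
    expect_gt(decileTable(d_raw)$expected_frac[1], 0.10)
    expect_lt(d_raw@pvalue, 0.05)
    d_corr <- decileAnalysis(cc, useCorrection = TRUE)
    expect_lt(decileTable(d_corr)$expected_frac[1],
              decileTable(d_raw)$expected_frac[1])
})

test_that("power-matched subsampling respects its matching constraint", {
    cc <- correctCatalog(simulateCatalog(mildConfig(71)))
    ## subset = full recovers p = 1
    res_full <- matchedPowerSubsampleTest(cc, cc, "nominal", nSims = 50,
                                          seed = 1)
    expect_equal(res_full$p, 1)
    ## every accepted draw is within tolerance of the target power
    sub <- subsetLoci(cc, seq_len(floor(nLoci(cc) / 2)))
    res <- matchedPowerSubsampleTest(cc, sub, "nominal", nSims = 200,
                                     tol = 0.01, seed = 2)
    expect_true(all(abs(res$sim_power - res$target_power) <=
                    0.01 * res$target_power + 1e-9))
    expect_true(res$p >= 0 && res$p <= 1)
    ## foreign loci are rejected
    other <- simulateCatalog(mildConfig(72, nPapers = 2))
    expect_error(matchedPowerSubsampleTest(cc, other, seed = 1), "absent")
})

test_that("random subsets yield spread-out subsampling p-values", {
    cc <- correctCatalog(simulateCatalog(mildConfig(81)))
    n <- nLoci(cc)
    set.seed(9)
    ps <- replicate(40, {
        idx <- sample(n, floor(n / 2))
        matchedPowerSubsampleTest(cc, subsetLoci(cc, sort(idx)), "nominal",
                                  nSims = 120,
                                  seed = sample.int(1e6, 1))$p
    })
    ## calibration: roughly uniform, certainly not degenerate
    expect_gt(mean(ps > 0.2), 0.3)
    expect_gt(sd(ps), 0.1)
})

test_that("paired AUC comparison matches a concordant-pair oracle", {
    lab <- c(0, 0, 0, 1, 1, 1)
    perfect <- aucCompare(c(1, 2, 3, 7, 8, 9), c(9, 8, 7, 3, 2, 1), lab)
    expect_equal(perfect$auc_a, 1)
    expect_equal(perfect$auc_b, 0)
    ## identical predictors: no difference, p = 1
    same <- aucCompare(1:6, 1:6, lab)
    expect_equal(same$auc_a, same$auc_b)
    expect_equal(same$p, 1)
    ## toy scores with a tie, against the pairwise enumeration oracle
    sA <- c(0.1, 0.4, 0.4, 0.3, 0.8, 0.9)
    sB <- c(0.2, 0.1, 0.5, 0.7, 0.6, 0.4)
    got <- aucCompare(sA, sB, lab)
    expect_equal(got$auc_a, aucEnumOracle(sA, lab), tolerance = 1e-12)
    expect_equal(got$auc_b, aucEnumOracle(sB, lab), tolerance = 1e-12)
    expect_true(got$p >= 0 && got$p <= 1)
    expect_error(aucCompare(1:3, 1:3, c(1, 1, 1)), "both classes")
})
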