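## A well-formed three-variant table used by several reading tests.
wellFormedTable <- function() {
    data.frame(variant_id = c("rs1", "rs2", "rs3"), chrom = c("1", "1", "2"),
               pos = c(1e6, 5e6, 2e6),
               disc_beta = c(0.30, -0.28, 0.35), disc_se = 0.05,
               disc_freq = c(0.2, 0.4, 0.3), disc_n = 8000,
               rep_beta = c(0.22, -0.20, 0.30), rep_se = 0.06,
               rep_freq = c(0.21, 0.39, 0.31), rep_n = 4000)
}

test_that("paper tables parse, validate and reject bad rows", {
    tab <- wellFormedTable()
    cat1 <- readPaperTable(writePaperTable(tab), paperId = "10001",
                           discoveryAlpha = 1e-5)
    expect_s4_class(cat1, "StudyCatalog")
    expect_equal(nLoci(cat1), 3L)
    expect_equal(nPapers(cat1), 1L)
    ## CSV dialect is sniffed
    catCsv <- readPaperTable(writePaperTable(tab, sep = ",", ext = ".csv"),
                             paperId = "10001", discoveryAlpha = 1e-5)
    expect_equal(nLoci(catCsv), 3L)
    ## a zero replication SE row is rejected with a diagnostic
    bad <- tab
    bad$rep_se[2] <- 0
    expect_warning(
        cat2 <- readPaperTable(writePaperTable(bad), paperId = "10001",
                               discoveryAlpha = 1e-5),
        "rs2.*standard error")
    expect_equal(nLoci(cat2), 2L)
    ## sub-threshold discovery rows violate the ascertainment assumption
    low <- tab
    low$disc_beta[1] <- 0.05
    expect_warning(
        cat3 <- readPaperTable(writePaperTable(low), paperId = "10001",
                               discoveryAlpha = 1e-5),
        "threshold cutoff")
    expect_equal(nLoci(cat3), 2L)
    ## hard errors
    expect_error(readPaperTable(writePaperTable(tab), paperId = "x",
                                discoveryAlpha = NULL), "discoveryAlpha")
    allbad <- tab
    allbad$disc_se <- -1
    expect_error(suppressWarnings(
        readPaperTable(writePaperTable(allbad), paperId = "x",
                       discoveryAlpha = 1e-5)), "no valid rows")
})

test_that("a single frequency column serves both stages", {
    tab <- wellFormedTable()
    tab$freq <- tab$disc_freq
    tab$disc_freq <- tab$rep_freq <- NULL
    cat1 <- readPaperTable(writePaperTable(tab), paperId = "10001",
                           discoveryAlpha = 1e-5)
    mc <- S4Vectors::mcols(catalogLoci(cat1))
    expect_identical(mc$disc_freq, mc$rep_freq)
})

test_that("column maps bind arbitrary source headers", {
    tab <- wellFormedTable()
    names(tab)[names(tab) == "variant_id"] <- "SNP"
    names(tab)[names(tab) == "disc_beta"] <- "BETA_DISCOVERY"
    cat1 <- readPaperTable(writePaperTable(tab), paperId = "10001",
                           discoveryAlpha = 1e-5,
                           colMap = c(variant_id = "SNP",
                                      disc_beta = "BETA_DISCOVERY"))
    expect_equal(nLoci(cat1), 3L)
    expect_error(readPaperTable(writePaperTable(tab), paperId = "10001",
                                discoveryAlpha = 1e-5,
                                colMap = c(variant_id = "NOPE")), "NOPE")
})

test_that("a YAML manifest assembles a multi-paper catalog", {
    dir <- tempfile()
    dir.create(dir)
    t1 <- wellFormedTable()
    t2 <- wellFormedTable()
    t2$variant_id <- c("rs9", "rs10", "rs11")
    utils::write.table(t1, file.path(dir, "p1.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(t2, file.path(dir, "p2.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(c(
        "papers:",
        "  - file: p1.tsv",
        "    paper_id: '11111'",
        "    discovery_alpha: 1.0e-5",
        "    same_ancestry: true",
        "    per_locus_n: true",
        "  - file: p2.tsv",
        "    paper_id: '22222'",
        "    discovery_alpha: 5.0e-4",
        "    same_ancestry: false",
        "    per_locus_n: true"), file.path(dir, "manifest.yaml"))
    cat1 <- readCatalogManifest(file.path(dir, "manifest.yaml"))
    expect_equal(nPapers(cat1), 2L)
    expect_equal(nLoci(cat1), 6L)
    expect_equal(catalogPapers(cat1)$discovery_alpha, c(1e-5, 5e-4))
    ## a missing alpha is a hard error
    writeLines(c("papers:", "  - file: p1.tsv", "    paper_id: 'x'"),
               file.path(dir, "bad.yaml"))
    expect_error(readCatalogManifest(file.path(dir, "bad.yaml")),
                 "discovery_alpha")
})

test_that("the canonical catalog TSV round-trips", {
    cat0 <- correctCatalog(toyCatalog())
    path <- tempfile(fileext = ".tsv")
    writeCatalogTSV(cat0, path)
    back <- readCatalogTSV(path)
    expect_equal(nLoci(back), nLoci(cat0))
    expect_equal(nPapers(back), nPapers(cat0))
    m0 <- as.data.frame(S4Vectors::mcols(catalogLoci(cat0)))
    m1 <- as.data.frame(S4Vectors::mcols(catalogLoci(back)))
    expect_equal(m1[names(m0)], m0, tolerance = 1e-12)
})

test_that("positional pruning enforces the independence window", {
    ## two variants 500 kb apart plus one 5 Mb away -> 2 loci
    tab <- wellFormedTable()
    tab$chrom <- "1"
    tab$pos <- c(1e6, 1.5e6, 6.5e6)
    cat1 <- readPaperTable(writePaperTable(tab), paperId = "10001",
                           discoveryAlpha = 1e-5)
    pruned <- pruneLoci(cat1, windowBp = 1e6, seed = 1)
    expect_equal(nLoci(pruned), 2L)
    ## variants on distinct chromosomes are untouched
    tab$chrom <- c("1", "2", "3")
    cat2 <- readPaperTable(writePaperTable(tab), paperId = "10001",
                           discoveryAlpha = 1e-5)
    expect_equal(nLoci(pruneLoci(cat2, seed = 1)), 3L)
    ## pruning is within-paper only: identical positions in two papers stay
    twoP <- toyCatalog()
    expect_equal(nLoci(pruneLoci(twoP, seed = 3)), nLoci(twoP))
})

test_that("chained clusters match a brute-force component count", {
    ## single-linkage: A-B and B-C within 1 Mb chain into one cluster even
    ## though A-C is 1.6 Mb apart
    mkcat <- function(pos, chrom = rep("1", length(pos))) {
        n <- length(pos)
        tab <- data.frame(variant_id = sprintf("v%d", 1:n), chrom = chrom,
                          pos = pos, disc_beta = 0.3, disc_se = 0.05,
                          disc_freq = 0.3, disc_n = 8000, rep_beta = 0.2,
                          rep_se = 0.06, rep_freq = 0.3, rep_n = 4000)
        readPaperTable(writePaperTable(tab), paperId = "P",
                       discoveryAlpha = 1e-5)
    }
    componentOracle <- function(pos, window = 1e6) {
        n <- length(pos)
        adj <- abs(outer(pos, pos, "-")) <= window
        seen <- rep(FALSE, n)
        k <- 0
        for (i in seq_len(n)) {
            if (seen[i]) next
            k <- k + 1
            frontier <- i
            while (length(frontier)) {
                seen[frontier] <- TRUE
                frontier <- which(apply(
                    adj[frontier, , drop = FALSE], 2, any) & !seen)
            }
        }
        k
    }
    chain <- c(1e6, 1.8e6, 2.6e6)
    expect_equal(nLoci(pruneLoci(mkcat(chain), seed = 2)),
                 componentOracle(chain))
    set.seed(42)
    for (i in 1:10) {
        pos <- sort(sample(seq(1e5, 12e6, by = 1e5), sample(3:9, 1)))
        pruned <- pruneLoci(mkcat(pos), seed = i)
        expect_equal(nLoci(pruned), componentOracle(pos))
        ## no retained same-chromosome pair within the window
        kept <- GenomicRanges::start(catalogLoci(pruned))
        if (length(kept) > 1)
            expect_true(min(dist(kept)) > 1e6)
    }
})

test_that("pruning is idempotent and reproducible under a seed", {
    set.seed(99)
    pos <- sort(sample(seq(1e5, 8e6, by = 5e4), 12))
    tab <- data.frame(variant_id = sprintf("v%d", 1:12), chrom = "1",
                      pos = pos, disc_beta = 0.3, disc_se = 0.05,
                      disc_freq = 0.3, disc_n = 8000, rep_beta = 0.2,
                      rep_se = 0.06, rep_freq = 0.3, rep_n = 4000)
    cat1 <- readPaperTable(writePaperTable(tab), paperId = "P",
                           discoveryAlpha = 1e-5)
    p1 <- pruneLoci(cat1, seed = 7)
    p2 <- pruneLoci(cat1, seed = 7)
    expect_identical(S4Vectors::mcols(catalogLoci(p1))$variant_id,
                     S4Vectors::mcols(catalogLoci(p2))$variant_id)
    ## pruning a pruned catalog changes nothing (clusters are singletons)
    expect_identical(
        S4Vectors::mcols(catalogLoci(pruneLoci(p1, seed = 7)))$variant_id,
        S4Vectors::mcols(catalogLoci(p1))$variant_id)
    expect_error(pruneLoci(cat1), "seed")
})

test_that("catalog subsetting filters papers without touching records", {
    ## build a catalog with known flag composition: 39 of 100 papers carry
    ## both flags, 87 share ancestry
    set.seed(3)
    papers <- S4Vectors::DataFrame(
        paper_id = sprintf("P%03d", 1:100),
        discovery_alpha = 1e-5,
        same_ancestry = rep(c(TRUE, FALSE), c(87, 13)),
        per_locus_n = rep(c(TRUE, FALSE, TRUE), c(39, 48, 13)),
        trait_variance = 1)
    loci <- GenomicRanges::GRanges(
        "1", IRanges::IRanges(seq(1e6, by = 2e6, length.out = 100),
                              width = 1),
        variant_id = sprintf("v%03d", 1:100),
        disc_beta = 0.3, disc_se = 0.05, disc_freq = 0.3, disc_n = 8000,
        rep_beta = 0.2, rep_se = 0.06, rep_freq = 0.3, rep_n = 4000,
        paper_id = sprintf("P%03d", 1:100))
    cat1 <- StudyCatalog(loci, papers)
    both <- subsetCatalog(cat1, requireSameAncestry = TRUE,
                          requirePerLocusN = TRUE)
    expect_equal(nPapers(both), 39L)
    anc <- subsetCatalog(cat1, requireSameAncestry = TRUE)
    expect_equal(nPapers(anc), 87L)
    ## no flags -> identity
    none <- subsetCatalog(cat1)
    expect_equal(nPapers(none), 100L)
    ## records pass through unaltered
    mc_in <- S4Vectors::mcols(catalogLoci(cat1))
    mc_out <- S4Vectors::mcols(catalogLoci(both))
    idx <- match(mc_out$variant_id, mc_in$variant_id)
    expect_identical(as.data.frame(mc_out), as.data.frame(mc_in[idx, ]))
})

test_that("catalog validity enforces the domain invariants", {
    cat0 <- toyCatalog()
    bad <- catalogLoci(cat0)
    S4Vectors::mcols(bad)$disc_se[1] <- -1
    expect_error(StudyCatalog(bad, catalogPapers(cat0)), "standard error")
    bad2 <- catalogLoci(cat0)
    S4Vectors::mcols(bad2)$rep_freq[2] <- 1.2
    expect_error(StudyCatalog(bad2, catalogPapers(cat0)), "frequencies")
    badp <- catalogPapers(cat0)
    badp$discovery_alpha <- 0.2
    expect_error(StudyCatalog(catalogLoci(cat0), badp), "0, 0.05")
})
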