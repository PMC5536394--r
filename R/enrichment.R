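## Frequency-matched resampling tests for annotation enrichment.

.mafBin <- function(maf, binWidth = 0.05) {
    if (any(maf <= 0 | maf > 0.5))
        stop("MAF must be folded to the minor allele: (0, 0.5]")
    pmin(ceiling(maf / binWidth), ceiling(0.5 / binWidth))
}

#' Read an annotated variant pool
#'
#' The pool is a TSV with columns \code{variant_id}, \code{maf} (minor
#' allele frequency, folded to (0, 0.5]) and \code{annotation} (a partition
#' such as intergenic / genic_other / exonic_synonymous /
#' exonic_nonsynonymous). An \code{exonic} logical column is derived from the
#' annotation when absent.
#'
#' @param path TSV path.
#' @return a \code{data.frame} pool.
#' @export
readAnnotatedPool <- function(path) {
    pool <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    stopifnot(all(c("variant_id", "maf", "annotation") %in% colnames(pool)))
    if (is.null(pool$exonic))
        pool$exonic <- grepl("^exonic", pool$annotation)
    pool
}

#' MAF-matched resampling test of annotation enrichment
#'
#' Tests whether a query set of variants is enriched for an annotation class
#' relative to a pre-annotated background pool, controlling for allele
#' frequency: each simulated null set reproduces the query's size and its
#' per-bin minor-allele-frequency composition (bins of width
#' \code{binWidth} over (0, 0.5]), and optionally its exonic/non-exonic
#' composition within bins. Null sets are drawn without replacement within
#' each stratum. The empirical p-value carries the +1 correction so it is
#' never exactly zero.
#'
#' @param query data.frame of query variants with columns \code{maf} and
#'   \code{annotation} (and \code{exonic} if \code{matchExonic}).
#' @param pool background pool data.frame (see
#'   \code{\link{readAnnotatedPool}}).
#' @param annotationClass the class tested for enrichment.
#' @param nSims number of simulated null sets (default 10000; must be >= 1).
#' @param binWidth MAF bin width (default 0.05).
#' @param matchExonic also match exonic status within MAF bins.
#' @param seed RNG seed.
#' @return list with \code{fold} (observed / mean null count), \code{p},
#'   \code{observed}, \code{null_mean} and \code{null} (null count vector).
#' @examples
#' pool <- simulateAnnotatedPool(2000, seed = 1)
#' query <- pool[sample(nrow(pool), 50), ]
#' matchedResampleTest(query, pool, "exonic_nonsynonymous",
#'                     nSims = 200, seed = 2)$fold
#' @export
matchedResampleTest <- function(query, pool, annotationClass,
                                nSims = 10000L, binWidth = 0.05,
                                matchExonic = FALSE, seed) {
    if (missing(seed)) stop("'seed' is required")
    nSims <- as.integer(nSims)
    if (nSims < 1L) stop("'nSims' must be >= 1")
    if (!nrow(query)) stop("empty query set")
    qbin <- .mafBin(query$maf, binWidth)
    pbin <- .mafBin(pool$maf, binWidth)
    if (matchExonic) {
        stopifnot(!is.null(query$exonic), !is.null(pool$exonic))
        qbin <- paste(qbin, as.logical(query$exonic))
        pbin <- paste(pbin, as.logical(pool$exonic))
    }
    strata <- table(qbin)
    pool_by <- split(seq_len(nrow(pool)), pbin)
    empty <- setdiff(names(strata), names(pool_by))
    if (length(empty))
        stop("no pool candidates in MAF bin(s): ",
             paste(empty, collapse = ", "))
    short <- names(strata)[vapply(names(strata), function(b)
        length(pool_by[[b]]) < strata[[b]], logical(1))]
    replace <- length(short) > 0
    if (replace)
        warning("pool smaller than query in bin(s) ",
                paste(short, collapse = ", "),
                "; sampling with replacement there")
    in_class <- pool$annotation == annotationClass
    observed <- sum(query$annotation == annotationClass)
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    null_counts <- vapply(seq_len(nSims), function(s) {
        idx <- unlist(lapply(names(strata), function(b) {
            cand <- pool_by[[b]]
            k <- strata[[b]]
            cand[sample.int(length(cand), k,
                            replace = k > length(cand))]
        }), use.names = FALSE)
        sum(in_class[idx])
    }, numeric(1))
    null_mean <- mean(null_counts)
    list(fold = if (null_mean > 0) observed / null_mean else NA_real_,
         p = (1 + sum(null_counts >= observed)) / (nSims + 1),
         observed = observed, null_mean = null_mean, null = null_counts)
}

#' Enrichment of an annotation class among replicated versus attempted loci
#'
#' One-tailed exact binomial test of the class count among replicated loci
#' against the class rate in the full attempted set, with the fold change of
#' the two rates.
#'
#' @param attempted data.frame of all loci brought to replication, with an
#'   \code{annotation} column.
#' @param replicated data.frame of the subset that replicated.
#' @param annotationClass the class tested.
#' @return list with \code{fold} (rate ratio), \code{p} (one-tailed binomial
#'   upper tail), \code{observed}, \code{expected_rate}.
#' @export
replicatedVsAttemptedTest <- function(attempted, replicated,
                                      annotationClass) {
    if (!nrow(attempted) || !nrow(replicated))
        stop("empty variant set")
    rate0 <- mean(attempted$annotation == annotationClass)
    x <- sum(replicated$annotation == annotationClass)
    n <- nrow(replicated)
    p <- if (rate0 == 0) {
        if (x > 0) 0 else 1
    } else {
        stats::binom.test(x, n, p = rate0,
                          alternative = "greater")$p.value
    }
    list(fold = if (rate0 > 0) (x / n) / rate0 else NA_real_, p = p,
         observed = x, expected_rate = rate0)
}
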