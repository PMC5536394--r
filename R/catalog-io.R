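## Catalog input/output, validation, positional pruning and subsetting.

.makeLociGRanges <- function(df) {
    GRanges(seqnames = as.character(df$chrom),
            ranges = IRanges(start = as.integer(df$pos), width = 1L),
            variant_id = as.character(df$variant_id),
            disc_beta = as.numeric(df$disc_beta),
            disc_se = as.numeric(df$disc_se),
            disc_freq = as.numeric(df$disc_freq),
            disc_n = as.numeric(df$disc_n),
            rep_beta = as.numeric(df$rep_beta),
            rep_se = as.numeric(df$rep_se),
            rep_freq = as.numeric(df$rep_freq),
            rep_n = as.numeric(df$rep_n),
            paper_id = as.character(df$paper_id))
}

.sniffSep <- function(path) {
    header <- readLines(path, n = 1L)
    if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Read one paper's variant summary table
#'
#' Parses a delimited (TSV/CSV) table with one row per variant and builds a
#' validated single-paper \code{\link{StudyCatalog}}. Column names are bound
#' to catalog semantics through \code{colMap}, so arbitrary source headers
#' can be ingested. Rows with missing or invalid required fields are dropped
#' with a row-level warning; rows whose discovery test statistic falls below
#' the paper's threshold cutoff are likewise rejected, because the Winner's
#' Curse model conditions on ascertainment.
#'
#' If the table carries a single allele-frequency column (canonical name
#' \code{freq}) instead of distinct discovery/replication frequencies, that
#' one frequency is used for both stages.
#'
#' @param path path to the delimited table (separator sniffed from the header
#'   unless \code{sep} is given).
#' @param paperId paper identifier (e.g. PMID).
#' @param discoveryAlpha the paper's two-tailed discovery p-value threshold.
#' @param sameAncestry logical flag: replication conducted in the same
#'   continental ancestry as discovery.
#' @param perLocusN logical flag: replication sample sizes reported per locus
#'   (rather than as the study maximum).
#' @param traitVariance total trait variance (default 1, standardized trait).
#' @param journal optional journal label.
#' @param colMap named character vector mapping canonical column names
#'   (\code{variant_id}, \code{chrom}, \code{pos}, \code{disc_beta},
#'   \code{disc_se}, \code{disc_freq}, \code{disc_n}, \code{rep_beta},
#'   \code{rep_se}, \code{rep_freq}, \code{rep_n}, or the single-frequency
#'   \code{freq}) to source headers. Canonical names already present need not
#'   be mapped.
#' @param sep field separator; \code{NULL} to sniff tab-vs-comma.
#' @return a single-paper \code{StudyCatalog}.
#' @examples
#' tab <- data.frame(variant_id = c("rs1", "rs2"), chrom = "1",
#'                   pos = c(1e6, 5e6), disc_beta = c(0.3, -0.25),
#'                   disc_se = 0.04, freq = c(0.2, 0.4), disc_n = 5000,
#'                   rep_beta = c(0.25, -0.2), rep_se = 0.05, rep_n = 3000)
#' tf <- tempfile(fileext = ".tsv")
#' write.table(tab, tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' cat1 <- readPaperTable(tf, paperId = "10001", discoveryAlpha = 5e-8)
#' nLoci(cat1)
#' @export
readPaperTable <- function(path, paperId, discoveryAlpha,
                           sameAncestry = TRUE, perLocusN = TRUE,
                           traitVariance = 1, journal = NA_character_,
                           colMap = NULL, sep = NULL) {
    if (missing(discoveryAlpha) || is.null(discoveryAlpha) ||
        !is.finite(discoveryAlpha))
        stop("'discoveryAlpha' is required for paper ", paperId)
    if (!file.exists(path))
        stop("cannot read paper table: ", path)
    if (is.null(sep))
        sep <- .sniffSep(path)
    df <- tryCatch(
        utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE),
        error = function(e) stop("unparseable table '", path, "': ",
                                 conditionMessage(e)))
    if (!is.null(colMap)) {
        hit <- match(unname(colMap), colnames(df))
        if (anyNA(hit))
            stop("colMap refers to absent source columns: ",
                 paste(colMap[is.na(hit)], collapse = ", "))
        colnames(df)[hit] <- names(colMap)
    }
    ## single frequency column serves both stages
    if (!all(c("disc_freq", "rep_freq") %in% colnames(df))) {
        if ("freq" %in% colnames(df)) {
            df$disc_freq <- df$freq
            df$rep_freq <- df$freq
        } else if ("disc_freq" %in% colnames(df)) {
            df$rep_freq <- df$disc_freq
        } else if ("rep_freq" %in% colnames(df)) {
            df$disc_freq <- df$rep_freq
        }
    }
    required <- c("variant_id", "chrom", "pos", "disc_beta", "disc_se",
                  "disc_freq", "disc_n", "rep_beta", "rep_se", "rep_freq",
                  "rep_n")
    missing_cols <- setdiff(required, colnames(df))
    if (length(missing_cols))
        stop("table '", path, "' lacks required columns: ",
             paste(missing_cols, collapse = ", "))
    df <- df[required]
    num_cols <- setdiff(required, c("variant_id", "chrom"))
    for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))

    cutoff <- qnorm(discoveryAlpha / 2, lower.tail = FALSE)
    reasons <- character(nrow(df))
    bad <- !complete.cases(df)
    reasons[bad] <- "missing required fields"
    ok <- !bad
    chk <- function(cond, why) {
        idx <- ok & !cond
        reasons[idx] <<- why
        ok <<- ok & cond
    }
    chk(df$disc_se > 0 & df$rep_se > 0, "non-positive standard error")
    chk(df$disc_freq > 0 & df$disc_freq < 1 &
        df$rep_freq > 0 & df$rep_freq < 1, "frequency outside (0, 1)")
    chk(df$disc_n > 0 & df$rep_n > 0, "non-positive sample size")
    chk(abs(df$disc_beta / df$disc_se) >= cutoff * (1 - 1e-9),
        "discovery statistic below the paper's threshold cutoff")
    if (any(!ok)) {
        dropped <- which(!ok)
        warning(sprintf(
            "paper %s: dropped %d of %d rows [%s]", paperId,
            length(dropped), nrow(df),
            paste(sprintf("row %d (%s): %s", dropped,
                          as.character(df$variant_id[dropped]),
                          reasons[dropped]), collapse = "; ")))
    }
    df <- df[ok, , drop = FALSE]
    if (!nrow(df))
        stop("paper ", paperId, ": no valid rows in ", path)
    df$paper_id <- paperId
    papers <- DataFrame(paper_id = paperId, discovery_alpha = discoveryAlpha,
                        same_ancestry = isTRUE(sameAncestry),
                        per_locus_n = isTRUE(perLocusN),
                        trait_variance = traitVariance, journal = journal)
    StudyCatalog(.makeLociGRanges(df), papers)
}

#' Combine single- or multi-paper catalogs
#'
#' @param ... \code{StudyCatalog} objects with disjoint paper_ids.
#' @return the combined \code{StudyCatalog}.
#' @export
combineCatalogs <- function(...) {
    cats <- list(...)
    stopifnot(length(cats) >= 1L,
              all(vapply(cats, is, logical(1), "StudyCatalog")))
    loci <- suppressWarnings(do.call(c, lapply(cats, catalogLoci)))
    papers <- do.call(rbind, lapply(cats, function(x) {
        p <- catalogPapers(x)
        if (is.null(p$journal)) p$journal <- NA_character_
        p[, c(.PAPER_COLS, "journal")]
    }))
    if (all(vapply(cats, is, logical(1), "SyntheticCatalog"))) {
        truth <- do.call(rbind, lapply(cats, catalogTruth))
        new("SyntheticCatalog", loci = loci, papers = papers, truth = truth)
    } else {
        StudyCatalog(loci, papers)
    }
}

#' Read a catalog manifest
#'
#' A manifest (YAML or JSON) lists the per-paper tables and their metadata:
#'
#' \preformatted{
#' papers:
#'   - file: tables/19060906.tsv
#'     paper_id: "19060906"
#'     discovery_alpha: 5.0e-8
#'     same_ancestry: true
#'     per_locus_n: true
#' }
#'
#' Optional per-paper keys: \code{trait_variance}, \code{journal},
#' \code{col_map} (mapping of canonical to source column names), \code{sep}.
#' File paths are resolved relative to the manifest location.
#'
#' @param path manifest path (\code{.yaml}/\code{.yml}/\code{.json}).
#' @return a multi-paper \code{StudyCatalog}.
#' @export
readCatalogManifest <- function(path) {
    if (!file.exists(path))
        stop("cannot read manifest: ", path)
    man <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
        if (!requireNamespace("jsonlite", quietly = TRUE))
            stop("jsonlite is required for JSON manifests")
        jsonlite::fromJSON(path, simplifyVector = FALSE)
    } else {
        yaml::read_yaml(path)
    }
    if (is.null(man$papers) || !length(man$papers))
        stop("manifest lists no papers")
    base <- dirname(path)
    cats <- lapply(man$papers, function(p) {
        if (is.null(p$discovery_alpha))
            stop("manifest entry for paper '", p$paper_id,
                 "' lacks discovery_alpha")
        f <- p$file
        if (!grepl("^(/|[A-Za-z]:)", f))
            f <- file.path(base, f)
        colMap <- if (!is.null(p$col_map)) unlist(p$col_map) else NULL
        readPaperTable(f, paperId = as.character(p$paper_id),
                       discoveryAlpha = as.numeric(p$discovery_alpha),
                       sameAncestry = isTRUE(p$same_ancestry),
                       perLocusN = isTRUE(p$per_locus_n),
                       traitVariance =
                           if (is.null(p$trait_variance)) 1
                           else as.numeric(p$trait_variance),
                       journal = if (is.null(p$journal)) NA_character_
                                 else as.character(p$journal),
                       colMap = colMap, sep = p$sep)
    })
    do.call(combineCatalogs, cats)
}

#' Write / read the canonical catalog TSV
#'
#' One row per locus with fixed columns: the eleven per-locus fields plus the
#' per-paper metadata (\code{discovery_alpha}, \code{same_ancestry},
#' \code{per_locus_n}, \code{trait_variance}, \code{journal}) repeated on
#' each row, and any Winner's-Curse columns present. \code{readCatalogTSV}
#' reconstructs the \code{StudyCatalog} from such a file.
#'
#' @param catalog a \code{StudyCatalog}.
#' @param path output (input) path.
#' @return \code{writeCatalogTSV} returns \code{path} invisibly;
#'   \code{readCatalogTSV} returns a \code{StudyCatalog}.
#' @export
writeCatalogTSV <- function(catalog, path) {
    loci <- catalogLoci(catalog)
    mc <- as.data.frame(mcols(loci))
    df <- data.frame(variant_id = mc$variant_id,
                     chrom = as.character(seqnames(loci)),
                     pos = start(loci),
                     mc[setdiff(colnames(mc), "variant_id")],
                     check.names = FALSE)
    papers <- as.data.frame(catalogPapers(catalog))
    if (is.null(papers$journal)) papers$journal <- NA_character_
    idx <- match(df$paper_id, papers$paper_id)
    df <- cbind(df, papers[idx, c("discovery_alpha", "same_ancestry",
                                  "per_locus_n", "trait_variance",
                                  "journal")])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCatalogTSV
#' @export
readCatalogTSV <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    df$paper_id <- as.character(df$paper_id)
    papers <- unique(df[c("paper_id", "discovery_alpha", "same_ancestry",
                          "per_locus_n", "trait_variance", "journal")])
    loci <- .makeLociGRanges(df)
    for (extra in c("beta_hat", "wc_bias", "wc_converged"))
        if (extra %in% colnames(df))
            mcols(loci)[[extra]] <- df[[extra]]
    StudyCatalog(loci, papers)
}

#' Subset a catalog to selected loci
#'
#' Keeps the loci at the given indices (or logical mask); papers left with
#' no loci are dropped. Used to form locus subsets for power-matched
#' subsampling tests.
#'
#' @param catalog a \code{StudyCatalog}.
#' @param i integer or logical index into the loci.
#' @return a \code{StudyCatalog} with the selected loci.
#' @export
subsetLoci <- function(catalog, i) {
    stopifnot(is(catalog, "StudyCatalog"))
    loci <- catalogLoci(catalog)[i]
    keep <- catalogPapers(catalog)$paper_id %in% mcols(loci)$paper_id
    out <- catalog
    out@loci <- loci
    out@papers <- catalogPapers(catalog)[keep, , drop = FALSE]
    if (is(out, "SyntheticCatalog"))
        out@truth <- out@truth[i, , drop = FALSE]
    validObject(out)
    out
}

#' Prune loci to positional independence within papers
#'
#' Reduces each paper's loci so that no two retained variants on the same
#' chromosome lie within \code{windowBp} of each other. Clusters are formed
#' by single-linkage chaining: variants on a chromosome are sorted by
#' position and consecutive variants at distance <= \code{windowBp} are
#' linked. One representative per cluster is drawn uniformly at random under
#' \code{seed} (not necessarily the most significant variant, avoiding
#' ranking bias). Pruning is within-paper only; the same position may recur
#' across papers.
#'
#' @param catalog a \code{StudyCatalog}.
#' @param windowBp independence window in base pairs (default 1 Mb).
#' @param seed RNG seed for representative selection.
#' @return the pruned \code{StudyCatalog}.
#' @examples
#' cat <- simulateCatalog(simulationConfig(nPapers = 2, seed = 7))
#' nLoci(pruneLoci(cat, seed = 1)) == nLoci(cat)  # simulated loci are spaced
#' @export
pruneLoci <- function(catalog, windowBp = 1e6, seed) {
    stopifnot(is(catalog, "StudyCatalog"))
    if (missing(seed))
        stop("'seed' is required: cluster representatives are drawn at random")
    loci <- catalogLoci(catalog)
    pos <- start(loci)
    if (any(is.na(pos)))
        stop("loci without positions: ",
             paste(mcols(loci)$variant_id[is.na(pos)], collapse = ", "))
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    keep <- integer(0)
    pid <- mcols(loci)$paper_id
    for (p in unique(pid)) {
        pidx <- which(pid == p)
        chr <- as.character(seqnames(loci))[pidx]
        for (ch in unique(chr)) {
            cidx <- pidx[chr == ch]
            ord <- cidx[order(pos[cidx])]
            d <- diff(pos[ord])
            cluster <- cumsum(c(1L, as.integer(d > windowBp)))
            for (cl in split(ord, cluster)) {
                keep <- c(keep,
                          if (length(cl) == 1L) cl
                          else cl[sample.int(length(cl), 1L)])
            }
        }
    }
    keep <- sort(keep)
    out <- catalog
    out@loci <- loci[keep]
    if (is(out, "SyntheticCatalog"))
        out@truth <- out@truth[keep, , drop = FALSE]
    validObject(out)
    out
}

#' Subset a catalog on paper-level reporting flags
#'
#' Retains the papers satisfying the requested conjunction of flags
#' (same continental ancestry between stages; per-locus replication N), and
#' their loci. Variant records are never altered.
#'
#' @param catalog a \code{StudyCatalog}.
#' @param requireSameAncestry require \code{same_ancestry} papers.
#' @param requirePerLocusN require \code{per_locus_n} papers.
#' @return the subset \code{StudyCatalog}.
#' @export
subsetCatalog <- function(catalog, requireSameAncestry = FALSE,
                          requirePerLocusN = FALSE) {
    stopifnot(is(catalog, "StudyCatalog"))
    papers <- catalogPapers(catalog)
    keep <- rep(TRUE, nrow(papers))
    if (requireSameAncestry) keep <- keep & papers$same_ancestry
    if (requirePerLocusN) keep <- keep & papers$per_locus_n
    kept_ids <- papers$paper_id[keep]
    lkeep <- mcols(catalogLoci(catalog))$paper_id %in% kept_ids
    out <- catalog
    out@papers <- papers[keep, , drop = FALSE]
    out@loci <- catalogLoci(catalog)[lkeep]
    if (is(out, "SyntheticCatalog"))
        out@truth <- out@truth[lkeep, , drop = FALSE]
    validObject(out)
    out
}
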