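# Perfect 7-mer miRNA seed-match scanning in UTR sequences, conservation
# labelling from an external site table, and per-site score attachment.

#' Derive the 7-nt seed-match site from a mature miRNA sequence
#'
#' The seed is miRNA bases 2-8 (1-based, 5' end); the target site is its
#' reverse complement in the DNA alphabet.
#'
#' @param matureSeq mature miRNA sequence(s), RNA alphabet (length >= 8)
#' @return character vector of 7-nt DNA site sequences
#' @export
seedFromMirna <- function(matureSeq) {
    matureSeq <- toupper(matureSeq)
    if (any(nchar(matureSeq) < 8L))
        stop("mature miRNA sequence must be at least 8 nt")
    if (any(grepl("[^ACGU]", matureSeq)))
        stop("mature miRNA sequence must be RNA alphabet {A,C,G,U}")
    seed <- substr(matureSeq, 2L, 8L)
    dna <- DNAStringSet(chartr("U", "T", seed))
    as.character(reverseComplement(dna), use.names = FALSE)
}

#' Scan UTR sequences for perfect 7-mer seed-match sites
#'
#' Reports every exact occurrence of every seed family's site 7-mer in every
#' UTR sequence, including overlapping occurrences and multiple families
#' matching the same position.  \code{N} bases never match.
#'
#' @param utrs a [UTRSet-class]
#' @param seeds data.frame from [readSeedTable()] (\code{family_id},
#'   \code{site7}, \code{conserved_family})
#' @return \code{DataFrame} with one row per site: \code{gene_id},
#'   \code{accession}, \code{utr_start} (0-based 5' end of the 7-mer),
#'   \code{family_id}, \code{conserved_family}, and placeholder columns
#'   \code{conserved} (FALSE until [labelConserved()]), \code{pct} and
#'   \code{context_score} (NA until [attachScores()])
#' @export
scanSeedSites <- function(utrs, seeds) {
    stopifnot(all(c("family_id", "site7") %in% names(seeds)))
    rows <- vector("list", nrow(seeds))
    for (i in seq_len(nrow(seeds))) {
        hits <- vmatchPattern(seeds$site7[i], utrs@seq, fixed = TRUE)
        nh <- elementNROWS(hits)
        if (sum(nh) == 0L) next
        which_utr <- rep(seq_along(utrs@seq), nh)
        rows[[i]] <- data.frame(
            gene_id = utrs@geneId[which_utr],
            accession = utrs@accession[which_utr],
            utr_start = unlist(start(hits), use.names = FALSE) - 1L,
            family_id = seeds$family_id[i],
            conserved_family =
                if ("conserved_family" %in% names(seeds))
                    seeds$conserved_family[i] else NA
        )
    }
    df <- do.call(rbind, rows)
    if (is.null(df))
        df <- data.frame(gene_id = character(0), accession = character(0),
                         utr_start = integer(0), family_id = character(0),
                         conserved_family = logical(0))
    df <- df[order(df$gene_id, df$utr_start, df$family_id), , drop = FALSE]
    out <- DataFrame(df, row.names = NULL)
    out$conserved <- rep(FALSE, nrow(out))
    out$pct <- rep(NA_real_, nrow(out))
    out$context_score <- rep(NA_real_, nrow(out))
    out
}

.siteKey <- function(gene, pos, family) paste(gene, pos, family, sep = "\r")

.validateSiteTable <- function(table, utrs, seeds, what, maxMismatch = 0.05) {
    ## coordinate-system sanity: the 7-mer at each table position must be the
    ## family's site sequence
    if (nrow(table) == 0L)
        return(invisible(0))
    site7 <- setNames(seeds$site7, seeds$family_id)
    seqs <- utrSeqs(utrs)
    geneAcc <- setNames(utrs@accession, utrs@geneId)
    known <- table$gene_id %in% names(geneAcc) &
        table$family_id %in% names(site7)
    mism <- 0L
    checked <- 0L
    for (i in which(known)) {
        s <- seqs[[geneAcc[[table$gene_id[i]]]]]
        st <- table$utr_start[i] + 1L
        if (st < 1L || st + 6L > length(s)) {
            mism <- mism + 1L
            checked <- checked + 1L
            next
        }
        checked <- checked + 1L
        if (as.character(subseq(s, st, st + 6L)) != site7[[table$family_id[i]]])
            mism <- mism + 1L
    }
    rate <- if (checked) mism / checked else 0
    if (rate > maxMismatch)
        stop(sprintf(
            "%s table: %.1f%% of entries do not match the family 7-mer at the
 stated UTR position - likely a coordinate-system mismatch", what, 100 * rate))
    if (mism > 0L)
        message(sprintf("%s table: %d/%d entries (%.2f%%) mismatch the family
 7-mer at the stated position", what, mism, checked, 100 * rate))
    invisible(rate)
}

#' Label scanned sites as conserved from an external conserved-site table
#'
#' A site is conserved iff a (gene, utr_start, family) row is present in the
#' table; all other sites are non-conserved.  The table's coordinate system is
#' validated by checking that the 7-mer at each listed position equals the
#' family's site sequence; a mismatch rate above 5% is an error.
#'
#' @param sites DataFrame from [scanSeedSites()]
#' @param table data.frame from [readSiteTable()]
#' @param utrs the UTRSet the sites were scanned from (for validation)
#' @param seeds the seed table (for validation)
#' @return \code{sites} with the \code{conserved} flag set
#' @export
labelConserved <- function(sites, table, utrs = NULL, seeds = NULL) {
    if (!is.null(utrs) && !is.null(seeds))
        .validateSiteTable(table, utrs, seeds, "conserved-site")
    key <- .siteKey(sites$gene_id, sites$utr_start, sites$family_id)
    tkey <- .siteKey(table$gene_id, table$utr_start, table$family_id)
    sites$conserved <- key %in% tkey
    sites
}

#' Attach per-site scores (P_CT-like or context-like) from a score table
#'
#' @param sites DataFrame from [scanSeedSites()]
#' @param table data.frame with \code{gene_id}, \code{utr_start},
#'   \code{family_id}, \code{score}
#' @param kind "pct" (fills \code{pct}) or "context" (fills
#'   \code{context_score})
#' @inheritParams labelConserved
#' @return \code{sites} with scores attached where present (NA elsewhere)
#' @export
attachScores <- function(sites, table, kind = c("pct", "context"),
                         utrs = NULL, seeds = NULL) {
    kind <- match.arg(kind)
    if (!"score" %in% names(table))
        stop("score table requires a 'score' column")
    if (!is.null(utrs) && !is.null(seeds))
        .validateSiteTable(table, utrs, seeds, paste0(kind, "-score"))
    tkey <- .siteKey(table$gene_id, table$utr_start, table$family_id)
    if (anyDuplicated(tkey)) {
        dup <- split(table$score, tkey)
        bad <- vapply(dup, function(v) length(unique(v)) > 1L, TRUE)
        if (any(bad))
            stop("duplicate site keys with conflicting scores in ", kind,
                 " table")
        keep <- !duplicated(tkey)
        table <- table[keep, , drop = FALSE]
        tkey <- tkey[keep]
    }
    key <- .siteKey(sites$gene_id, sites$utr_start, sites$family_id)
    m <- match(key, tkey)
    col <- if (kind == "pct") "pct" else "context_score"
    sites[[col]] <- ifelse(is.na(m), NA_real_, table$score[m])
    sites
}

#' Write scanned seed-match sites as a TSV
#' @param sites DataFrame from [scanSeedSites()]
#' @param path output path
#' @param params optional provenance strings
#' @return invisibly, the path
#' @export
writeSeedSites <- function(sites, path, params = character()) {
    writeTsv(as.data.frame(sites), path, params)
}
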