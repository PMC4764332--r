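# Assignment of cleavage sites to 3'UTR models and APA calling.  A gene is
# APA-positive iff at least two cleavage sites are assigned to its 3'UTR
# (including a 20-nt slack past the annotated 3' end); the analysis anchor is
# the 5'-most assigned site.

.slackRanges <- function(utrs, tailSlack) {
    ## tailSlack nt immediately 3' of each UTR's transcript-sense end
    n <- length(utrs)
    chrom <- character(n); lo <- integer(n); hi <- integer(n); str <- character(n)
    for (i in seq_len(n)) {
        gr <- utrs@ranges[[i]]
        chrom[i] <- as.character(seqnames(gr)[1L])
        str[i] <- as.character(strand(gr)[1L])
        if (str[i] == "-") {
            hi[i] <- min(start(gr)) - 1L
            lo[i] <- hi[i] - tailSlack + 1L
        } else {
            lo[i] <- max(end(gr)) + 1L
            hi[i] <- lo[i] + tailSlack - 1L
        }
    }
    lo <- pmax(lo, 1L)
    GRanges(chrom, IRanges(lo, pmax(hi, lo - 1L)), strand = str)
}

#' Assign cleavage sites to 3'UTR models and call APA genes
#'
#' A cleavage site is assigned to a gene if its position falls within the
#' gene's 3'UTR intervals or within \code{tailSlack} nt 3' of the annotated
#' transcript-sense UTR end (slack sites are clamped to UTR position
#' \code{length - 1} for distance computations).  Genes with multiple
#' transcript accessions contribute their longest UTR.  Sites flagged as
#' internal-priming artifacts are excluded by default.  A gene is APA-positive
#' iff it has at least two assigned sites; its analysis anchor
#' (\code{apa_pos}) is the 5'-most assigned site in UTR coordinates.
#'
#' @param sites cleavage-site GRanges from [callCleavageSites()]
#' @param utrs a [UTRSet-class]
#' @param tailSlack nt past the annotated 3' end still assigned (default 20)
#' @param excludeInternalPriming drop sites with \code{internal_priming ==
#'   TRUE} before assignment (default TRUE)
#' @param longestPerGene reduce the UTRSet to one (longest) model per gene
#'   before assignment (default TRUE)
#' @param minSupportPerSample if the sites carry a per-sample \code{counts}
#'   matrix, a per-sample APA flag matrix (\code{apa_in_sample}) is computed
#'   calling a gene APA-positive within a sample iff >= 2 of its assigned
#'   sites have at least this many reads in that sample (default 10)
#' @return \code{DataFrame}, one row per gene, with columns \code{gene_id},
#'   \code{accession}, \code{utr_length}, \code{n_cs},
#'   \code{cs_utr_positions} (IntegerList, sorted ascending), \code{apa_pos}
#'   (NA unless APA-positive), \code{distal_pos}, \code{upstream_len},
#'   \code{downstream_len}, \code{shared_cs} (TRUE if any of the gene's sites
#'   was also assigned to another gene) and, when per-sample counts are
#'   available, \code{apa_in_sample}
#' @export
assignApa <- function(sites, utrs, tailSlack = 20L,
                      excludeInternalPriming = TRUE,
                      longestPerGene = TRUE,
                      minSupportPerSample = 10L) {
    if (longestPerGene)
        utrs <- selectLongestUtr(utrs)
    counts <- mcols(sites)$counts
    keep <- rep(TRUE, length(sites))
    if (excludeInternalPriming && length(sites))
        keep <- !vapply(sites$internal_priming, isTRUE, TRUE)
    sites <- sites[keep]
    if (!is.null(counts))
        counts <- counts[keep, , drop = FALSE]
    n <- length(utrs)
    len <- unname(width(utrs@seq))
    csPos <- vector("list", n)          # per gene: UTR-relative CS positions
    csIdx <- vector("list", n)          # per gene: indices into `sites`
    if (length(sites) && n) {
        utrGr <- unlist(utrs@ranges, use.names = FALSE)
        utrOf <- rep(seq_len(n), elementNROWS(utrs@ranges))
        hits <- findOverlaps(sites, utrGr)
        hitUtr <- utrOf[subjectHits(hits)]
        hitPos <- genomicToUtr(utrs, utrs@accession[hitUtr],
                               start(sites)[queryHits(hits)])
        slack <- .slackRanges(utrs, tailSlack)
        sh <- findOverlaps(sites, slack)
        ## a site in both the UTR and another gene's slack counts for both
        allUtr <- c(hitUtr, subjectHits(sh))
        allSite <- c(queryHits(hits), queryHits(sh))
        allPos <- c(hitPos, len[subjectHits(sh)] - 1L)
        for (g in unique(allUtr)) {
            m <- allUtr == g
            csPos[[g]] <- sort(allPos[m])
            csIdx[[g]] <- allSite[m]
        }
    }
    nCs <- lengths(csPos)
    siteUse <- table(unlist(csIdx))
    sharedSites <- as.integer(names(siteUse)[siteUse > 1L])
    shared <- vapply(csIdx, function(ix) any(ix %in% sharedSites), TRUE)
    apaPos <- ifelse(nCs >= 2L,
                     vapply(csPos, function(p)
                         if (length(p)) p[1L] else NA_integer_, 1L),
                     NA_integer_)
    distal <- vapply(csPos, function(p)
        if (length(p)) p[length(p)] else NA_integer_, 1L)
    out <- DataFrame(
        gene_id = utrs@geneId,
        accession = utrs@accession,
        utr_length = len,
        n_cs = as.integer(nCs),
        cs_utr_positions = IntegerList(csPos),
        apa_pos = as.integer(apaPos),
        distal_pos = as.integer(distal),
        upstream_len = as.integer(apaPos),
        downstream_len = as.integer(len - apaPos),
        shared_cs = shared
    )
    if (!is.null(counts) && ncol(counts) > 0L) {
        flags <- matrix(FALSE, nrow = n, ncol = ncol(counts),
                        dimnames = list(NULL, colnames(counts)))
        for (g in seq_len(n)) {
            ix <- csIdx[[g]]
            if (length(ix) >= 2L)
                flags[g, ] <- colSums(counts[ix, , drop = FALSE] >=
                                      minSupportPerSample) >= 2L
        }
        out$apa_in_sample <- flags
    }
    metadata(out)$tail_slack <- tailSlack
    out
}

#' Keep APA-positive genes with enough UTR sequence on both sides of the APA
#'
#' @param calls DataFrame from [assignApa()]
#' @param minFlank minimum nt of UTR sequence required both 5' and 3' of the
#'   APA position
#' @return the qualifying subset of \code{calls}
#' @export
filterFlank <- function(calls, minFlank) {
    stopifnot(minFlank >= 0L)
    keep <- !is.na(calls$apa_pos) &
        calls$upstream_len >= minFlank &
        calls$downstream_len >= minFlank
    calls[keep, ]
}

#' Per-gene anchor positions for positional analyses
#'
#' For \code{anchor = "apa"}, the 5'-most APA site.  For \code{anchor =
#' "utr_end"} (the full-length 3'UTR end), the distal assigned cleavage site
#' when one exists, else the last base of the annotated UTR.
#'
#' @param calls DataFrame from [assignApa()]
#' @param anchor "apa" or "utr_end"
#' @return integer vector of 0-based UTR anchor positions (NA where undefined)
#' @export
apaAnchor <- function(calls, anchor = c("apa", "utr_end")) {
    anchor <- match.arg(anchor)
    if (anchor == "apa")
        return(calls$apa_pos)
    ifelse(is.na(calls$distal_pos), calls$utr_length - 1L, calls$distal_pos)
}

#' Write APA calls as a TSV
#'
#' @param calls DataFrame from [assignApa()]
#' @param path output path
#' @param params optional provenance strings
#' @return invisibly, the path
#' @export
writeApaCalls <- function(calls, path, params = character()) {
    df <- data.frame(
        gene_id = calls$gene_id,
        accession = calls$accession,
        utr_length = calls$utr_length,
        n_cs = calls$n_cs,
        cs_utr_positions = vapply(calls$cs_utr_positions,
                                  paste, "", collapse = ","),
        apa_pos = calls$apa_pos,
        upstream_len = calls$upstream_len,
        downstream_len = calls$downstream_len,
        shared_cs = calls$shared_cs
    )
    if (!is.null(calls$apa_in_sample))
        for (s in colnames(calls$apa_in_sample))
            df[[paste0("APA_", s)]] <- calls$apa_in_sample[, s]
    writeTsv(df, path, params)
}
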