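# Mean per-base conservation profiles around transcript-sense anchors
# (APA sites or seed-match sites), from a sparse per-base score track.
# Missing scores are excluded from means, never imputed as 0.

#' Mean conservation profile around UTR anchors
#'
#' For each transcript-sense offset in \code{[-flank5p, flank3p)}, averages
#' the track score at the strand-aware genomic base lying at that offset from
#' each anchor, over the anchors for which that base exists (inside the UTR)
#' and has a score.  Offsets with no contributing anchor are NA.
#'
#' @param utrs a [UTRSet-class]
#' @param anchors data.frame with columns \code{accession} and \code{utr_pos}
#'   (0-based anchor positions)
#' @param track a [ConservationTrack-class]
#' @param flank5p,flank3p bases 5' / 3' of the anchor (anchor itself is
#'   offset 0, included in the 3' side)
#' @return data.frame(offset, mean, n)
#' @export
conservationProfile <- function(utrs, anchors, track, flank5p = 12L,
                                flank3p = 19L) {
    stopifnot(flank5p >= 0L, flank3p >= 0L)
    offsets <- seq(-flank5p, flank3p - 1L)
    if (nrow(anchors) == 0L)
        return(data.frame(offset = offsets, mean = NA_real_, n = 0L))
    i <- .utrIndex(utrs, anchors$accession)
    len <- width(utrs@seq)[i]
    chrom <- vapply(utrs@ranges[i], function(gr)
        as.character(seqnames(gr)[1L]), "")
    acc <- rep(anchors$accession, each = length(offsets))
    upos <- rep(anchors$utr_pos, each = length(offsets)) + offsets
    inUtr <- upos >= 0L & upos < rep(len, each = length(offsets))
    gpos <- rep(NA_integer_, length(upos))
    gpos[inUtr] <- utrToGenomic(utrs, acc[inUtr], upos[inUtr])
    sc <- rep(NA_real_, length(upos))
    sc[inUtr] <- trackScores(track,
                             rep(chrom, each = length(offsets))[inUtr],
                             gpos[inUtr])
    offv <- rep(offsets, nrow(anchors))
    ok <- !is.na(sc)
    n <- as.integer(tapply(ok, offv, sum))
    mu <- tapply(sc, offv, function(v) mean(v, na.rm = TRUE))
    ord <- order(as.integer(names(mu)))
    data.frame(offset = as.integer(names(mu))[ord],
               mean = ifelse(n[ord] > 0L, as.numeric(mu)[ord], NA_real_),
               n = n[ord], row.names = NULL)
}

#' Conservation profile around APA sites, split by presence of a conserved
#' seed site in the window 5' of the APA
#'
#' Genes (flank-filtered APA calls) are split by whether they carry at least
#' one conserved seed-match site with \code{utr_start} in
#' \code{[apa - window5p, apa)}; a mean conservation profile around the APA
#' anchor is returned for each group.
#'
#' @param calls flank-filtered DataFrame from [assignApa()]
#' @param sites labelled sites DataFrame
#' @param utrs a [UTRSet-class]
#' @param track a [ConservationTrack-class]
#' @param flank profile half-width around the APA (default 1000)
#' @param window5p window defining "has a conserved site 5' of the APA"
#'   (default 300)
#' @return list with data.frames \code{with_site} and \code{without_site}
#'   (either NULL, with a message, when its group is empty) and the group
#'   sizes
#' @export
conservationByGroup <- function(calls, sites, utrs, track, flank = 1000L,
                                window5p = 300L) {
    calls <- filterFlank(calls, flank)
    if (nrow(calls) == 0L)
        stop("no genes left after the flank filter")
    apa <- setNames(calls$apa_pos, calls$gene_id)
    s <- sites[sites$conserved & sites$gene_id %in% names(apa), , drop = FALSE]
    d <- s$utr_start - apa[s$gene_id]
    hasSite <- unique(s$gene_id[d >= -window5p & d < 0L])
    grp <- calls$gene_id %in% hasSite
    prof <- function(sub) {
        if (nrow(sub) == 0L)
            return(NULL)
        conservationProfile(
            utrs,
            data.frame(accession = sub$accession, utr_pos = sub$apa_pos),
            track, flank5p = flank, flank3p = flank)
    }
    withSite <- prof(calls[grp, ])
    withoutSite <- prof(calls[!grp, ])
    if (is.null(withSite))
        message("no genes with a conserved site in the 5' window")
    if (is.null(withoutSite))
        message("no genes without a conserved site in the 5' window")
    list(with_site = withSite, without_site = withoutSite,
         n_with = sum(grp), n_without = sum(!grp))
}
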