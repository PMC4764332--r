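# Poly(A) cleavage-site calling from pooled 3'-end read positions:
# read-run clustering, local-maxima site selection with greedy spacing
# resolution, support filtering, and the internal-priming composition filter.
# Deterministic given its inputs; no RNG in this module.

#' Cluster pooled 3'-end read positions into read runs
#'
#' A read run is a maximal set of occupied positions on one chromosome/strand
#' in which the distance between consecutive occupied positions is below
#' \code{gapMax}.  Reads from all samples are pooled.
#'
#' @param ends width-1 GRanges of 3'-end positions (see [readReadEnds()])
#' @param gapMax runs break where consecutive occupied positions are >=
#'   \code{gapMax} apart (default 10 nt)
#' @return GRanges of runs (span from first to last occupied position) with
#'   metadata columns \code{positions} and \code{counts} (IntegerLists over
#'   occupied positions) and \code{total} read count
#' @export
buildRuns <- function(ends, gapMax = 10L) {
    stopifnot(gapMax >= 1L)
    if (length(ends) == 0L) {
        out <- GRanges()
        out$positions <- IntegerList()
        out$counts <- IntegerList()
        out$total <- integer(0)
        return(out)
    }
    key <- paste0(as.character(seqnames(ends)), "\r",
                  as.character(strand(ends)))
    pieces <- lapply(split(start(ends), key), function(p) {
        tab <- table(p)
        pos <- as.integer(names(tab))
        cnt <- as.integer(tab)
        o <- order(pos)
        pos <- pos[o]; cnt <- cnt[o]
        run <- cumsum(c(1L, as.integer(diff(pos) >= gapMax)))
        list(pos = splitAsList(pos, run), cnt = splitAsList(cnt, run))
    })
    keys <- rep(names(pieces), vapply(pieces, function(x) length(x$pos), 1L))
    chrom <- sub("\r.*$", "", keys)
    str <- sub("^.*\r", "", keys)
    posl <- do.call(c, unname(lapply(pieces, `[[`, "pos")))
    cntl <- do.call(c, unname(lapply(pieces, `[[`, "cnt")))
    out <- GRanges(chrom,
                   IRanges(min(posl), max(posl)),
                   strand = str)
    names(posl) <- names(cntl) <- NULL
    out$positions <- posl
    out$counts <- cntl
    out$total <- sum(cntl)
    sort(out, ignore.strand = FALSE)
}

## local maxima of one run's occupied-position counts; plateaus (adjacent
## occupied positions with tied counts) collapse to the 5'-most position
.runCandidates <- function(pos, cnt, minus) {
    k <- length(pos)
    left <- c(TRUE, cnt[-1L] >= cnt[-k])
    right <- c(cnt[-k] >= cnt[-1L], TRUE)
    cand <- left & right
    if (!any(cand))
        return(integer(0))
    idx <- which(cand)
    ## collapse consecutive candidate indices with equal counts
    blk <- cumsum(c(1L, as.integer(diff(idx) != 1L |
                                   cnt[idx[-1L]] != cnt[idx[-length(idx)]])))
    keep <- vapply(split(idx, blk), function(b)
        if (minus) b[length(b)] else b[1L], 1L)
    unname(keep)
}

#' Call cleavage sites from read runs
#'
#' Candidate sites are the local maxima of each run's per-position read
#' counts (tied plateaus keep the 5'-most position).  Per chromosome/strand,
#' candidates are then greedily accepted in order of decreasing support
#' (ties: 5'-most first); a candidate within \code{minSpacing - 1} nt of an
#' already kept site is rejected, so kept sites are pairwise >=
#' \code{minSpacing} apart.  Finally sites supported by fewer than
#' \code{minSupport} reads at the run maximum are dropped.
#'
#' @param runs GRanges from [buildRuns()]
#' @param minSupport minimum reads at the site position (default 10)
#' @param minSpacing minimum distance between kept sites (default 50 nt)
#' @return width-1 GRanges of cleavage sites with metadata columns
#'   \code{support}, \code{run_start}, \code{run_end} (closed genomic run
#'   span), \code{run_nocc} (number of occupied positions) and
#'   \code{internal_priming} (NA until [flagInternalPriming()] is applied)
#' @export
callSites <- function(runs, minSupport = 10L, minSpacing = 50L) {
    stopifnot(minSpacing >= 1L)
    if (length(runs) == 0L)
        return(.emptySites())
    cand <- vector("list", length(runs))
    for (i in seq_along(runs)) {
        pos <- runs$positions[[i]]
        cnt <- runs$counts[[i]]
        minus <- as.character(strand(runs)[i]) == "-"
        j <- .runCandidates(pos, cnt, minus)
        if (length(j))
            cand[[i]] <- data.frame(
                chrom = as.character(seqnames(runs)[i]),
                strand = as.character(strand(runs)[i]),
                pos = pos[j], support = cnt[j],
                run_start = start(runs)[i], run_end = end(runs)[i],
                run_nocc = length(pos))
    }
    cand <- do.call(rbind, cand)
    if (is.null(cand))
        return(.emptySites())
    kept <- vector("list", 0L)
    for (key in unique(paste0(cand$chrom, "\r", cand$strand))) {
        g <- cand[paste0(cand$chrom, "\r", cand$strand) == key, , drop = FALSE]
        minus <- g$strand[1L] == "-"
        o <- order(-g$support, if (minus) -g$pos else g$pos)
        g <- g[o, , drop = FALSE]
        keptPos <- integer(0)
        take <- logical(nrow(g))
        for (i in seq_len(nrow(g))) {
            if (length(keptPos) == 0L ||
                min(abs(keptPos - g$pos[i])) >= minSpacing) {
                take[i] <- TRUE
                keptPos <- c(keptPos, g$pos[i])
            }
        }
        kept[[key]] <- g[take, , drop = FALSE]
    }
    res <- do.call(rbind, kept)
    res <- res[res$support >= minSupport, , drop = FALSE]
    if (nrow(res) == 0L)
        return(.emptySites())
    out <- GRanges(res$chrom, IRanges(res$pos, width = 1L),
                   strand = res$strand)
    out$support <- as.integer(res$support)
    out$run_start <- as.integer(res$run_start)
    out$run_end <- as.integer(res$run_end)
    out$run_nocc <- as.integer(res$run_nocc)
    out$internal_priming <- NA
    sort(out, ignore.strand = FALSE)
}

.emptySites <- function() {
    out <- GRanges()
    out$support <- integer(0)
    out$run_start <- integer(0)
    out$run_end <- integer(0)
    out$run_nocc <- integer(0)
    out$internal_priming <- logical(0)
    out
}

#' Flag putative cleavage sites caused by internal priming
#'
#' Oligo-dT primers can misprime on genomically encoded A-rich stretches.
#' For each site, the 50-nt genomic window centered on the site (realized as
#' \code{[pos - window/2, pos + window/2)}) is taken in transcript sense
#' (reverse-complemented for minus-strand sites) and scanned for any
#' \code{k}-mer containing at least \code{minA} A's with all remaining bases
#' G.  Windows truncated by a contig end are scanned as far as they exist
#' (with a warning).
#'
#' @param sites GRanges from [callSites()]
#' @param genome genome FASTA path or DNAStringSet
#' @param window window length centered on the site (default 50)
#' @param k stretch length (default 10)
#' @param minA minimum A count within the stretch (default 8)
#' @return logical vector, TRUE where the site is a suspected internal-priming
#'   artifact
#' @export
flagInternalPriming <- function(sites, genome, window = 50L, k = 10L,
                                minA = 8L) {
    stopifnot(window >= k)
    genome <- .readGenome(genome)
    half <- window %/% 2L
    out <- logical(length(sites))
    truncated <- FALSE
    for (i in seq_along(sites)) {
        chrom <- as.character(seqnames(sites)[i])
        if (!chrom %in% names(genome))
            stop("chromosome '", chrom, "' absent from genome FASTA")
        contig <- genome[[chrom]]
        lo <- start(sites)[i] - half
        hi <- start(sites)[i] + half - 1L
        if (lo < 1L || hi > length(contig)) {
            truncated <- TRUE
            lo <- max(lo, 1L)
            hi <- min(hi, length(contig))
        }
        s <- subseq(contig, lo, hi)
        if (as.character(strand(sites)[i]) == "-")
            s <- reverseComplement(s)
        out[i] <- .hasARichStretch(s, k, minA)
    }
    if (truncated)
        warning("internal-priming window truncated at a contig end for ",
                "at least one site")
    out
}

.hasARichStretch <- function(s, k, minA) {
    if (length(s) < k)
        return(FALSE)
    m <- letterFrequencyInSlidingView(s, k, c("A", "G"))
    any(m[, "A"] >= minA & m[, "A"] + m[, "G"] == k)
}

#' Count read ends inside each site's run, per sample
#'
#' @param sites GRanges from [callSites()]
#' @param ends width-1 GRanges of read ends with a \code{sample} column
#' @return integer matrix, one row per site, one column per sample; row sums
#'   equal the run read totals
#' @export
quantifyPerSample <- function(sites, ends) {
    samples <- sort(unique(ends$sample))
    m <- matrix(0L, nrow = length(sites), ncol = length(samples),
                dimnames = list(NULL, samples))
    if (length(sites) == 0L || length(ends) == 0L)
        return(m)
    runs <- GRanges(seqnames(sites),
                    IRanges(sites$run_start, sites$run_end),
                    strand = strand(sites))
    hits <- findOverlaps(runs, ends)
    if (length(hits)) {
        tab <- table(queryHits(hits), ends$sample[subjectHits(hits)])
        m[as.integer(rownames(tab)), colnames(tab)] <-
            m[as.integer(rownames(tab)), colnames(tab)] + unclass(tab)
    }
    m
}

#' Full cleavage-site calling pipeline
#'
#' [buildRuns()] on pooled reads, [callSites()], [flagInternalPriming()], and
#' per-sample quantification, in the canonical order: spacing resolution and
#' the support filter are applied before the composition flag, and flagged
#' sites are retained in the output (marked) so downstream steps can decide
#' to exclude them.
#'
#' @inheritParams buildRuns
#' @inheritParams callSites
#' @inheritParams flagInternalPriming
#' @return GRanges of cleavage sites with \code{internal_priming} set and a
#'   \code{counts} integer matrix column of per-sample read counts
#' @export
callCleavageSites <- function(ends, genome, gapMax = 10L, minSupport = 10L,
                              minSpacing = 50L, window = 50L, k = 10L,
                              minA = 8L) {
    runs <- buildRuns(ends, gapMax = gapMax)
    sites <- callSites(runs, minSupport = minSupport, minSpacing = minSpacing)
    if (length(sites))
        sites$internal_priming <- flagInternalPriming(
            sites, genome, window = window, k = k, minA = minA)
    mcols(sites)$counts <- quantifyPerSample(sites, ends)
    sites
}

#' Write called cleavage sites as a TSV
#'
#' Columns mirror a deposited 3'seq result table: 0-based half-open run
#' interval \code{RUN_S}/\code{RUN_E}, the run maximum \code{RUN_MAX}
#' (0-based), \code{SUPPORT}, \code{RUN_SPAN} (half-open span) and
#' \code{RUN_NOCC} (occupied positions), per-sample read counts, and
#' \code{InternalPrim_FLAG}.
#'
#' @param sites GRanges from [callCleavageSites()]
#' @param path output TSV
#' @param params optional "name=value" strings for the provenance comment
#' @return invisibly, the path
#' @export
writeCleavageSites <- function(sites, path, params = character()) {
    df <- data.frame(
        CHROM = as.character(seqnames(sites)),
        STRAND = as.character(strand(sites)),
        RUN_S = sites$run_start - 1L,
        RUN_E = sites$run_end,
        RUN_MAX = start(sites) - 1L,
        SUPPORT = sites$support,
        RUN_SPAN = sites$run_end - sites$run_start + 1L,
        RUN_NOCC = sites$run_nocc
    )
    cm <- mcols(sites)$counts
    if (!is.null(cm))
        for (s in colnames(cm))
            df[[paste0("READS_", s)]] <- cm[, s]
    df$InternalPrim_FLAG <- as.integer(sites$internal_priming)
    writeTsv(df, path, params)
}
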