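# Positional enrichment statistics: binned site-density profiles around
# per-gene anchors, the randomized-APA null model, the two-gene-set partition
# permutation test, the cluster-versus-all permutation test, score-window
# comparisons and the APA-vs-non-APA relative-position comparison.
#
# Distances are UTR-relative: d = utr_start - anchor.  Negative d is 5'
# (upstream) of the anchor; a site exactly at the anchor (d = 0) belongs to
# the first downstream bin (half-open binning).  All permutation p-values use
# the +1-corrected one-sided estimator (1 + #{null >= observed}) / (1 + nIter),
# which is never exactly 0.

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    force(expr)
}

.checkBins <- function(flank, binWidth) {
    if (flank %% binWidth != 0L)
        stop("flank (", flank, ") must be a multiple of bin width (",
             binWidth, ")")
    as.integer(seq(-flank, flank, by = binWidth))
}

## bin index in 1..nb for distances in [-flank, flank), else NA
.binIndex <- function(d, flank, binWidth) {
    idx <- (d + flank) %/% binWidth + 1L
    idx[d < -flank | d >= flank] <- NA_integer_
    idx
}

## per-gene x per-bin site-count matrix for genes in `calls`
.geneBinMatrix <- function(calls, sites, anchor, flank, binWidth,
                           conservedOnly = TRUE) {
    edges <- .checkBins(flank, binWidth)
    nb <- length(edges) - 1L
    anch <- apaAnchor(calls, anchor)
    genes <- calls$gene_id
    M <- matrix(0L, nrow = length(genes), ncol = nb)
    s <- sites
    if (conservedOnly)
        s <- s[s$conserved, , drop = FALSE]
    g <- match(s$gene_id, genes)
    ok <- !is.na(g) & !is.na(anch[g])
    if (any(ok)) {
        d <- s$utr_start[ok] - anch[g[ok]]
        b <- .binIndex(d, flank, binWidth)
        ok2 <- !is.na(b)
        lin <- b[ok2] + nb * (g[ok][ok2] - 1L)
        tab <- tabulate(lin, nbins = nb * length(genes))
        M <- matrix(tab, nrow = length(genes), ncol = nb, byrow = TRUE)
    }
    list(M = M, edges = edges, anchors = anch)
}

#' Binned positional profile of seed-match sites around a per-gene anchor
#'
#' Each site contributes one count to the bin containing its distance
#' \code{utr_start - anchor}; sites outside \code{[-flank, flank)} are
#' ignored.  Conserved and non-conserved sites are tallied separately.  For
#' \code{anchor = "apa"}, pass calls filtered with
#' \code{\link{filterFlank}(calls, flank)} so every gene has sequence across
#' all bins; for \code{anchor = "utr_end"} pass APA-positive genes with at
#' least \code{flank} nt 5' of the full-length UTR end.
#'
#' @param calls DataFrame from [assignApa()] (pre-filtered, see above)
#' @param sites DataFrame from [scanSeedSites()]
#' @param anchor "apa" (5'-most APA site) or "utr_end" (full-length UTR end)
#' @param flank profile half-width in nt (default 1000)
#' @param binWidth bin width in nt (default 100; must divide flank)
#' @return a [PositionalProfile-class]
#' @export
profileSites <- function(calls, sites, anchor = c("apa", "utr_end"),
                         flank = 1000L, binWidth = 100L) {
    anchor <- match.arg(anchor)
    edges <- .checkBins(flank, binWidth)
    nb <- length(edges) - 1L
    anch <- apaAnchor(calls, anchor)
    use <- !is.na(anch)
    calls <- calls[use, ]
    anch <- anch[use]
    cons <- .geneBinMatrix(calls, sites, anchor, flank, binWidth,
                           conservedOnly = TRUE)$M
    s <- sites[!sites$conserved, , drop = FALSE]
    noncons <- .geneBinMatrix(calls, s, anchor, flank, binWidth,
                              conservedOnly = FALSE)$M
    covered <- vapply(seq_len(nb), function(b)
        sum(anch + edges[b] >= 0L & anch + edges[b + 1L] <= calls$utr_length),
        1L)
    new("PositionalProfile",
        anchor = anchor,
        binEdges = edges,
        countsConserved = as.integer(colSums(cons)),
        countsNonconserved = as.integer(colSums(noncons)),
        nGenes = length(anch),
        genesPerBin = covered)
}

#' Randomized-APA null model for positional site enrichment
#'
#' Tests, per bin of distance from the APA site, the null hypothesis that the
#' number of conserved seed-match sites at that distance from the true APA
#' site is no larger than at a randomly placed APA site.  Per iteration, each
#' participating gene receives a pseudo-APA position drawn uniformly from
#' \code{[flank, utr_length - flank)} (the first and last \code{flank} bases
#' are omitted so the full profile window fits), and the same binned counting
#' is applied.
#'
#' Only genes with \code{utr_length > 2 * flank} participate; others are
#' excluded (with a message).  Pass flank-filtered APA-positive calls.
#'
#' @param calls DataFrame from [assignApa()], flank-filtered
#' @param sites DataFrame from [scanSeedSites()] with conservation labels
#' @param flank profile half-width (default 1000 nt)
#' @param binWidth bin width (default 100 nt)
#' @param nIter randomization iterations (default 10000)
#' @param seed integer RNG seed (required; ensemble is reproducible)
#' @param conservedOnly count conserved sites only (default TRUE, matching
#'   the tested hypothesis)
#' @param ties "conservative" (default): ties between the observed statistic
#'   and null draws count toward the p-value, the standard never-zero
#'   +1-corrected estimator; "randomized": the observed value is ranked
#'   uniformly within its tie group, giving exactly uniform p-values under
#'   the null (used for calibration assessment; never larger than the
#'   conservative value)
#' @return a [PermTestResult-class] with per-bin observed counts, the null
#'   ensemble and one-sided p-values
#' @export
randomizedApaNull <- function(calls, sites, flank = 1000L, binWidth = 100L,
                              nIter = 10000L, seed, conservedOnly = TRUE,
                              ties = c("conservative", "randomized")) {
    ties <- match.arg(ties)
    edges <- .checkBins(flank, binWidth)
    nb <- length(edges) - 1L
    ok <- !is.na(calls$apa_pos) & calls$utr_length > 2L * flank
    if (!any(ok))
        stop("no eligible genes: need APA-positive genes with utr_length > ",
             2L * flank)
    if (any(!ok))
        message(sum(!ok), " gene(s) excluded (utr_length <= ", 2L * flank,
                " or no APA site)")
    calls <- calls[ok, ]
    gb <- .geneBinMatrix(calls, sites, "apa", flank, binWidth,
                         conservedOnly = conservedOnly)
    obs <- colSums(gb$M)
    s <- if (conservedOnly) sites[sites$conserved, , drop = FALSE] else sites
    g <- match(s$gene_id, calls$gene_id)
    sp <- s$utr_start[!is.na(g)]
    gi <- g[!is.na(g)]
    nG <- nrow(calls)
    len <- calls$utr_length
    lo <- flank                     # anchors uniform on [flank, len - flank)
    span <- len - 2L * flank        # > 0 for all participants
    null <- matrix(0L, nrow = nIter, ncol = nb)
    .withSeed(seed, {
        chunk <- 200L
        it <- 0L
        while (it < nIter) {
            m <- min(chunk, nIter - it)
            A <- matrix(lo + floor(runif(nG * m) * span),
                        nrow = nG, ncol = m)
            if (length(sp)) {
                D <- sp - A[gi, , drop = FALSE]
                B <- (D + flank) %/% binWidth + 1L
                B[D < -flank | D >= flank] <- NA_integer_
                lin <- B + nb * rep(0:(m - 1L), each = length(sp))
                tab <- tabulate(lin[!is.na(lin)], nbins = nb * m)
                null[it + seq_len(m), ] <-
                    matrix(tab, nrow = m, ncol = nb, byrow = TRUE)
            }
            it <- it + m
        }
        if (ties == "randomized")
            u <- runif(nb)
    })
    if (ties == "conservative")
        u <- NULL
    .permResult("randomized_apa", edges, as.numeric(obs), null * 1.0,
                nIter, seed,
                list(n_genes = nG, statistic = if (conservedOnly)
                    "conserved_count" else "site_count", ties = ties),
                u = u)
}

## +1-corrected one-sided permutation p-values.  With u = NULL (the
## default "conservative" estimator) ties count toward the p-value:
## p = (1 + #{null >= obs}) / (1 + nIter); this is the standard
## never-zero estimator and is conservative when the statistic is discrete.
## With a vector u of per-bin uniforms ("randomized" tie handling) the
## observed value is ranked uniformly within its tie group, which makes the
## p-value exactly uniform on the 1/(1+nIter) grid under exchangeability;
## the randomized value never exceeds the conservative one.
.permPvalues <- function(obs, null, nIter, u = NULL) {
    nb <- length(obs)
    vapply(seq_len(nb), function(b) {
        gt <- sum(null[, b] > obs[b])
        eq <- sum(null[, b] == obs[b])
        if (is.null(u))
            (1 + gt + eq) / (1 + nIter)
        else
            (1 + gt + floor(u[b] * (eq + 1))) / (1 + nIter)
    }, 1.0)
}

.permResult <- function(test, edges, obs, null, nIter, seed, info, u = NULL) {
    new("PermTestResult", test = test, binEdges = edges,
        observed = as.numeric(obs), nullStats = null,
        pValues = .permPvalues(obs, null, nIter, u),
        nIter = as.integer(nIter), seed = as.integer(seed),
        info = info)
}

#' Two-gene-set partition permutation test on positional site density
#'
#' Per bin, the statistic is the difference in per-gene conserved-site density
#' between \code{setB} and \code{setA} (density of \code{setB} minus density
#' of \code{setA}; densities are per contributing gene, so unequal set sizes
#' are comparable).  The null randomly re-partitions the union of the two
#' sets into groups of the original sizes; the one-sided p-value asks whether
#' the observed excess in \code{setB} is as large or larger under random
#' partitions.
#'
#' @param setA,setB disjoint character vectors of gene ids (e.g.
#'   pro-proliferation and pro-differentiation sets); both must intersect the
#'   profiled genes
#' @param calls flank-filtered DataFrame from [assignApa()]
#' @param sites labelled sites DataFrame
#' @inheritParams randomizedApaNull
#' @return a [PermTestResult-class]
#' @export
twoSetPartitionTest <- function(setA, setB, calls, sites, flank = 1000L,
                                binWidth = 100L, nIter = 10000L, seed,
                                ties = c("conservative", "randomized")) {
    ties <- match.arg(ties)
    if (length(setA) == 0L || length(setB) == 0L)
        stop("empty gene set")
    if (length(intersect(setA, setB)))
        stop("setA and setB must be disjoint")
    calls <- calls[!is.na(calls$apa_pos), ]
    gb <- .geneBinMatrix(calls, sites, "apa", flank, binWidth,
                         conservedOnly = TRUE)
    iA <- which(calls$gene_id %in% setA)
    iB <- which(calls$gene_id %in% setB)
    if (length(iA) == 0L || length(iB) == 0L)
        stop("a gene set has no APA-profiled members")
    nA <- length(iA); nB <- length(iB)
    obs <- colSums(gb$M[iB, , drop = FALSE]) / nB -
        colSums(gb$M[iA, , drop = FALSE]) / nA
    pool <- c(iA, iB)
    nb <- ncol(gb$M)
    null <- matrix(0, nrow = nIter, ncol = nb)
    u <- NULL
    .withSeed(seed, {
        for (i in seq_len(nIter)) {
            pb <- sample(pool, nB)
            pa <- setdiff(pool, pb)
            null[i, ] <- colSums(gb$M[pb, , drop = FALSE]) / nB -
                colSums(gb$M[pa, , drop = FALSE]) / nA
        }
        if (ties == "randomized")
            u <- runif(nb)
    })
    .permResult("two_set_partition", gb$edges, obs, null, nIter, seed,
                list(nA = nA, nB = nB, n_genes = nrow(calls), ties = ties),
                u = u)
}

#' Cluster-versus-all permutation test on positional site density
#'
#' The target set is the profiled genes carrying at least one conserved site
#' of any of the given seed families (e.g. the miR-17-92 cluster families).
#' Per bin, the statistic compares the mean per-gene *site share* (the
#' fraction of a gene's in-window conserved sites falling in that bin)
#' between the target set and all comparison genes; the null redraws random
#' gene subsets of the target-set size from the comparison universe.
#'
#' Two design points keep the test calibrated: the comparison universe is
#' restricted to profiled genes that carry at least one conserved site
#' within the profile window (matching the conditioning of the target set,
#' which has a site by construction), and the per-gene share normalization
#' cancels differences in per-gene site abundance, isolating *positional*
#' structure.  When the cluster comprises all families the target set equals
#' the universe and the statistic is identically zero.
#'
#' @param clusterFamilies character vector of family ids defining the cluster
#' @inheritParams twoSetPartitionTest
#' @return a [PermTestResult-class]; \code{info} records the target-set size
#' @export
clusterVsAllTest <- function(clusterFamilies, calls, sites, flank = 1000L,
                             binWidth = 100L, nIter = 10000L, seed,
                             ties = c("conservative", "randomized")) {
    ties <- match.arg(ties)
    calls <- calls[!is.na(calls$apa_pos), ]
    gb <- .geneBinMatrix(calls, sites, "apa", flank, binWidth,
                         conservedOnly = TRUE)
    tot <- rowSums(gb$M)
    keep <- tot >= 1L
    if (!any(keep))
        stop("no profiled genes carry an in-window conserved site")
    calls <- calls[keep, ]
    S <- gb$M[keep, , drop = FALSE] / tot[keep]
    targGenes <- unique(sites$gene_id[sites$conserved &
                                      sites$family_id %in% clusterFamilies])
    iT <- which(calls$gene_id %in% targGenes)
    if (length(iT) == 0L)
        stop("cluster target set is empty among profiled genes")
    nT <- length(iT)
    nAll <- nrow(calls)
    allShare <- colSums(S) / nAll
    obs <- colSums(S[iT, , drop = FALSE]) / nT - allShare
    nb <- ncol(S)
    null <- matrix(0, nrow = nIter, ncol = nb)
    u <- NULL
    .withSeed(seed, {
        for (i in seq_len(nIter)) {
            r <- sample.int(nAll, nT)
            null[i, ] <- colSums(S[r, , drop = FALSE]) / nT - allShare
        }
        if (ties == "randomized")
            u <- runif(nb)
    })
    .permResult("cluster_vs_all", gb$edges, obs, null, nIter, seed,
                list(n_target = nT, n_genes = nAll,
                     families = clusterFamilies, ties = ties),
                u = u)
}

#' Compare site scores 5' versus 3' of the APA site
#'
#' Two-sample Student t-test (pooled variance by default, two-sided) on the
#' requested score between sites within \code{window} nt 5' of the APA site
#' (\code{utr_start} in \code{[apa - window, apa)}) and sites within
#' \code{window} nt 3' of it (\code{[apa, apa + window)}), over genes with at
#' least \code{minFlank} nt of UTR on each side of the APA site.  Sites
#' lacking the requested score are skipped.
#'
#' @param calls DataFrame from [assignApa()]
#' @param sites sites DataFrame carrying \code{pct} / \code{context_score}
#' @param window window size in nt on each side (default 300)
#' @param minFlank flank filter (default 500)
#' @param kind which score to compare: "pct" or "context"
#' @param conservedOnly restrict to conserved sites (default FALSE)
#' @param welch use Welch's unequal-variance t-test instead of the pooled
#'   Student test (default FALSE)
#' @return list with \code{mean_5p}, \code{mean_3p}, \code{t_statistic},
#'   \code{p_value}, \code{df}, \code{n_5p}, \code{n_3p}
#' @export
scoreWindowCompare <- function(calls, sites, window = 300L, minFlank = 500L,
                               kind = c("pct", "context"),
                               conservedOnly = FALSE, welch = FALSE) {
    kind <- match.arg(kind)
    col <- if (kind == "pct") "pct" else "context_score"
    calls <- filterFlank(calls, minFlank)
    apa <- setNames(calls$apa_pos, calls$gene_id)
    s <- sites[sites$gene_id %in% names(apa) & !is.na(sites[[col]]), ,
               drop = FALSE]
    if (conservedOnly)
        s <- s[s$conserved, , drop = FALSE]
    d <- s$utr_start - apa[s$gene_id]
    x5 <- s[[col]][d >= -window & d < 0L]
    x3 <- s[[col]][d >= 0L & d < window]
    if (length(x5) < 2L || length(x3) < 2L)
        stop("need at least 2 scored sites in each window (5': ", length(x5),
             ", 3': ", length(x3), ")")
    if (stats::var(x5) == 0 && stats::var(x3) == 0 &&
        mean(x5) == mean(x3))
        return(list(mean_5p = mean(x5), mean_3p = mean(x3),
                    t_statistic = 0, p_value = 1,
                    df = length(x5) + length(x3) - 2L,
                    n_5p = length(x5), n_3p = length(x3)))
    tt <- stats::t.test(x5, x3, var.equal = !welch)
    list(mean_5p = mean(x5), mean_3p = mean(x3),
         t_statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter), n_5p = length(x5), n_3p = length(x3))
}

#' Compare relative positions of conserved sites between APA-positive and
#' APA-negative genes
#'
#' Each conserved site is mapped to its relative position
#' \code{utr_start / utr_length} in \code{[0, 1)} along the full-length
#' 3'UTR; the two gene classes (with / without an APA site) are compared by a
#' Student t-test on the relative-position samples.  Also returns
#' percentage-decile density profiles for plotting.
#'
#' @param calls DataFrame from [assignApa()] covering both classes
#' @param sites labelled sites DataFrame
#' @param minLen minimum full-length UTR length (default 1000 nt)
#' @param welch use Welch's t-test (default FALSE: pooled Student)
#' @return list with \code{t_statistic}, \code{p_value}, \code{mean_apa},
#'   \code{mean_non_apa}, \code{n_apa_sites}, \code{n_non_apa_sites} and a
#'   \code{deciles} data.frame (per-class site fraction per UTR-length decile)
#' @export
relativePositionCompare <- function(calls, sites, minLen = 1000L,
                                    welch = FALSE) {
    calls <- calls[calls$utr_length >= minLen, ]
    isApa <- !is.na(calls$apa_pos)
    relpos <- function(sub) {
        len <- setNames(sub$utr_length, sub$gene_id)
        s <- sites[sites$conserved & sites$gene_id %in% names(len), ,
                   drop = FALSE]
        s$utr_start / len[s$gene_id]
    }
    ra <- relpos(calls[isApa, ])
    rn <- relpos(calls[!isApa, ])
    if (length(ra) < 2L || length(rn) < 2L)
        stop("need at least 2 conserved sites in each gene class (APA: ",
             length(ra), ", non-APA: ", length(rn), ")")
    tt <- stats::t.test(ra, rn, var.equal = !welch)
    br <- seq(0, 1, by = 0.1)
    deciles <- data.frame(
        decile_start = br[-11L], decile_end = br[-1L],
        frac_apa = as.vector(table(cut(ra, br, right = FALSE,
                                       include.lowest = TRUE))) / length(ra),
        frac_non_apa = as.vector(table(cut(rn, br, right = FALSE,
                                           include.lowest = TRUE))) / length(rn))
    list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
         mean_apa = mean(ra), mean_non_apa = mean(rn),
         n_apa_sites = length(ra), n_non_apa_sites = length(rn),
         deciles = deciles)
}

#' Write a positional profile (optionally with a null test) as a TSV
#'
#' @param profile a PositionalProfile
#' @param path output path
#' @param nullResult optional PermTestResult whose bins match the profile
#' @param params optional provenance strings
#' @return invisibly, the path
#' @export
writeProfile <- function(profile, path, nullResult = NULL,
                         params = character()) {
    df <- siteCounts(profile)
    if (!is.null(nullResult)) {
        stopifnot(identical(binEdges(profile), binEdges(nullResult)))
        df$null_mean <- colMeans(nullResult@nullStats)
        df$null_sd <- apply(nullResult@nullStats, 2L, stats::sd)
        df$p_value <- nullResult@pValues
    }
    writeTsv(df, path, params)
}
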