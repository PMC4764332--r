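# Synthetic-data generator: emits every input the pipeline consumes (genome
# FASTA, UTR models, 3'-end reads, seed tables, conserved-site and score
# tables, conservation track, CDS FASTA, gene sets) with full ground-truth
# bookkeeping.  All randomness derives from cfg$seed; regeneration with the
# same config is byte-identical.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the statistical structure of a 3'-end-sequencing APA
#' study: log-normal UTR lengths (median ~1.5 kb), a distal cleavage site per
#' gene plus a proximal one in a configurable fraction of genes, negative-
#' binomial read support with small positional jitter, background seed-match
#' planting with a conserved fraction, an excess of conserved sites in the
#' window 5' of the proximal site for one gene class ("prodiff"), a
#' distal-end excess of conserved sites in non-APA genes, A-rich
#' internal-priming decoys, an elevated conservation level on conserved-site
#' bases, stronger P_CT-like / context-like scores for sites 5' of the APA,
#' and two codon-usage classes with Dirichlet-distributed usage.
#'
#' @param n_genes number of genes (default 1000)
#' @param utr_meanlog,utr_sdlog,utr_min,utr_max log-normal UTR length
#'   parameters, truncated (defaults: median 1500 nt, sdlog 0.7, 300..10000)
#' @param apa_fraction fraction of genes given a proximal cleavage site
#'   (default 0.6); the proximal site is uniform in 0.2..0.8 of the UTR
#' @param support_mu,support_size,support_min,support_max negative-binomial
#'   read support per cleavage site, truncated to 20..200 by default
#' @param jitter_sd Gaussian positional jitter of read ends, nt (default 2)
#' @param jitter_frac fraction of a site's reads subject to jitter; the rest
#'   fall exactly at the cleavage site, emulating the major-site structure of
#'   3'-end read runs (default 0.5)
#' @param n_samples number of read samples (default 2)
#' @param site_density_background planted seed-site density, sites per kb
#'   (default 4)
#' @param conserved_fraction fraction of background planted sites flagged
#'   conserved (default 0.7)
#' @param enrichment_window,enrichment_factor window 5' of the proximal site
#'   and multiplicative conserved-site density factor in it for the enriched
#'   class (defaults 300 nt, 3)
#' @param distal_enrichment_factor conserved-site density factor in the last
#'   \code{enrichment_window} nt of non-APA genes (default 2)
#' @param class_fractions named fractions for classes prodiff / proprolif
#'   (defaults 0.25 / 0.35, mirroring the unequal sizes of real expanded
#'   differentiation / proliferation gene sets)
#'   (remainder is background); prodiff is the enriched class
#' @param n_families,n_cluster_families,cluster_site_fraction seed families
#'   (default 100, of which ~70 conserved, the scale of real conserved seed
#'   family catalogues);
#'   the first \code{n_cluster_families} conserved families form the
#'   "cluster" whose members are over-represented among window-planted sites
#' @param internal_priming_decoy_rate per-gene probability of an A-rich decoy
#'   read cluster (default 0.1)
#' @param decoy_support_mu Poisson mean of decoy cluster support (default 18)
#' @param noise_cluster_rate per-gene probability of a low-support (<10
#'   reads) noise cluster (default 0.3)
#' @param conservation_base,conservation_site track level off/on planted
#'   conserved-site bases (defaults 0.2, 0.9)
#' @param pct_shape_window,pct_shape_bg Beta shapes of P_CT-like scores for
#'   sites in / outside the 5'-of-APA window
#' @param context_mean_window,context_mean_bg,context_sd Normal parameters of
#'   context-like scores (more negative = stronger) in / outside the window
#' @param codon_center_distance L2 distance between the two class codon-usage
#'   centers (default 0.08)
#' @param codon_concentration Dirichlet concentration of per-gene usage
#'   around the class center (default 4000: classes are coherent, as the
#'   codon-usage structure shared across a transcriptome is)
#' @param cds_codon_range range of CDS lengths in codons (default 400..900)
#' @param seed_set_size genes sampled per class into the seed gene sets
#'   (default 40)
#' @param genes_per_contig,gene_gap,gc_background genome layout (defaults 50
#'   genes per contig, 200-nt gaps, 40% GC)
#' @param seed integer RNG seed
#' @return a validated config list of class \code{apa_sim_config}
#' @export
simConfig <- function(n_genes = 1000L,
                      utr_meanlog = log(1500), utr_sdlog = 0.7,
                      utr_min = 300L, utr_max = 10000L,
                      apa_fraction = 0.6,
                      support_mu = 60, support_size = 6,
                      support_min = 20L, support_max = 200L,
                      jitter_sd = 2, jitter_frac = 0.5, n_samples = 2L,
                      site_density_background = 4,
                      conserved_fraction = 0.7,
                      enrichment_window = 300L, enrichment_factor = 3,
                      distal_enrichment_factor = 2,
                      class_fractions = c(prodiff = 0.25, proprolif = 0.35),
                      n_families = 100L, n_cluster_families = 4L,
                      cluster_site_fraction = 0.6,
                      internal_priming_decoy_rate = 0.1,
                      decoy_support_mu = 18,
                      noise_cluster_rate = 0.3,
                      conservation_base = 0.2, conservation_site = 0.9,
                      pct_shape_window = c(6, 4), pct_shape_bg = c(4, 6),
                      context_mean_window = -0.35, context_mean_bg = -0.15,
                      context_sd = 0.08,
                      codon_center_distance = 0.08,
                      codon_concentration = 4000,
                      cds_codon_range = c(400L, 900L),
                      seed_set_size = 40L,
                      genes_per_contig = 50L, gene_gap = 200L,
                      gc_background = 0.4,
                      seed = 1L) {
    cfg <- as.list(environment())
    stopifnot(cfg$n_genes >= 0L,
              cfg$apa_fraction >= 0, cfg$apa_fraction <= 1,
              cfg$site_density_background >= 0,
              cfg$conserved_fraction >= 0, cfg$conserved_fraction <= 1,
              cfg$enrichment_factor >= 1,
              cfg$distal_enrichment_factor >= 1,
              all(cfg$class_fractions >= 0), sum(cfg$class_fractions) <= 1,
              cfg$internal_priming_decoy_rate >= 0,
              cfg$n_cluster_families <= cfg$n_families,
              cfg$utr_min >= 50L, cfg$utr_min < cfg$utr_max)
    if (cfg$enrichment_window >= 0.8 * cfg$utr_max)
        stop("infeasible geometry: enrichment window ", cfg$enrichment_window,
             " cannot fit 5' of any proximal site (utr_max = ", cfg$utr_max,
             ")")
    class(cfg) <- "apa_sim_config"
    cfg
}

.randSeq <- function(n, gc) {
    if (n <= 0L) return("")
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.revcompChr <- function(s) {
    as.character(reverseComplement(DNAString(s)))
}

## plant seed-match sites for one gene; returns data.frame or NULL
.plantSites <- function(cfg, len, class, proxPos, families) {
    consFam <- families$family_id[families$conserved_family]
    clustFam <- families$family_id[families$cluster]
    dens <- cfg$site_density_background / 1000
    pos <- integer(0); cons <- logical(0); fam <- character(0)
    inWin <- logical(0)
    nbg <- stats::rpois(1L, dens * len)
    if (nbg > 0L) {
        pos <- sample.int(len - 7L, nbg, replace = TRUE) - 1L
        cons <- stats::runif(nbg) < cfg$conserved_fraction
        fam <- ifelse(cons,
                      sample(consFam, nbg, replace = TRUE),
                      sample(families$family_id, nbg, replace = TRUE))
        inWin <- rep(FALSE, nbg)
    }
    ## conserved-site excess 5' of the proximal APA site, enriched class only
    if (!is.na(proxPos) && class == "prodiff" && cfg$enrichment_factor > 1) {
        wlo <- max(0L, proxPos - cfg$enrichment_window)
        wlen <- proxPos - wlo
        nex <- stats::rpois(1L, dens * cfg$conserved_fraction *
                                (cfg$enrichment_factor - 1) * wlen)
        if (nex > 0L && wlen > 7L) {
            p <- wlo + sample.int(wlen, nex, replace = TRUE) - 1L
            useClust <- stats::runif(nex) < cfg$cluster_site_fraction
            f <- ifelse(useClust,
                        sample(clustFam, nex, replace = TRUE),
                        sample(consFam, nex, replace = TRUE))
            pos <- c(pos, p); cons <- c(cons, rep(TRUE, nex))
            fam <- c(fam, f); inWin <- c(inWin, rep(TRUE, nex))
        }
    }
    ## distal-end conserved-site excess in non-APA genes
    if (is.na(proxPos) && cfg$distal_enrichment_factor > 1) {
        wlen <- min(cfg$enrichment_window, len - 7L)
        nd <- stats::rpois(1L, dens * cfg$conserved_fraction *
                               (cfg$distal_enrichment_factor - 1) * wlen)
        if (nd > 0L) {
            p <- (len - 7L - wlen) + sample.int(wlen, nd, replace = TRUE)
            pos <- c(pos, p); cons <- c(cons, rep(TRUE, nd))
            fam <- c(fam, sample(consFam, nd, replace = TRUE))
            inWin <- c(inWin, rep(FALSE, nd))
        }
    }
    if (length(pos) == 0L)
        return(NULL)
    pos <- pmin(pos, len - 7L)
    ## drop overlapping plantings (random precedence) so every kept site's
    ## 7-mer survives verbatim in the emitted sequence
    ord <- sample.int(length(pos))
    keep <- logical(length(pos))
    kept <- integer(0)
    for (i in ord) {
        if (length(kept) == 0L || min(abs(kept - pos[i])) >= 7L) {
            keep[i] <- TRUE
            kept <- c(kept, pos[i])
        }
    }
    data.frame(utr_start = pos[keep], family_id = fam[keep],
               conserved = cons[keep], planted_in_window = inWin[keep])
}

.makeFamilies <- function(cfg) {
    ## distinct random 7-mers; avoid pure A/G 7-mers (internal-priming motif)
    site <- character(0)
    while (length(site) < cfg$n_families) {
        cand <- paste(sample(c("A", "C", "G", "T"), 7L, replace = TRUE),
                      collapse = "")
        if (grepl("^[AG]+$", cand) || cand %in% site)
            next
        site <- c(site, cand)
    }
    fam <- sprintf("fam%02d", seq_len(cfg$n_families))
    conserved <- rep(FALSE, cfg$n_families)
    conserved[seq_len(max(cfg$n_cluster_families,
                          round(0.7 * cfg$n_families)))] <- TRUE
    cluster <- seq_len(cfg$n_families) <= cfg$n_cluster_families
    data.frame(family_id = fam, site7 = site,
               conserved_family = conserved, cluster = cluster)
}

.truncNB <- function(n, mu, size, lo, hi) {
    v <- stats::rnbinom(n, mu = mu, size = size)
    pmin(pmax(v, lo), hi)
}

.dirichlet <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    g / sum(g)
}

.codonCenters <- function(cfg) {
    ## non-uniform baseline usage (base-composition product plus a fixed
    ## per-codon preference pattern), as in real transcriptomes where all
    ## genes share most of their codon-usage structure; the two classes shift
    ## the baseline in opposite directions by codon_center_distance (L2)
    sense <- .senseCodons()
    k <- length(sense)
    bp <- c(A = 0.28, C = 0.22, G = 0.22, T = 0.28)
    p0 <- vapply(sense, function(cd)
        prod(bp[strsplit(cd, "")[[1]]]), 1.0)
    p0 <- p0 * (1 + 0.5 * sin(seq_len(k)))
    p0 <- p0 / sum(p0)
    d <- cfg$codon_center_distance / sqrt(k)   # per-codon half-offsets
    v <- rep(c(1, -1), length.out = k) * d
    cA <- pmax(p0 + v / 2, 1e-6); cA <- cA / sum(cA)
    cB <- pmax(p0 - v / 2, 1e-6); cB <- cB / sum(cB)
    list(prodiff = setNames(cB, sense), proprolif = setNames(cA, sense),
         background = setNames(p0, sense))
}

#' Generate a synthetic APA / seed-site dataset with ground truth
#'
#' In \code{mode = "full"}, builds genome contigs (40% GC background), plants
#' the seed-match 7-mers into the UTR sequences, writes A-rich decoy motifs,
#' simulates jittered 3'-end reads for every cleavage site, and assembles the
#' conservation track, CDS sequences, and all tables.  In
#' \code{mode = "annotation"} only the annotation-level truth is generated
#' (UTR lengths, classes, cleavage-site positions, planted sites, scores,
#' gene sets) plus ready-made APA calls and a sites table in the schema of
#' [scanSeedSites()]; this is the fast path for statistical calibration
#' studies that do not exercise sequence-level steps.
#'
#' @param cfg a config from [simConfig()]
#' @param mode "full" or "annotation"
#' @return a list of class \code{apa_sim}; common elements: \code{cfg},
#'   \code{truth} (genes / cs / sites / families data.frames, gene_sets
#'   list), \code{calls} (truth-derived APA calls), \code{sites}
#'   (truth-derived sites DataFrame), \code{seeds}, and in full mode
#'   additionally \code{genome}, \code{utrs}, \code{ends}, \code{track},
#'   \code{cds} plus the score/conserved tables
#' @export
simulateApaData <- function(cfg = simConfig(), mode = c("full", "annotation")) {
    mode <- match.arg(mode)
    stopifnot(inherits(cfg, "apa_sim_config"))
    .withSeed(cfg$seed, .simulateApaDataImpl(cfg, mode))
}

.simulateApaDataImpl <- function(cfg, mode) {
    n <- cfg$n_genes
    gid <- sprintf("g%04d", seq_len(n))
    ## UTR lengths: truncated log-normal
    len <- integer(n)
    todo <- seq_len(n)
    while (length(todo)) {
        v <- round(stats::rlnorm(length(todo), cfg$utr_meanlog, cfg$utr_sdlog))
        ok <- v >= cfg$utr_min & v <= cfg$utr_max
        len[todo[ok]] <- as.integer(v[ok])
        todo <- todo[!ok]
    }
    fr <- cfg$class_fractions
    class <- sample(c(names(fr), "background"), n, replace = TRUE,
                    prob = c(fr, max(0, 1 - sum(fr))))
    hasApa <- stats::runif(n) < cfg$apa_fraction
    proxPos <- ifelse(hasApa,
                      floor((0.2 + 0.6 * stats::runif(n)) * len), NA_integer_)
    distalPos <- len - 1L
    families <- .makeFamilies(cfg)
    sitesL <- vector("list", n)
    for (i in seq_len(n)) {
        s <- .plantSites(cfg, len[i], class[i], proxPos[i], families)
        if (!is.null(s)) {
            s <- cbind(gene_id = gid[i], s)
            sitesL[[i]] <- s
        }
    }
    sites <- do.call(rbind, sitesL)
    if (is.null(sites))
        sites <- data.frame(gene_id = character(0), utr_start = integer(0),
                            family_id = character(0), conserved = logical(0),
                            planted_in_window = logical(0))
    ## positional criterion for score levels: within the window 5' of the APA
    apaOf <- setNames(proxPos, gid)
    d <- sites$utr_start - apaOf[sites$gene_id]
    sites$in_apa_window <- !is.na(d) & d >= -cfg$enrichment_window & d < 0L
    nS <- nrow(sites)
    sites$pct <- rep(NA_real_, nS)
    cons <- which(sites$conserved)
    w <- sites$in_apa_window[cons]
    sites$pct[cons] <- ifelse(
        w,
        stats::rbeta(length(cons), cfg$pct_shape_window[1L],
                     cfg$pct_shape_window[2L]),
        stats::rbeta(length(cons), cfg$pct_shape_bg[1L], cfg$pct_shape_bg[2L]))
    sites$context <- stats::rnorm(
        nS,
        ifelse(sites$in_apa_window, cfg$context_mean_window,
               cfg$context_mean_bg),
        cfg$context_sd)
    ## gene sets: seeds sampled per class + full class membership
    geneSets <- list()
    for (cl in names(cfg$class_fractions)) {
        members <- gid[class == cl]
        geneSets[[paste0(cl, "_all")]] <- members
        geneSets[[paste0(cl, "_seed")]] <-
            sort(sample(members, min(cfg$seed_set_size, length(members))))
    }
    ## cleavage-site truth (support drawn in full mode only)
    csL <- list(data.frame(gene_id = gid, utr_pos = distalPos,
                           kind = rep("distal", n)))
    if (any(hasApa))
        csL <- c(csL, list(data.frame(gene_id = gid[hasApa],
                                      utr_pos = proxPos[hasApa],
                                      kind = "proximal")))
    cs <- do.call(rbind, csL)
    cs <- cs[order(cs$gene_id, cs$utr_pos), , drop = FALSE]
    rownames(cs) <- NULL
    genes <- data.frame(gene_id = gid, class = class, utr_length = len,
                        apa = hasApa, prox_pos = proxPos,
                        distal_pos = distalPos)
    truth <- list(genes = genes, cs = cs, sites = sites,
                  families = families, gene_sets = geneSets)
    seeds <- families[, c("family_id", "site7", "conserved_family")]
    out <- list(cfg = cfg, truth = truth, seeds = seeds,
                calls = .truthCalls(truth), sites = .truthSites(truth))
    class(out) <- "apa_sim"
    if (mode == "annotation")
        return(out)
    c2 <- .simulateSequences(cfg, out)
    class(c2) <- "apa_sim"
    c2
}

## truth-level APA calls in the assignApa() schema
.truthCalls <- function(truth) {
    g <- truth$genes
    csPos <- lapply(seq_len(nrow(g)), function(i)
        if (g$apa[i]) c(g$prox_pos[i], g$distal_pos[i]) else g$distal_pos[i])
    DataFrame(
        gene_id = g$gene_id, accession = g$gene_id,
        utr_length = g$utr_length,
        n_cs = ifelse(g$apa, 2L, 1L),
        cs_utr_positions = IntegerList(csPos),
        apa_pos = ifelse(g$apa, g$prox_pos, NA_integer_),
        distal_pos = g$distal_pos,
        upstream_len = ifelse(g$apa, g$prox_pos, NA_integer_),
        downstream_len = ifelse(g$apa, g$utr_length - g$prox_pos,
                                NA_integer_),
        shared_cs = rep(FALSE, nrow(g)))
}

## truth-level sites in the scanSeedSites() schema
.truthSites <- function(truth) {
    s <- truth$sites
    consFam <- setNames(truth$families$conserved_family,
                        truth$families$family_id)
    DataFrame(
        gene_id = s$gene_id, accession = s$gene_id,
        utr_start = s$utr_start, family_id = s$family_id,
        conserved_family = unname(consFam[s$family_id]),
        conserved = s$conserved,
        pct = s$pct, context_score = s$context)
}

.simulateSequences <- function(cfg, sim) {
    truth <- sim$truth
    g <- truth$genes
    n <- nrow(g)
    nContig <- max(1L, ceiling(n / cfg$genes_per_contig))
    contigOf <- rep(sprintf("ctg%02d", seq_len(nContig)),
                    each = cfg$genes_per_contig, length.out = n)
    strandOf <- sample(c("+", "-"), n, replace = TRUE)
    ## per-gene UTR sequence with planted 7-mers and decoy motifs
    utrSeq <- character(n)
    decoyL <- vector("list", n)
    noiseL <- vector("list", n)
    siteBy <- split(seq_len(nrow(truth$sites)), truth$sites$gene_id)
    for (i in seq_len(n)) {
        s <- .randSeq(g$utr_length[i], cfg$gc_background)
        ix <- siteBy[[g$gene_id[i]]]
        if (!is.null(ix))
            for (j in ix) {
                p <- truth$sites$utr_start[j]
                fam <- truth$sites$family_id[j]
                site7 <- truth$families$site7[
                    match(fam, truth$families$family_id)]
                substr(s, p + 1L, p + 7L) <- site7
            }
        csPos <- truth$cs$utr_pos[truth$cs$gene_id == g$gene_id[i]]
        sitePos <- truth$sites$utr_start[ix]
        ## A-rich internal-priming decoy: motif + read cluster
        if (stats::runif(1L) < cfg$internal_priming_decoy_rate &&
            g$utr_length[i] > 200L) {
            for (try in 1:10) {
                dp <- sample.int(g$utr_length[i] - 40L, 1L) + 10L
                farCs <- all(abs(csPos - dp) >= 60L)
                farSite <- length(sitePos) == 0L ||
                    min(abs(sitePos - dp)) >= 30L
                if (farCs && farSite) {
                    nA <- sample(8:10, 1L)
                    motif <- paste(sample(c(rep("A", nA),
                                            rep("G", 10L - nA))),
                                   collapse = "")
                    substr(s, dp - 4L, dp + 5L) <- motif
                    decoyL[[i]] <- data.frame(
                        gene_id = g$gene_id[i], utr_pos = dp,
                        kind = "decoy",
                        support = max(10L,
                                      stats::rpois(1L, cfg$decoy_support_mu)))
                    break
                }
            }
        }
        ## low-support noise cluster (dies at the support filter)
        if (stats::runif(1L) < cfg$noise_cluster_rate &&
            g$utr_length[i] > 200L) {
            for (try in 1:10) {
                np <- sample.int(g$utr_length[i] - 20L, 1L) + 10L
                if (all(abs(csPos - np) >= 60L) &&
                    (is.null(decoyL[[i]]) ||
                     abs(decoyL[[i]]$utr_pos - np) >= 60L)) {
                    noiseL[[i]] <- data.frame(
                        gene_id = g$gene_id[i], utr_pos = np,
                        kind = "noise", support = sample(3:8, 1L))
                    break
                }
            }
        }
        utrSeq[i] <- s
    }
    ## genome assembly: gap, gene, gap, gene, ..., gap per contig
    gstart <- integer(n)
    contigSeq <- setNames(character(nContig), sprintf("ctg%02d",
                                                      seq_len(nContig)))
    for (ci in seq_len(nContig)) {
        idx <- which(contigOf == names(contigSeq)[ci])
        pieces <- character(2L * length(idx) + 1L)
        cur <- 0L
        for (k in seq_along(idx)) {
            i <- idx[k]
            pieces[2L * k - 1L] <- .randSeq(cfg$gene_gap, cfg$gc_background)
            cur <- cur + cfg$gene_gap
            gstart[i] <- cur + 1L
            pieces[2L * k] <- if (strandOf[i] == "-")
                .revcompChr(utrSeq[i]) else utrSeq[i]
            cur <- cur + g$utr_length[i]
        }
        pieces[2L * length(idx) + 1L] <- .randSeq(cfg$gene_gap,
                                                  cfg$gc_background)
        contigSeq[ci] <- paste(pieces, collapse = "")
    }
    genome <- DNAStringSet(contigSeq)
    ## UTRSet (single-interval models)
    ranges <- GRangesList(lapply(seq_len(n), function(i)
        GRanges(contigOf[i],
                IRanges(gstart[i], gstart[i] + g$utr_length[i] - 1L),
                strand = strandOf[i])))
    utrs <- new("UTRSet", geneId = g$gene_id, accession = g$gene_id,
                ranges = ranges, seq = DNAStringSet(utrSeq))
    ## cleavage-site truth with support, genomic coordinates and reads
    cs <- rbind(
        cbind(truth$cs,
              support = .truncNB(nrow(truth$cs), cfg$support_mu,
                                 cfg$support_size, cfg$support_min,
                                 cfg$support_max)),
        do.call(rbind, c(decoyL[!vapply(decoyL, is.null, TRUE)],
                         noiseL[!vapply(noiseL, is.null, TRUE)])))
    gi <- match(cs$gene_id, g$gene_id)
    cs$chrom <- contigOf[gi]
    cs$strand <- strandOf[gi]
    cs$genomic_pos <- ifelse(cs$strand == "-",
                             gstart[gi] + g$utr_length[gi] - 1L - cs$utr_pos,
                             gstart[gi] + cs$utr_pos)
    rownames(cs) <- NULL
    ## reads: jittered around each CS, split across samples
    totReads <- sum(cs$support)
    readCs <- rep(seq_len(nrow(cs)), cs$support)
    jit <- round(stats::rnorm(totReads, 0, cfg$jitter_sd)) *
        (stats::runif(totReads) < cfg$jitter_frac)
    contigLen <- setNames(width(genome), names(genome))
    rpos <- pmin(pmax(cs$genomic_pos[readCs] + jit, 1L),
                 contigLen[cs$chrom[readCs]])
    sampleLab <- sprintf("sample%d",
                         sample.int(cfg$n_samples, totReads, replace = TRUE))
    ends <- GRanges(cs$chrom[readCs], IRanges(rpos, width = 1L),
                    strand = cs$strand[readCs])
    ends$sample <- sampleLab
    ends <- sort(ends, ignore.strand = FALSE)
    ## conservation track: base level over UTR spans, elevated on planted
    ## conserved-site bases
    consSites <- truth$sites[truth$sites$conserved, , drop = FALSE]
    siteGr <- GRanges()
    if (nrow(consSites)) {
        sgi <- match(consSites$gene_id, g$gene_id)
        glo <- ifelse(strandOf[sgi] == "-",
                      gstart[sgi] + g$utr_length[sgi] - 1L -
                          (consSites$utr_start + 6L),
                      gstart[sgi] + consSites$utr_start)
        siteGr <- reduce(GRanges(contigOf[sgi], IRanges(glo, width = 7L)))
    }
    utrGr <- reduce(GRanges(contigOf,
                            IRanges(gstart, gstart + g$utr_length - 1L)))
    baseGr <- GenomicRanges::setdiff(utrGr, siteGr)
    baseGr$score <- rep(cfg$conservation_base, length(baseGr))
    trackGr <- baseGr
    if (length(siteGr)) {
        siteGr$score <- rep(cfg$conservation_site, length(siteGr))
        trackGr <- c(baseGr, siteGr)
    }
    track <- conservationTrack(sort(trackGr))
    ## CDS sequences per codon-usage class
    centers <- .codonCenters(cfg)
    sense <- .senseCodons()
    nc <- sample(seq(cfg$cds_codon_range[1L], cfg$cds_codon_range[2L]),
                 n, replace = TRUE)
    cdsSeq <- character(n)
    for (i in seq_len(n)) {
        p <- .dirichlet(centers[[g$class[i]]] * cfg$codon_concentration)
        cdsSeq[i] <- paste0(
            paste(sample(sense, nc[i], replace = TRUE, prob = p),
                  collapse = ""), "TAA")
    }
    cds <- DNAStringSet(setNames(cdsSeq, g$gene_id))
    truth$cs <- cs
    truth$genes$contig <- contigOf
    truth$genes$strand <- strandOf
    truth$genes$utr_gstart <- gstart
    c(sim[c("cfg", "seeds")],
      list(truth = truth, calls = .truthCalls(truth), sites = sim$sites,
           genome = genome, utrs = utrs, ends = ends, track = track,
           cds = cds))
}

#' Write a simulated dataset as the pipeline's file bundle
#'
#' Emits genome.fa, utrs.bed (BED12), cds.fa, reads.bed (BED6),
#' seeds.tsv, conserved_sites.tsv, pct.tsv, context.tsv,
#' conservation.bedGraph and gene_sets.tsv into \code{dir}.  Every file
#' parses back through the package's readers.
#'
#' @param sim a full-mode result of [simulateApaData()]
#' @param dir output directory (created if needed)
#' @return invisibly, a named character vector of the written paths
#' @export
writeSimBundle <- function(sim, dir) {
    stopifnot(inherits(sim, "apa_sim"), !is.null(sim$genome))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
        genome = file.path(dir, "genome.fa"),
        utrs = file.path(dir, "utrs.bed"),
        cds = file.path(dir, "cds.fa"),
        reads = file.path(dir, "reads.bed"),
        seeds = file.path(dir, "seeds.tsv"),
        conserved = file.path(dir, "conserved_sites.tsv"),
        pct = file.path(dir, "pct.tsv"),
        context = file.path(dir, "context.tsv"),
        conservation = file.path(dir, "conservation.bedGraph"),
        gene_sets = file.path(dir, "gene_sets.tsv"))
    writeXStringSet(sim$genome, paths["genome"])
    writeUtrModels(sim$utrs, paths["utrs"])
    writeXStringSet(sim$cds, paths["cds"])
    writeReadEnds(sim$ends, paths["reads"])
    writeTsv(sim$seeds, paths["seeds"])
    s <- as.data.frame(sim$sites)
    consTab <- s[s$conserved, c("gene_id", "utr_start", "family_id")]
    writeTsv(consTab, paths["conserved"])
    pctTab <- s[!is.na(s$pct), c("gene_id", "utr_start", "family_id", "pct")]
    names(pctTab)[4L] <- "score"
    writeTsv(pctTab, paths["pct"])
    ctxTab <- s[!is.na(s$context_score),
                c("gene_id", "utr_start", "family_id", "context_score")]
    names(ctxTab)[4L] <- "score"
    writeTsv(ctxTab, paths["context"])
    writeConservationTrack(sim$track, paths["conservation"])
    writeGeneSets(sim$truth$gene_sets, paths["gene_sets"])
    invisible(paths)
}

#' Recovery metrics of a pipeline run against the generator's ground truth
#'
#' Called cleavage sites are matched to planted ones within \code{tol} nt on
#' the same chromosome and strand; internal-priming-flagged calls are
#' excluded first (they are the filter's intended rejections).
#'
#' @param sim a full-mode result of [simulateApaData()]
#' @param calledSites GRanges from [callCleavageSites()]
#' @param apaCalls optional DataFrame from [assignApa()]
#' @param tol matching tolerance in nt (default 5)
#' @return list with \code{cs_recall}, \code{cs_precision},
#'   \code{max_call_error} (largest distance of an unflagged call to its
#'   nearest planted site; Inf if an unmatched call exists), \code{n_called},
#'   \code{n_flagged}, and when \code{apaCalls} is given \code{apa_recall}
#'   (fraction of planted APA-positive genes called APA-positive)
#' @export
truthReport <- function(sim, calledSites, apaCalls = NULL, tol = 5L) {
    stopifnot(inherits(sim, "apa_sim"))
    cs <- sim$truth$cs
    true <- cs[cs$kind %in% c("proximal", "distal"), , drop = FALSE]
    called <- calledSites[!vapply(calledSites$internal_priming, isTRUE, TRUE)]
    trueGr <- GRanges(true$chrom, IRanges(true$genomic_pos, width = 1L),
                      strand = true$strand)
    hits <- findOverlaps(trueGr + tol, called)
    recall <- length(unique(queryHits(hits))) / max(1L, length(trueGr))
    precision <- length(unique(subjectHits(hits))) / max(1L, length(called))
    maxErr <- if (length(called) == 0L) 0 else {
        d <- rep(Inf, length(called))
        h2 <- distanceToNearest(called, trueGr)
        d[queryHits(h2)] <- mcols(h2)$distance
        max(d)
    }
    out <- list(cs_recall = recall, cs_precision = precision,
                max_call_error = maxErr,
                n_called = length(called),
                n_flagged = sum(vapply(calledSites$internal_priming,
                                       isTRUE, TRUE)))
    if (!is.null(apaCalls)) {
        trueApa <- sim$truth$genes$gene_id[sim$truth$genes$apa]
        pos <- apaCalls$gene_id[!is.na(apaCalls$apa_pos)]
        out$apa_recall <- mean(trueApa %in% pos)
        ## conditional on both planted sites surviving cleavage-site calling
        matched <- rep(FALSE, length(trueGr))
        matched[unique(queryHits(hits))] <- TRUE
        bothCalled <- vapply(trueApa, function(gn) {
            m <- true$gene_id == gn
            sum(m) == 2L && all(matched[m])
        }, TRUE)
        out$apa_recall_recovered <- if (any(bothCalled))
            mean(trueApa[bothCalled] %in% pos) else NA_real_
    }
    out
}
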