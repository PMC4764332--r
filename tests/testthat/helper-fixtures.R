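# Shared fixture builders.  Everything is constructed in code; no stored
# binary data.

# A UTRSet built directly from explicit intervals and a genome.
makeUtrSet <- function(genome, gene, acc, chrom, starts, ends, strand) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                                 strand = strand)
    grl <- stats::setNames(GenomicRanges::GRangesList(gr),
                               paste0(gene, "|", acc))
    readUtrModels(grl, genome)
}

# random DNA of length n (uses the session RNG)
randDna <- function(n, bases = c("A", "C", "G", "T")) {
    paste(sample(bases, n, replace = TRUE), collapse = "")
}

# read-end GRanges from a data.frame(chrom, pos, strand, sample)
makeEnds <- function(df) {
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$pos, width = 1L),
                                 strand = df$strand)
    gr$sample <- df$sample
    gr
}

# a minimal sites DataFrame in the scanSeedSites() schema
makeSites <- function(gene_id, utr_start, family_id = "famA",
                      conserved = TRUE, pct = NA_real_,
                      context_score = NA_real_) {
    n <- max(length(gene_id), length(utr_start))
    utr_start <- rep_len(utr_start, n)
    S4Vectors::DataFrame(
        gene_id = rep_len(gene_id, n),
        accession = rep_len(gene_id, n),
        utr_start = as.integer(utr_start),
        family_id = rep_len(family_id, n),
        conserved_family = rep_len(TRUE, n),
        conserved = rep_len(conserved, n),
        pct = rep_len(pct, n),
        context_score = rep_len(context_score, n))
}

# a minimal APA-calls DataFrame (assignApa() schema) from per-gene vectors
makeCalls <- function(gene_id, utr_length, apa_pos = NA_integer_,
                      distal_pos = utr_length - 1L) {
    n <- length(gene_id)
    apa_pos <- rep_len(as.integer(apa_pos), n)
    utr_length <- rep_len(as.integer(utr_length), n)
    distal_pos <- rep_len(as.integer(distal_pos), n)
    csp <- lapply(seq_len(n), function(i)
        sort(unique(c(apa_pos[i], distal_pos[i]))))
    S4Vectors::DataFrame(
        gene_id = gene_id, accession = gene_id,
        utr_length = utr_length,
        n_cs = ifelse(is.na(apa_pos), 1L, 2L),
        cs_utr_positions = IRanges::IntegerList(csp),
        apa_pos = apa_pos, distal_pos = distal_pos,
        upstream_len = apa_pos,
        downstream_len = utr_length - apa_pos,
        shared_cs = rep(FALSE, n))
}

# brute-force oracle: single-linkage clustering of positions with gap rule
oracleRuns <- function(pos, gapMax = 10L) {
    pos <- sort(unique(pos))
    if (length(pos) == 0L) return(list())
    grp <- cumsum(c(1L, as.integer(diff(pos) >= gapMax)))
    unname(split(pos, grp))
}

# brute-force oracle for the internal-priming rule on a character window
oracleARich <- function(s, k = 10L, minA = 8L) {
    n <- nchar(s)
    if (n < k) return(FALSE)
    for (i in seq_len(n - k + 1L)) {
        w <- strsplit(substr(s, i, i + k - 1L), "")[[1]]
        nA <- sum(w == "A"); nG <- sum(w == "G")
        if (nA >= minA && nA + nG == k) return(TRUE)
    }
    FALSE
}

# brute-force oracle for cleavage-site selection within one chrom/strand:
# exhaustive greedy on (support desc, 5'-most) over given candidates
oracleSelect <- function(pos, support, minus = FALSE, minSpacing = 50L,
                         minSupport = 10L) {
    o <- order(-support, if (minus) -pos else pos)
    keptP <- integer(0); keptS <- integer(0)
    for (i in o) {
        if (length(keptP) == 0L || min(abs(keptP - pos[i])) >= minSpacing) {
            keptP <- c(keptP, pos[i]); keptS <- c(keptS, support[i])
        }
    }
    keep <- keptS >= minSupport
    sort(keptP[keep])
}

# pooled two-sample Student t statistic and p, from first principles
oracleStudentT <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    p <- 2 * pt(-abs(t), df = nx + ny - 2)
    list(t = t, p = p, df = nx + ny - 2)
}
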