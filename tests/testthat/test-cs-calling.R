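# Cleavage-site calling: read runs, local maxima with spacing resolution,
# support filter, internal-priming flag, per-sample quantification.

endsAt <- function(pos, strand = "+", chrom = "c1", sample = "s1") {
    makeEnds(data.frame(chrom = chrom, pos = pos, strand = strand,
                        sample = sample))
}

test_that("read runs respect the gap rule and pool samples", {
    # 12 reads at one position -> a single one-position run
    r <- buildRuns(endsAt(rep(100L, 12)))
    expect_equal(length(r), 1L)
    expect_equal(r$positions[[1]], 100L)
    expect_equal(r$counts[[1]], 12L)
    expect_equal(r$total, 12L)

    # {100, 105, 130}: 105-100 < 10 joins, 130 starts a new run
    r <- buildRuns(endsAt(c(100L, 105L, 130L)))
    expect_equal(length(r), 2L)
    expect_equal(r$positions[[1]], c(100L, 105L))
    expect_equal(r$positions[[2]], 130L)

    # boundary: gap 9 merges, gap 10 splits ("below 10 nt")
    expect_equal(length(buildRuns(endsAt(c(100L, 109L)))), 1L)
    expect_equal(length(buildRuns(endsAt(c(100L, 110L)))), 2L)

    # strands and chromosomes never share a run
    e <- makeEnds(data.frame(chrom = c("c1", "c1", "c2"),
                             pos = c(100L, 103L, 103L),
                             strand = c("+", "-", "+"), sample = "s1"))
    expect_equal(length(buildRuns(e)), 3L)
})

test_that("read runs match a brute-force clustering oracle on random input", {
    set.seed(202)
    for (i in 1:200) {
        pos <- sample.int(500, sample(1:40, 1), replace = TRUE)
        gap <- sample(2:15, 1)
        r <- buildRuns(endsAt(pos), gapMax = gap)
        expected <- oracleRuns(pos, gap)
        expect_equal(length(r), length(expected))
        expect_equal(unname(as.list(r$positions)),
                     lapply(expected, as.integer))
        # maximality: occupied positions in adjacent runs are >= gap apart
        if (length(r) > 1)
            expect_true(all(start(r)[-1] - end(r)[-length(r)] >= gap))
        # counts conserve reads
        expect_equal(sum(unlist(r$counts)), length(pos))
    }
})

test_that("site calling: support, spacing and plateau rules", {
    # two candidates 30 apart: higher support wins the spacing conflict
    e <- c(endsAt(rep(100L, 12)), endsAt(rep(130L, 15)))
    s <- callSites(buildRuns(e, gapMax = 50L))
    expect_equal(length(s), 1L)
    expect_equal(start(s), 130L)
    expect_equal(s$support, 15L)

    # support below threshold -> nothing
    expect_length(callSites(buildRuns(endsAt(rep(100L, 9)))), 0L)

    # two runs 60 apart: both kept (>= 50 spacing)
    e <- c(endsAt(rep(100L, 20)), endsAt(rep(160L, 11)))
    s <- callSites(buildRuns(e))
    expect_equal(sort(start(s)), c(100L, 160L))

    # plateau: tied counts at adjacent positions keep the 5'-most
    e <- c(endsAt(rep(100L, 11)), endsAt(rep(101L, 11)))
    s <- callSites(buildRuns(e))
    expect_equal(start(s), 100L)
    sM <- callSites(buildRuns(endsAt(c(rep(100L, 11), rep(101L, 11)), "-")))
    expect_equal(start(sM), 101L)     # 5'-most on minus strand
})

test_that("site calling matches the exhaustive greedy oracle", {
    set.seed(303)
    for (i in 1:300) {
        k <- sample(1:8, 1)
        pos <- sort(sample(seq(1L, 400L, by = 3L), k))
        support <- sample(5:40, k, replace = TRUE)
        minus <- runif(1) < 0.5
        e <- endsAt(rep(pos, support), if (minus) "-" else "+")
        # isolate candidate behaviour: single-position runs via small gap
        s <- callSites(buildRuns(e, gapMax = 3L), minSupport = 10L,
                       minSpacing = 50L)
        expect_equal(sort(start(s)),
                     oracleSelect(pos, support, minus = minus))
        # invariants: pairwise spacing and support threshold
        if (length(s) > 1)
            expect_true(min(diff(sort(start(s)))) >= 50L)
        expect_true(all(s$support >= 10L))
    }
})

test_that("site calling is invariant to read order", {
    set.seed(77)
    pos <- rep(sample.int(1000, 50, replace = TRUE),
               sample(1:30, 50, replace = TRUE))
    e1 <- endsAt(pos)
    e2 <- e1[sample(length(e1))]
    s1 <- callSites(buildRuns(e1))
    s2 <- callSites(buildRuns(e2))
    expect_equal(start(s1), start(s2))
    expect_equal(s1$support, s2$support)
})

test_that("internal-priming flag follows the A/G composition rule", {
    pad <- function(core) {
        # embed the 10-mer core in a neutral 50-nt window centred at pos 26
        left <- strrep("CT", 10)
        right <- strrep("TC", 10)
        paste0(left, core, right)
    }
    mkGenome <- function(w) Biostrings::DNAStringSet(c(c1 = w))
    siteAt <- function(pos, strand = "+") {
        gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(pos, pos),
                                     strand = strand)
        gr$support <- 20L; gr$run_start <- pos; gr$run_end <- pos
        gr$run_nocc <- 1L; gr$internal_priming <- NA
        gr
    }
    expect_true(flagInternalPriming(siteAt(26L),
                                    mkGenome(pad("AAAAAAAAAA"))))
    # 8 A + 2 G qualifies
    expect_true(flagInternalPriming(siteAt(26L),
                                    mkGenome(pad("AAAAGAAAGA"))))
    # a C inside the most A-rich 10-mer disqualifies
    expect_false(flagInternalPriming(siteAt(26L),
                                     mkGenome(pad("AAAAAAAACA"))))
    # minus strand scans the reverse complement (T/C-rich genomic slice)
    rcWin <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pad("AAAAGAAAGA"))))
    expect_true(flagInternalPriming(siteAt(26L, "-"),
                                    mkGenome(rcWin)))
    # truncation at the contig end scans what exists, with a warning
    expect_warning(
        got <- flagInternalPriming(siteAt(15L), mkGenome(pad("AAAAAAAAAA"))),
        "truncated")
    expect_true(got)
})

test_that("internal-priming flag agrees exactly with the brute-force scan", {
    set.seed(404)
    n <- 2000
    wins <- vapply(seq_len(n), function(i)
        randDna(50, c("A", "A", "G", "C", "T")), "")
    genome <- Biostrings::DNAStringSet(setNames(wins, paste0("w", seq_len(n))))
    gr <- GenomicRanges::GRanges(paste0("w", seq_len(n)),
                                 IRanges::IRanges(26L, 26L), strand = "+")
    gr$support <- 20L; gr$run_start <- 26L; gr$run_end <- 26L
    gr$run_nocc <- 1L; gr$internal_priming <- NA
    got <- flagInternalPriming(gr, genome)
    expected <- vapply(wins, oracleARich, TRUE, USE.NAMES = FALSE)
    expect_equal(got, expected)
    expect_gt(sum(expected), 0L)    # the A-biased alphabet produces positives
})

test_that("per-sample quantification conserves the pooled run totals", {
    e <- c(endsAt(c(100L, 101L), sample = "A"),
           endsAt(105L, sample = "B"))
    runs <- buildRuns(e)
    s <- callSites(runs, minSupport = 1L)
    m <- quantifyPerSample(s, e)
    expect_equal(unname(m[1, "A"]), 2L)
    expect_equal(unname(m[1, "B"]), 1L)
    expect_equal(sum(m), 3L)

    # no ends in the run interval -> all-zero over known samples
    far <- endsAt(900L, sample = "B")
    m2 <- quantifyPerSample(s, far)
    expect_equal(unname(m2[1, ]), 0L)

    # pooled counts equal the sum over samples on a random instance
    set.seed(9)
    pos <- rep(sample.int(300, 20), sample(10:30, 20, replace = TRUE))
    smp <- sample(c("x", "y", "z"), length(pos), replace = TRUE)
    ee <- makeEnds(data.frame(chrom = "c1", pos = pos, strand = "+",
                              sample = smp))
    ss <- callSites(buildRuns(ee))
    mm <- quantifyPerSample(ss, ee)
    for (i in seq_along(ss)) {
        inRun <- pos >= ss$run_start[i] & pos <= ss$run_end[i]
        expect_equal(sum(mm[i, ]), sum(inRun))
    }
})

test_that("cleavage-site TSV mirrors the deposited-table schema", {
    e <- c(endsAt(rep(100L, 12), sample = "A"),
           endsAt(rep(300L, 15), sample = "B"))
    genome <- Biostrings::DNAStringSet(c(c1 = randDna(400)))
    set.seed(2)
    s <- callCleavageSites(e, genome)
    f <- tempfile(fileext = ".tsv")
    writeCleavageSites(s, f, params = "test=1")
    df <- readCleavageSiteTable(f)
    expect_equal(nrow(df), 2L)
    expect_true(all(c("RUN_S", "RUN_E", "RUN_MAX", "SUPPORT",
                      "InternalPrim_FLAG") %in% names(df)))
    expect_equal(df$RUN_MAX, c(99L, 299L))   # 0-based positions
    smry <- summarizeCleavageSiteTable(df)
    expect_equal(smry$n_sites, 2L)
    expect_equal(smry$n_retained + smry$n_flagged, 2L)
})
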