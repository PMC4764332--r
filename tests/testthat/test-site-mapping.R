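# Seed derivation, 7-mer scanning, conservation labels, score attachment.

seedsDf <- function(site7 = "GCACTTT", family_id = "mir17",
                    conserved_family = TRUE) {
    data.frame(family_id = family_id, site7 = site7,
               conserved_family = conserved_family)
}

utrFromSeq <- function(seqs) {
    # one single-interval plus-strand UTR per named sequence on one contig
    lens <- nchar(seqs)
    starts <- cumsum(c(1L, head(lens + 10L, -1L)))
    contig <- paste(vapply(seq_along(seqs), function(i)
        paste0(seqs[i], strrep("T", 10L)), ""), collapse = "")
    genome <- Biostrings::DNAStringSet(c(ctg = contig))
    grl <- stats::setNames(
        GenomicRanges::GRangesList(lapply(seq_along(seqs), function(i)
            GenomicRanges::GRanges("ctg",
                IRanges::IRanges(starts[i], starts[i] + lens[i] - 1L),
                strand = "+"))),
        paste0(names(seqs), "|", names(seqs)))
    readUtrModels(grl, genome)
}

test_that("seed derivation reverse-complements miRNA bases 2-8", {
    # miR-17-5p-like mature sequence: bases 2-8 AAAGUGC -> site GCACTTT
    expect_equal(seedFromMirna("UAAAGUGCUUAUAGUGCAGGUAG"), "GCACTTT")
    expect_equal(seedFromMirna("AAAAAAAA"), "TTTTTTT")
    expect_error(seedFromMirna("AAAAAAA"), "at least 8")
    expect_error(seedFromMirna("AAAAAAAT"), "RNA alphabet")
    expect_equal(seedFromMirna(c("UAAAGUGCUU", "AAAAAAAA")),
                 c("GCACTTT", "TTTTTTT"))
})

test_that("scanning finds exact, overlapping and multi-family matches", {
    u <- utrFromSeq(c(g1 = "GCACTTT"))
    s <- scanSeedSites(u, seedsDf())
    expect_equal(nrow(s), 1L)
    expect_equal(s$utr_start, 0L)

    # no match
    expect_equal(nrow(scanSeedSites(utrFromSeq(c(g1 = "CCCCCCCC")),
                                    seedsDf())), 0L)

    # adjacent occurrences
    s2 <- scanSeedSites(utrFromSeq(c(g1 = "GCACTTTGCACTTT")), seedsDf())
    expect_equal(sort(s2$utr_start), c(0L, 7L))

    # overlapping occurrences are all reported
    s3 <- scanSeedSites(utrFromSeq(c(g1 = "AAAAAAAAA")),
                        seedsDf("AAAAAAA", "polyA"))
    expect_equal(sort(s3$utr_start), 0:2)

    # two families matching the same position
    s4 <- scanSeedSites(utrFromSeq(c(g1 = "GCACTTTA")),
                        seedsDf(c("GCACTTT", "CACTTTA"), c("f1", "f2"),
                                c(TRUE, FALSE)))
    expect_equal(nrow(s4), 2L)
    expect_setequal(s4$family_id, c("f1", "f2"))
})

test_that("N bases never match a seed", {
    genome <- Biostrings::DNAStringSet(c(ctg = "GCANTTTGCACTTT"))
    u <- makeUtrSet(genome, "g1", "g1", "ctg", 1, 14, "+")
    s <- scanSeedSites(u, seedsDf())
    expect_equal(s$utr_start, 7L)
})

test_that("scanning equals a naive substring scan on random UTRs", {
    set.seed(505)
    seeds <- seedsDf(c("GCACTTT", "TTTGCAC", "ACGTACG"),
                     c("f1", "f2", "f3"), c(TRUE, TRUE, FALSE))
    for (i in 1:60) {
        n <- sample(50:400, 1)
        seqs <- setNames(vapply(1:3, function(j) randDna(n), ""),
                         paste0("g", 1:3))
        u <- utrFromSeq(seqs)
        got <- scanSeedSites(u, seeds)
        for (g in names(seqs)) for (f in seq_len(nrow(seeds))) {
            site <- seeds$site7[f]
            naive <- integer(0)
            for (p in seq_len(n - 6L))
                if (substr(seqs[[g]], p, p + 6L) == site)
                    naive <- c(naive, p - 1L)
            mine <- got$utr_start[got$gene_id == g &
                                  got$family_id == seeds$family_id[f]]
            expect_equal(sort(mine), naive)
        }
    }
})

test_that("conservation labels come from the table, validated against 7-mers", {
    u <- utrFromSeq(c(g1 = "GCACTTTAAGCACTTT"))
    seeds <- seedsDf()
    s <- scanSeedSites(u, seeds)
    expect_equal(nrow(s), 2L)

    # empty table -> all non-conserved
    s0 <- labelConserved(s, data.frame(gene_id = character(0),
                                       utr_start = integer(0),
                                       family_id = character(0)))
    expect_false(any(s0$conserved))

    # one listed site -> exactly one conserved
    tab <- data.frame(gene_id = "g1", utr_start = 9L, family_id = "mir17")
    s1 <- labelConserved(s, tab, u, seeds)
    expect_equal(sum(s1$conserved), 1L)
    expect_true(s1$conserved[s1$utr_start == 9L])

    # a table whose positions disagree with the sequence is rejected
    bad <- data.frame(gene_id = "g1", utr_start = c(1L, 3L, 5L),
                      family_id = "mir17")
    expect_error(labelConserved(s, bad, u, seeds), "mismatch")
})

test_that("score attachment joins by site key and rejects conflicts", {
    u <- utrFromSeq(c(g1 = "GCACTTTAAGCACTTT"))
    s <- scanSeedSites(u, seedsDf())
    tab <- data.frame(gene_id = "g1", utr_start = 0L, family_id = "mir17",
                      score = 0.8)
    s1 <- attachScores(s, tab, "pct")
    expect_equal(s1$pct[s1$utr_start == 0L], 0.8)
    expect_true(is.na(s1$pct[s1$utr_start == 9L]))

    s2 <- attachScores(s, transform(tab, score = -0.4), "context")
    expect_equal(s2$context_score[s2$utr_start == 0L], -0.4)

    dup <- rbind(tab, transform(tab, score = 0.2))
    expect_error(attachScores(s, dup, "pct"), "conflicting")
    # exact duplicates are tolerated (deduplicated)
    s3 <- attachScores(s, rbind(tab, tab), "pct")
    expect_equal(s3$pct[s3$utr_start == 0L], 0.8)
})

test_that("generator bookkeeping round-trips through labelling and scores", {
    sim <- simulateApaData(simConfig(n_genes = 50, seed = 41))
    d <- tempfile(); p <- writeSimBundle(sim, d)
    utrs <- readUtrModels(p[["utrs"]], p[["genome"]])
    seeds <- readSeedTable(p[["seeds"]])
    s <- scanSeedSites(utrs, seeds)
    s <- labelConserved(s, readSiteTable(p[["conserved"]]), utrs, seeds)
    s <- attachScores(s, readSiteTable(p[["pct"]]), "pct")
    s <- attachScores(s, readSiteTable(p[["context"]]), "context")
    truth <- sim$truth$sites
    # every planted site is found at its recorded position
    key <- paste(s$gene_id, s$utr_start, s$family_id)
    tkey <- paste(truth$gene_id, truth$utr_start, truth$family_id)
    expect_true(all(tkey %in% key))
    # conserved flags match the generator's bookkeeping exactly
    expect_setequal(key[s$conserved], tkey[truth$conserved])
    # scores agree where planted
    m <- match(tkey, key)
    expect_equal(s$pct[m], truth$pct)
    expect_equal(s$context_score[m], truth$context)
})
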