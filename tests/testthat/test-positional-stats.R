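# Positional profiles, the randomized-APA null, the two permutation tests,
# score-window and relative-position comparisons.

test_that("profile bins sites by distance from the APA anchor", {
    calls <- makeCalls("g1", utr_length = 3000L, apa_pos = 1500L)
    sites <- makeSites("g1", 1350L, conserved = TRUE)
    pr <- profileSites(calls, sites, "apa")
    df <- siteCounts(pr)
    hit <- df$count_conserved > 0
    expect_equal(sum(df$count_conserved), 1L)
    expect_equal(df$bin_start[hit], -200L)   # distance -150 -> bin [-200,-100)
    expect_equal(df$bin_end[hit], -100L)

    # a site exactly at the anchor belongs to the first downstream bin
    pr0 <- profileSites(calls, makeSites("g1", 1500L), "apa")
    df0 <- siteCounts(pr0)
    expect_equal(df0$bin_start[df0$count_conserved > 0], 0L)

    # no sites -> all-zero profile
    prE <- profileSites(calls, makeSites("g1", integer(0)), "apa")
    expect_true(all(siteCounts(prE)$count_conserved == 0L))

    # conserved and non-conserved are tallied separately
    s2 <- rbind(makeSites("g1", c(1350L, 1450L), conserved = TRUE),
                makeSites("g1", 1350L, conserved = FALSE))
    pr2 <- profileSites(calls, s2, "apa")
    expect_equal(sum(pr2@countsConserved), 2L)
    expect_equal(sum(pr2@countsNonconserved), 1L)

    expect_error(profileSites(calls, sites, "apa", flank = 1000L,
                              binWidth = 300L), "multiple")
})

test_that("binning conserves the total site count within the flank", {
    set.seed(61)
    calls <- makeCalls(sprintf("g%02d", 1:30), utr_length = 4000L,
                       apa_pos = sample(1200:2800, 30, replace = TRUE))
    pos <- unlist(lapply(seq_len(30), function(i)
        sample(0:3993, 20, replace = TRUE)))
    sites <- makeSites(rep(calls$gene_id, each = 20), pos)
    pr <- profileSites(calls, sites, "apa")
    d <- sites$utr_start - calls$apa_pos[match(sites$gene_id, calls$gene_id)]
    expect_equal(sum(pr@countsConserved), sum(d >= -1000 & d < 1000))
})

test_that("uniformly planted sites give a flat profile (binomial check)", {
    set.seed(62)
    n <- 400
    calls <- makeCalls(sprintf("g%03d", 1:n), utr_length = 4000L,
                       apa_pos = 2000L)
    nPer <- 10L
    sites <- makeSites(rep(calls$gene_id, each = nPer),
                       unlist(replicate(n, sample(0:3993, nPer), FALSE)))
    pr <- profileSites(calls, sites, "apa")
    counts <- pr@countsConserved
    expTot <- n * nPer * (100 / 3994)
    sdTot <- sqrt(n * nPer * (100 / 3994) * (1 - 100 / 3994))
    expect_true(all(abs(counts - expTot) < 3.5 * sdTot))
    expect_equal(pr@genesPerBin, rep(n, 20L))
})

test_that("utr_end anchoring uses the distal cleavage site", {
    calls <- makeCalls("g1", utr_length = 3000L, apa_pos = 1200L,
                       distal_pos = 2900L)
    expect_equal(apaAnchor(calls, "utr_end"), 2900L)
    sites <- makeSites("g1", 2800L)
    pr <- profileSites(calls, sites, "utr_end")
    df <- siteCounts(pr)
    expect_equal(df$bin_start[df$count_conserved > 0], -100L)
})

test_that("randomized-APA null: eligibility, determinism, planted signal", {
    set.seed(63)
    # a gene with utr_length == 2*flank has no eligible anchor -> excluded
    short <- makeCalls("s", utr_length = 2000L, apa_pos = 1000L)
    expect_error(suppressMessages(
        randomizedApaNull(short, makeSites("s", 10L), seed = 1)),
        "no eligible")

    n <- 150
    calls <- makeCalls(sprintf("g%03d", 1:n), utr_length = 4000L,
                       apa_pos = sample(1100:2900, n, replace = TRUE))
    # plant 3x background density in [-300, 0) of the true APA
    bg <- lapply(seq_len(n), function(i) sample(0:3993, 8))
    extra <- lapply(seq_len(n), function(i)
        calls$apa_pos[i] - sample(300, 5))
    sites <- makeSites(
        rep(calls$gene_id, times = lengths(bg) + lengths(extra)),
        unlist(Map(c, bg, extra)))
    r1 <- randomizedApaNull(calls, sites, nIter = 400, seed = 7)
    r2 <- randomizedApaNull(calls, sites, nIter = 400, seed = 7)
    expect_identical(pValues(r1), pValues(r2))       # bit-reproducible
    expect_identical(nullStats(r1), nullStats(r2))
    pv <- pValues(r1)
    expect_true(all(pv[8:10] < 0.05))                # [-300,0) bins flagged
    expect_true(all(pv > 0 & pv <= 1))
    # observed counts match an independent profile of the same genes
    pr <- profileSites(calls, sites, "apa")
    expect_equal(observedStat(r1), as.numeric(pr@countsConserved),
                 ignore_attr = TRUE)
})

test_that("p-value estimator: bounds, monotonicity, tie handling", {
    # fixed ensemble: monotone in the observed statistic
    null <- matrix(rep(1:10, 3), ncol = 3)
    p <- apaMiR:::.permPvalues(c(0, 5, 11), null, 10L)
    expect_equal(p, c(11, 7, 1) / 11)
    expect_true(all(diff(p) < 0))
    # randomized tie handling never exceeds the conservative value
    set.seed(4)
    for (i in 1:50) {
        obs <- sample(0:5, 3, replace = TRUE)
        nl <- matrix(sample(0:5, 60, replace = TRUE), ncol = 3)
        pc <- apaMiR:::.permPvalues(obs, nl, 20L)
        pr <- apaMiR:::.permPvalues(obs, nl, 20L, u = runif(3))
        expect_true(all(pr <= pc))
        expect_true(all(pr >= 1 / 21))
    }
})

test_that("partition test: degenerate and planted-signal behaviour", {
    set.seed(64)
    n <- 120
    gid <- sprintf("g%03d", 1:n)
    calls <- makeCalls(gid, utr_length = 4000L, apa_pos = 2000L)
    A <- gid[1:60]; B <- gid[61:120]
    # a bin where both groups have zero sites has p = 1 (conservative ties)
    sites0 <- makeSites(gid, 2500L)       # all sites in bin [500,600)
    t0 <- twoSetPartitionTest(A, B, calls, sites0, nIter = 50, seed = 2)
    expect_equal(unname(pValues(t0)[1]), 1)
    expect_error(twoSetPartitionTest(character(0), B, calls, sites0,
                                     nIter = 10, seed = 1), "empty")
    expect_error(twoSetPartitionTest(A, c(B, A[1]), calls, sites0,
                                     nIter = 10, seed = 1), "disjoint")

    # nIter = 1: the +1-corrected estimator can only return 1/2 or 1
    t1 <- twoSetPartitionTest(A, B, calls, sites0, nIter = 1, seed = 3)
    expect_true(all(pValues(t1) %in% c(0.5, 1)))

    # planted excess of conserved sites in [-300,0) only in setB genes
    bg <- makeSites(rep(gid, each = 6),
                    unlist(replicate(n, sample(0:3993, 6), FALSE)))
    ex <- makeSites(rep(B, each = 6),
                    unlist(replicate(60, 2000L - sample(300L, 6), FALSE)))
    tt <- twoSetPartitionTest(A, B, calls, rbind(bg, ex),
                              nIter = 500, seed = 5)
    expect_true(all(pValues(tt)[8:10] < 0.05))
    # determinism
    tt2 <- twoSetPartitionTest(A, B, calls, rbind(bg, ex),
                               nIter = 500, seed = 5)
    expect_identical(pValues(tt), pValues(tt2))
})

test_that("cluster test: identity, degenerate ensemble, planted signal", {
    set.seed(65)
    n <- 100
    gid <- sprintf("g%03d", 1:n)
    calls <- makeCalls(gid, utr_length = 4000L, apa_pos = 2000L)
    sites <- makeSites(rep(gid, each = 5),
                       unlist(replicate(n, sample(0:3993, 5), FALSE)),
                       family_id = sample(c("fa", "fb"), 5 * n, TRUE))
    # cluster = all families: target set == universe, difference 0, p = 1
    tAll <- clusterVsAllTest(c("fa", "fb"), calls, sites,
                             nIter = 50, seed = 1)
    expect_true(all(observedStat(tAll) == 0))
    expect_true(all(pValues(tAll) == 1))
    expect_error(clusterVsAllTest("nosuch", calls, sites,
                                  nIter = 10, seed = 1), "empty")

    # planted cluster signal: fc sites concentrated in [-300,0) for a subset
    targ <- gid[1:30]
    cl <- makeSites(rep(targ, each = 4),
                    unlist(replicate(30, 2000L - sample(300L, 4), FALSE)),
                    family_id = "fc")
    tt <- clusterVsAllTest("fc", calls, rbind(sites, cl),
                           nIter = 500, seed = 6)
    expect_true(any(pValues(tt)[8:10] < 0.05))
})

test_that("score comparison matches hand-computed pooled t", {
    gid <- sprintf("g%02d", 1:40)
    calls <- makeCalls(gid, utr_length = 3000L, apa_pos = 1500L)

    # identical score multisets in both windows -> t = 0, p = 1
    sEq <- rbind(
        makeSites(gid, 1400L, pct = 0.5),
        makeSites(gid, 1600L, pct = 0.5))
    r <- scoreWindowCompare(calls, sEq, kind = "pct")
    expect_equal(r$t_statistic, 0)
    expect_equal(r$p_value, 1)

    # strong planted difference: t > 0, tiny p, matches the closed form
    set.seed(66)
    x5 <- rnorm(200, 0.6, 0.1); x3 <- rnorm(200, 0.4, 0.1)
    sBig <- rbind(
        makeSites(rep(gid, 5), rep(1400L, 200), pct = x5),
        makeSites(rep(gid, 5), rep(1600L, 200), pct = x3))
    rB <- scoreWindowCompare(calls, sBig, kind = "pct")
    expect_gt(rB$t_statistic, 0)
    expect_lt(rB$p_value, 1e-6)
    o <- oracleStudentT(x5, x3)
    expect_equal(rB$t_statistic, o$t, tolerance = 1e-12)
    expect_equal(rB$p_value, o$p, tolerance = 1e-12)
    expect_equal(rB$n_5p, 200L)

    # one empty window -> error
    s5only <- makeSites(gid, 1400L, pct = 0.5)
    expect_error(scoreWindowCompare(calls, s5only, kind = "pct"), "at least 2")

    # context scores route through context_score
    sCtx <- rbind(makeSites(gid, 1400L, context_score = rnorm(40, -0.4, 0.05)),
                  makeSites(gid, 1600L, context_score = rnorm(40, -0.1, 0.05)))
    rC <- scoreWindowCompare(calls, sCtx, kind = "context")
    expect_lt(rC$t_statistic, 0)   # 5' scores are lower (stronger)
})

test_that("score comparison p agrees with a permutation cross-check", {
    set.seed(67)
    gid <- sprintf("g%02d", 1:30)
    calls <- makeCalls(gid, utr_length = 3000L, apa_pos = 1500L)
    x5 <- rnorm(30, 0.52, 0.1); x3 <- rnorm(30, 0.45, 0.1)
    s <- rbind(makeSites(gid, 1400L, pct = x5),
               makeSites(gid, 1600L, pct = x3))
    r <- scoreWindowCompare(calls, s, kind = "pct")
    pooled <- c(x5, x3)
    B <- 4000
    tperm <- replicate(B, {
        idx <- sample(60, 30)
        oracleStudentT(pooled[idx], pooled[-idx])$t
    })
    pPerm <- mean(abs(tperm) >= abs(r$t_statistic))
    se <- sqrt(pPerm * (1 - pPerm) / B) + 1e-3
    expect_lt(abs(pPerm - r$p_value), 4 * se + 0.01)
})

test_that("relative positions separate APA from non-APA gene classes", {
    set.seed(68)
    n <- 80
    gid <- sprintf("g%03d", 1:n)
    isApa <- rep(c(TRUE, FALSE), each = n / 2)
    calls <- makeCalls(gid, utr_length = 2000L,
                       apa_pos = ifelse(isApa, 1000L, NA))
    # identical distributions -> t near 0, p not small
    sU <- makeSites(rep(gid, each = 10),
                    unlist(replicate(n, sample(0:1993, 10), FALSE)))
    r0 <- relativePositionCompare(calls, sU)
    expect_gt(r0$p_value, 0.001)

    # non-APA sites concentrated near the distal end (rel pos ~0.9)
    sA <- makeSites(rep(gid[isApa], each = 10),
                    unlist(replicate(n / 2, sample(0:1993, 10), FALSE)))
    sN <- makeSites(rep(gid[!isApa], each = 10),
                    unlist(replicate(n / 2, 1750L + sample(200L, 10), FALSE)))
    r1 <- relativePositionCompare(calls, rbind(sA, sN))
    expect_lt(r1$t_statistic, 0)          # APA genes less distal
    expect_lt(r1$p_value, 1e-6)
    expect_gt(r1$mean_non_apa, r1$mean_apa)
    # decile profile is a proper distribution
    expect_equal(sum(r1$deciles$frac_apa), 1)
    expect_equal(sum(r1$deciles$frac_non_apa), 1)
    # a site at utr_length - 7 still has relative position < 1
    s2 <- makeSites(gid, 1993L)
    expect_true(all(s2$utr_start / calls$utr_length < 1))

    expect_error(relativePositionCompare(calls, sA), "each gene class")
})

test_that("profile TSV export carries counts and null statistics", {
    calls <- makeCalls(sprintf("g%d", 1:30), utr_length = 4000L,
                       apa_pos = 1500L)
    sites <- makeSites(calls$gene_id, 1350L)
    pr <- profileSites(calls, sites, "apa")
    nt <- randomizedApaNull(calls, sites, nIter = 50, seed = 3)
    f <- tempfile(fileext = ".tsv")
    writeProfile(pr, f, nullResult = nt, params = "flank=1000")
    df <- readTsv(f)
    expect_equal(nrow(df), 20L)
    expect_true(all(c("count_conserved", "null_mean", "p_value") %in%
                    names(df)))
    expect_equal(sum(df$count_conserved), 30L)
})
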