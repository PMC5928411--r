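test_that("window track tiles chromosomes and pools counts", {
    g <- methGenome(c(chr1 = 60000))
    sm <- makeMeth(c(100, 200, 300), c(10, 10, 10), c(2, 4, 4),
        genome = g)
    tr <- windowMethylation(sm, g, windowSize = 20000, minCoverage = 5,
        minCpgs = 3)
    expect_length(tr, 3L)           # 60 kb -> exactly 3 windows
    expect_equal(mcols(tr)$level[1], 30 / 40)  # pooled 30 meth / 10 unmeth
    expect_true(mcols(tr)$usable[1])
    expect_false(mcols(tr)$usable[2])  # 0 covered CpGs -> excluded
    expect_true(is.na(mcols(tr)$level[3]))
})

test_that("binarization is strict-greater with ties assigned 0", {
    g <- methGenome(c(chr1 = 60000))
    sm <- makeMeth(c(100, 20100, 40100), c(6001, 5999, 6000),
        c(3999, 4001, 4000), genome = g)
    tr <- binarizeWindows(windowMethylation(sm, g, 20000, 5, 1))
    expect_equal(mcols(tr)$label, c(1L, 0L, 0L))  # .6001, .5999, .6000
    # property: label 1 iff level > threshold, over random levels
    set.seed(2)
    lev <- c(runif(50), 0.60)
    tot <- 10000L
    sm2 <- makeMeth(seq(100, by = 20000, length.out = 51),
        round(lev * tot), tot - round(lev * tot),
        genome = methGenome(c(chr1 = 51 * 20000)))
    tr2 <- binarizeWindows(windowMethylation(sm2,
        methGenome(c(chr1 = 51 * 20000)), 20000, 5, 1))
    expect_equal(mcols(tr2)$label,
        as.integer(round(lev * tot) / tot > 0.60))
})

test_that("Viterbi segmentation finds runs of 0 windows", {
    # all background -> no PMD
    expect_length(hmmSegment(makeTrack(rep(1L, 40))), 0L)
    # a clean 20-window run of 0s decodes exactly
    tr <- makeTrack(c(rep(1L, 40), rep(0L, 20), rep(1L, 40)))
    seg <- hmmSegment(tr)
    expect_length(seg, 1L)
    expect_equal(mcols(seg)$n_windows, 20L)
    expect_equal(start(seg), 40 * 20000 + 1)
    expect_equal(end(seg), 60 * 20000)
    # a single isolated 0 is absorbed by the background state
    one0 <- rep(1L, 81); one0[41] <- 0L
    expect_length(hmmSegment(makeTrack(one0)), 0L)
    # three isolated 0s decode as a PMD under the defaults
    tr3 <- makeTrack(c(rep(1L, 20), rep(0L, 3), rep(1L, 20)))
    expect_equal(mcols(hmmSegment(tr3))$n_windows, 3L)
})

test_that("excluded windows split the HMM sequence", {
    # 0-run interrupted by an excluded window cannot bridge it
    lab <- c(rep(1L, 10), rep(0L, 4), NA, rep(0L, 4), rep(1L, 10))
    seg <- hmmSegment(makeTrack(lab))
    expect_length(seg, 2L)
    expect_equal(mcols(seg)$n_windows, c(4L, 4L))
})

test_that("Baum-Welch refinement is deterministic and converges", {
    lab <- c(rep(1L, 30), rep(0L, 10), rep(1L, 30), rep(0L, 8),
        rep(1L, 24))
    tr <- makeTrack(lab)
    p <- hmmParams(train = "baum_welch", maxIter = 50)
    s1 <- hmmSegment(tr, p)
    s2 <- hmmSegment(tr, p)
    expect_identical(start(s1), start(s2))
    expect_identical(end(s1), end(s2))
    expect_length(s1, 2L)
})

test_that("consensus requires min samples and min windows", {
    g <- methGenome(c(chr1 = 2e6))
    pmd <- GRanges("chr1", IRanges(200001, 300000))  # 5 windows
    same <- list(a = pmd, b = pmd, c = pmd, d = pmd)
    cons <- consensusPmds(same, g, minSamples = 3, minWindows = 3)
    expect_length(cons, 1L)
    expect_equal(mcols(cons)$support, 4)
    expect_equal(mcols(cons)$n_windows, 5L)
    expect_equal(mcols(cons)$samples, "a,b,c,d")
    # present in only 2 of 4 samples -> absent
    two <- list(a = pmd, b = pmd, c = GRanges(), d = GRanges())
    expect_length(consensusPmds(two, g), 0L)
    # staggered calls: only the central 3 windows reach support 3
    stag <- list(
        a = GRanges("chr1", IRanges(200001, 300000)),   # win 11-15
        b = GRanges("chr1", IRanges(220001, 320000)),   # win 12-16
        c = GRanges("chr1", IRanges(240001, 340000)))   # win 13-17
    cons3 <- consensusPmds(stag, g, minSamples = 3, minWindows = 3)
    expect_length(cons3, 1L)
    expect_equal(start(cons3), 240001)
    expect_equal(end(cons3), 300000)
    # below min window run length is dropped
    cons4 <- consensusPmds(stag, g, minSamples = 3, minWindows = 4)
    expect_length(cons4, 0L)
    expect_error(consensusPmds(stag[1:2], g), "at least 3")
})

test_that("consensus is monotone in added samples", {
    g <- methGenome(c(chr1 = 2e6))
    set.seed(4)
    mk <- function() {
        st <- sample(seq(1, 1.6e6, by = 20000), 3)
        GRanges("chr1", IRanges(st, st + sample(3:8, 3) * 20000 - 1))
    }
    calls <- replicate(4, mk())
    c4 <- consensusPmds(calls, g)
    c5 <- consensusPmds(c(calls, mk()), g)
    # every consensus window from 4 samples survives a 5th sample
    if (length(c4))
        expect_true(all(overlapsAny(c4, c5)) &&
            sum(width(GenomicRanges::intersect(c4, c5))) == sum(width(c4)))
    else succeed()
})

test_that("satellite density is merged-overlap bp over region length", {
    region <- GRanges("chr1", IRanges(1, 100000))
    sat <- GRanges("chr1", IRanges(10001, 35000))
    expect_equal(satelliteDensity(region, sat), 0.25)
    expect_equal(satelliteDensity(region, GRanges("chr2",
        IRanges(1, 10))), 0.0)
    inside <- GRanges("chr1", IRanges(20000, 20999))
    expect_equal(satelliteDensity(inside, sat), 1.0)
    # fragmentation invariance: splitting satellite records changes nothing
    frag <- GRanges("chr1", IRanges(c(10001, 20001, 15000), c(20000,
        35000, 26000)))
    expect_equal(satelliteDensity(region, frag), 0.25)
    expect_true(all(satelliteDensity(region, frag) >= 0 &
        satelliteDensity(region, frag) <= 1))
})

test_that("satellite-density correlation recovers a planted slope", {
    set.seed(6)
    g <- methGenome(c(chr1 = 3.1e6))
    pmds <- GRanges("chr1", IRanges(seq(1, by = 1e5, length.out = 30),
        width = 5e4))
    dens <- runif(30, 0, 0.8)
    sat <- GRanges("chr1", IRanges(start(pmds),
        width = pmax(1, round(dens * 5e4))))
    level <- pmin(pmax(0.5 - 0.4 * satelliteDensity(pmds, sat) +
        rnorm(30, 0, 0.02), 0.01), 0.99)
    # one CpG cluster per PMD carrying the target level
    pos <- rep(start(pmds), each = 5) + seq(0, 400, by = 100)
    tot <- 1000L
    m <- round(rep(level, each = 5) * tot)
    sm <- makeMeth(pos, m, tot - m, genome = g, sampleId = "s")
    res <- pmdSatelliteCorrelation(pmds, list(sm), sat)
    expect_lt(res$r, -0.9)
    expect_lt(res$p, 1e-6)
    # constant density -> flagged NA
    satc <- GRanges("chr1", IRanges(start(pmds), width = 10000))
    resc <- pmdSatelliteCorrelation(pmds, list(sm), satc)
    expect_true(is.na(resc$r))
    expect_error(pmdSatelliteCorrelation(pmds[1:2], list(sm), sat),
        "at least 3")
})

test_that("independent methylation gives weak correlation in most runs", {
    g <- methGenome(c(chr1 = 3.1e6))
    pmds <- GRanges("chr1", IRanges(seq(1, by = 1e5, length.out = 30),
        width = 5e4))
    hits <- 0L
    for (sd0 in 1:20) {
        set.seed(100 + sd0)
        dens <- runif(30, 0, 0.8)
        sat <- GRanges("chr1", IRanges(start(pmds),
            width = pmax(1, round(dens * 5e4))))
        level <- runif(30, 0.2, 0.8)      # independent of density
        pos <- rep(start(pmds), each = 5) + seq(0, 400, by = 100)
        tot <- 1000L
        m <- round(rep(level, each = 5) * tot)
        sm <- makeMeth(pos, m, tot - m, genome = g)
        r <- pmdSatelliteCorrelation(pmds, list(sm), sat)$r
        if (abs(r) < 0.5) hits <- hits + 1L
    }
    expect_gte(hits, 19L)
})

test_that("gene-level PMD differences use a t test with BH correction", {
    g <- methGenome(c(chr1 = 1e6))
    pmds <- GRanges("chr1", IRanges(100001, 300000))
    genes <- GRanges("chr1", IRanges(c(150001, 500001), width = 10000),
        strand = "+", seqinfo = seqinfo(g))
    mcols(genes)$gene_id <- c("inPmd", "outside")
    mcols(genes)$tss <- start(genes)
    pos <- c(seq(150101, by = 500, length.out = 10),
        seq(500101, by = 500, length.out = 10))
    mk <- function(id, grp, lev) {
        tot <- 200L
        makeMeth(pos, round(lev * tot), tot - round(lev * tot),
            genome = g, sampleId = id, group = grp)
    }
    set.seed(8)
    samples <- list(
        mk("s1", "sperm", 0.10 + runif(20, 0, 0.02)),
        mk("s2", "sperm", 0.10 + runif(20, 0, 0.02)),
        mk("o1", "somatic", 0.90 + runif(20, 0, 0.02)),
        mk("o2", "somatic", 0.90 + runif(20, 0, 0.02)))
    res <- pmdGeneDiff(pmds, genes, samples,
        groups = c("sperm", "somatic"))
    # only the gene overlapping the PMD is tested
    expect_equal(res$gene_id, "inPmd")
    expect_true(res$significant)
    expect_lt(res$diff, -0.75)
    expect_true(res$hypo_sperm && res$hyper_somatic)
    # identical levels across groups -> not reported
    same <- list(mk("s1", "sperm", 0.5), mk("s2", "sperm", 0.5),
        mk("o1", "somatic", 0.5), mk("o2", "somatic", 0.5))
    res2 <- pmdGeneDiff(pmds, genes, same,
        groups = c("sperm", "somatic"))
    expect_false(any(res2$significant))
})
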