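test_that("HMR caller recovers a clean hypomethylated cluster", {
    g <- methGenome(c(chr1 = 1e5))
    # 10 CpGs at level 0 spaced 25 bp, methylated flanks >= 500 bp away
    hypoPos <- seq(5000, by = 25, length.out = 10)
    flankPos <- c(seq(3000, by = 100, length.out = 10),
        seq(6000, by = 100, length.out = 10))
    pos <- sort(c(hypoPos, flankPos))
    lev <- ifelse(pos %in% hypoPos, 0, 1)
    sm <- makeMeth(pos, round(lev * 10), 10 - round(lev * 10),
        genome = g)
    h <- callHmrs(sm)
    expect_length(h, 1L)
    expect_equal(start(h), 5000)
    expect_equal(end(h), 5000 + 9 * 25)
    expect_equal(mcols(h)$n_cpgs, 10L)
    expect_equal(mcols(h)$mean_meth, 0)

    # fully methylated chromosome -> nothing
    all1 <- makeMeth(pos, rep(10, length(pos)), rep(0, length(pos)),
        genome = g)
    expect_length(callHmrs(all1), 0L)

    # 4 isolated hypo CpGs fail the >= 5 CpG filter
    four <- makeMeth(seq(5000, by = 25, length.out = 4), rep(0, 4),
        rep(10, 4), genome = g)
    expect_length(callHmrs(four), 0L)
})

test_that("every emitted HMR satisfies its own definition", {
    set.seed(31)
    g <- methGenome(c(chr1 = 2e5))
    for (rep in 1:5) {
        pos <- sort(sample.int(1.9e5, 2000))
        truep <- ifelse(runif(2000) < 0.25, runif(2000, 0, 0.15),
            runif(2000, 0.5, 1))
        cov <- rpois(2000, 6)
        m <- rbinom(2000, cov, truep)
        keep <- cov > 0
        sm <- makeMeth(pos[keep], m[keep], (cov - m)[keep], genome = g)
        h <- callHmrs(sm)
        if (length(h) == 0) next
        expect_true(all(mcols(h)$n_cpgs >= 5))
        expect_true(all(mcols(h)$n_hypo / mcols(h)$n_cpgs >= 0.8))
        # boundary CpGs are hypomethylated: re-derive from the sites
        s <- methSites(sm)
        scov <- siteCoverage(sm); slev <- siteLevel(sm)
        covd <- s[scov >= 5]
        lv <- slev[scov >= 5]
        for (i in seq_along(h)) {
            inside <- which(start(covd) >= start(h)[i] &
                start(covd) <= end(h)[i])
            expect_equal(start(covd)[inside[1]], start(h)[i])
            expect_equal(start(covd)[inside[length(inside)]], end(h)[i])
            expect_lt(lv[inside[1]], 0.2)
            expect_lt(lv[inside[length(inside)]], 0.2)
        }
    }
})

test_that("raising the hypo level never shrinks total HMR bp", {
    set.seed(32)
    g <- methGenome(c(chr1 = 2e5))
    for (rep in 1:10) {
        pos <- sort(sample.int(1.9e5, 1500))
        truep <- runif(1500)
        cov <- rpois(1500, 8)
        m <- rbinom(1500, cov, truep)
        keep <- cov > 0
        sm <- makeMeth(pos[keep], m[keep], (cov - m)[keep], genome = g)
        bp20 <- sum(width(callHmrs(sm, hypoLevel = 0.20)))
        bp30 <- sum(width(callHmrs(sm, hypoLevel = 0.30)))
        expect_gte(bp30, bp20)
    }
})

test_that("HMR set comparison accounts for every base pair", {
    A <- GRanges("chr1", IRanges(100, 399))
    B <- GRanges("chr1", IRanges(200, 299))
    cmp <- compareHmrSets(A, B)
    expect_equal(cmp$shared_bp, 100)
    expect_equal(cmp$a_unique_bp, 200)
    expect_equal(cmp$b_unique_bp, 0)
    expect_equal(unname(cmp$pair_classes["nested"]), 1L)
    # identity and disjointness
    idc <- compareHmrSets(A, A)
    expect_equal(idc$shared_bp, idc$a_total_bp)
    expect_equal(idc$a_unique_bp, 0)
    dis <- compareHmrSets(A, GRanges("chr1", IRanges(1000, 1100)))
    expect_equal(dis$shared_bp, 0)
    # accounting identity on random sets
    set.seed(33)
    for (i in 1:10) {
        a <- randomIntervals(30, c(chr1 = 1e5, chr2 = 1e5), 3000)
        b <- randomIntervals(30, c(chr1 = 1e5, chr2 = 1e5), 3000)
        cc <- compareHmrSets(a, b)
        expect_equal(cc$shared_bp + cc$a_unique_bp, cc$a_total_bp)
        expect_equal(cc$shared_bp + cc$b_unique_bp, cc$b_total_bp)
    }
})

test_that("nesting classification honours the flank margin", {
    sp <- GRanges("chr1", IRanges(100, 399))
    expect_equal(classifyNesting(GRanges("chr1", IRanges(200, 299)), sp),
        "nested_both_sides")
    expect_equal(classifyNesting(GRanges("chr1", IRanges(100, 299)), sp),
        "nested_one_side")
    expect_equal(classifyNesting(GRanges("chr1", IRanges(50, 299)), sp),
        "not_nested")
    # coincident boundaries within the margin are not nesting
    expect_equal(classifyNesting(GRanges("chr1", IRanges(130, 380)), sp),
        "not_nested")
    expect_error(classifyNesting(GRanges("chr2", IRanges(200, 299)), sp),
        "different chromosomes")
})

test_that("group combiners take union, intersection and majority", {
    a <- GRanges("chr1", IRanges(100, 299))
    b <- GRanges("chr1", IRanges(200, 399))
    c0 <- GRanges("chr1", IRanges(250, 499))
    u <- combineHmrs(list(a, b, c0), "union")
    expect_equal(start(u), 100); expect_equal(end(u), 499)
    it <- combineHmrs(list(a, b, c0), "intersection")
    expect_equal(start(it), 250); expect_equal(end(it), 299)
    mj <- combineHmrs(list(a, b, c0), "majority")
    expect_equal(start(mj), 200); expect_equal(end(mj), 399)
})

test_that("TSS metaprofile bins are strand-oriented", {
    g <- methGenome(c(chr1 = 1e5))
    genes <- GRanges("chr1", IRanges(c(10000, 40000), width = 5000),
        strand = c("+", "-"), seqinfo = seqinfo(g))
    mcols(genes)$gene_id <- c("p", "m")
    mcols(genes)$tss <- c(10000L, 44999L)
    # one CpG 150 bp downstream of the + TSS at level 0.4
    sm <- makeMeth(10150, 4, 6, genome = g, group = "sperm")
    pr <- tssMetaprofile(list(sm), genes[1], flank = 2000, bin = 100)
    expect_equal(pr$offset, 100)
    expect_equal(pr$mean_meth, 0.4)
    # on the - gene, a CpG physically left of the TSS gets a positive
    # offset
    sm2 <- makeMeth(44999 - 150, 8, 2, genome = g, group = "sperm")
    pr2 <- tssMetaprofile(list(sm2), genes[2], flank = 2000, bin = 100)
    expect_equal(pr2$offset, 100)
    # uniform methylation gives a flat profile
    pos <- seq(8100, 11900, by = 100)
    sm3 <- makeMeth(pos, rep(3, length(pos)), rep(1, length(pos)),
        genome = g, group = "sperm")
    pr3 <- tssMetaprofile(list(sm3), genes[1], flank = 2000, bin = 100)
    expect_true(all(abs(pr3$mean_meth - 0.75) < 1e-12))
    # restriction errors when no TSS is inside the set
    expect_error(tssMetaprofile(list(sm3), genes,
        restrictTo = GRanges("chr1", IRanges(1, 10))), "restriction")
})

test_that("TSS gene sets follow point overlap with half-open boundaries", {
    g <- methGenome(c(chr1 = 1e5))
    genes <- GRanges("chr1", IRanges(c(1000, 2000, 3000), width = 100),
        strand = "+", seqinfo = seqinfo(g))
    mcols(genes)$gene_id <- c("both", "aOnly", "outside")
    mcols(genes)$tss <- c(1000L, 2000L, 3000L)
    A <- GRanges("chr1", IRanges(c(950, 1950), c(1050, 2050)))
    B <- GRanges("chr1", IRanges(950, 1050))
    sets <- hmrTssGeneSets(A, B, genes)
    expect_equal(sets$shared, "both")
    expect_equal(sets$a_specific, "aOnly")
    expect_length(sets$b_specific, 0L)
    # a TSS one bp past an HMR end does not overlap
    genes3 <- genes[3]
    mcols(genes3)$tss <- 2051L
    expect_length(hmrTssGeneSets(A, B, genes3)$a_specific, 0L)
    mcols(genes3)$tss <- 2050L
    expect_equal(hmrTssGeneSets(A, B, genes3)$a_specific, "outside")
})

test_that("planted promoter HMRs are recovered from the simulator", {
    cs <- cachedSim("hmr", smallSimConfig(seed = 301, nPmds = 0L,
        nSatBlocksPerChrom = 0L, satStartLength = 0L,
        nYoungSinesNearTss = 0L, nDmcSites = 0L))
    sperm <- cs$meth$samples[vapply(cs$meth$samples, sampleGroup, "") ==
        "sperm"]
    calls <- lapply(sperm, callHmrs,
        chromosomes = autosomes(cs$sim$genome))
    un <- combineHmrs(calls)
    ev <- truthEvaluation(un, cs$meth$truth$hmrs$sperm, toleranceBp = 50)
    expect_gte(ev$sensitivity, 0.9)
    expect_gte(ev$precision, 0.9)
    expect_lte(mean(c(ev$boundary$start_error, ev$boundary$end_error)),
        50)
})
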