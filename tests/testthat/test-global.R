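test_that("common-site matrix is the coverage-filtered intersection", {
    g <- methGenome(c(chr1 = 1e4))
    a <- makeMeth(c(10, 20, 30, 40, 50), rep(5, 5), rep(5, 5),
        genome = g, sampleId = "a", group = "sperm")
    # b shares qualifying coverage at 3 of the 5 positions
    b <- makeMeth(c(10, 20, 30, 40, 50), c(5, 5, 5, 1, 5),
        c(5, 5, 5, 1, 0), genome = g, sampleId = "b", group = "somatic")
    se <- buildCommonMatrix(list(a, b), siteMinCoverage = 10)
    expect_equal(nrow(se), 3L)
    expect_equal(start(SummarizedExperiment::rowRanges(se)),
        c(10, 20, 30))
    # threshold 1 on identical samples keeps everything
    se2 <- buildCommonMatrix(list(a, a), siteMinCoverage = 1)
    expect_equal(nrow(se2), 5L)
    # a sample with no qualifying site is an error
    z <- makeMeth(c(10, 20), c(0, 0), c(0, 0), genome = g,
        sampleId = "z", group = "somatic")
    expect_error(buildCommonMatrix(list(a, z), 10), "no site passing")
})

test_that("pairwise correlation is symmetric with unit diagonal", {
    g <- methGenome(c(chr1 = 1e6))
    set.seed(5)
    n <- 10000
    pos <- sort(sample.int(9e5, n))
    # planted shared component: both samples binomial around the same
    # per-site truth; independent noise from finite coverage
    truth <- rbeta(n, 3, 1)
    cov <- 50L
    mkS <- function(id) makeMeth(pos, rbinom(n, cov, truth),
        cov - rbinom(n, cov, truth), genome = g, sampleId = id)
    # expected r = var(truth) / (var(truth) + binomial noise var)
    a <- makeMeth(pos, (ma <- rbinom(n, cov, truth)), cov - ma,
        genome = g, sampleId = "a", group = "sperm")
    b <- makeMeth(pos, (mb <- rbinom(n, cov, truth)), cov - mb,
        genome = g, sampleId = "b", group = "somatic")
    se <- buildCommonMatrix(list(a, b), siteMinCoverage = 1)
    r <- pairwiseCorrelation(se)
    expect_equal(r, t(r))
    expect_equal(unname(diag(r)), c(1, 1))
    vt <- stats::var(truth)
    noise <- mean(truth * (1 - truth)) / cov
    expect_equal(r["a", "b"], vt / (vt + noise), tolerance = 0.05)

    # duplicated sample correlates at exactly 1
    se2 <- buildCommonMatrix(list(a, a), siteMinCoverage = 1)
    expect_equal(unname(pairwiseCorrelation(se2)[1, 2]), 1)
    # mirrored levels correlate at -1
    flip <- makeMeth(pos, cov - ma, ma, genome = g, sampleId = "f",
        group = "somatic")
    se3 <- buildCommonMatrix(list(a, flip), siteMinCoverage = 1)
    expect_equal(unname(pairwiseCorrelation(se3)[1, 2]), -1)
    # zero-variance sample flagged as NA
    const <- makeMeth(pos, rep(5L, n), rep(5L, n), genome = g,
        sampleId = "c", group = "somatic")
    expect_warning(rz <- pairwiseCorrelation(
        buildCommonMatrix(list(a, const), 1)), "zero-variance")
    expect_true(is.na(rz["a", "c"]))
})

test_that("DMC exact test matches enumeration and applies both cutoffs", {
    g <- methGenome(c(chr1 = 1e4))
    # extreme site: sperm pooled 0/20 vs somatic 20/0
    a <- makeMeth(c(10, 20), c(0, 5), c(20, 5), genome = g,
        sampleId = "a", group = "sperm")
    b <- makeMeth(c(10, 20), c(20, 5), c(0, 5), genome = g,
        sampleId = "b", group = "somatic")
    se <- buildCommonMatrix(list(a, b), siteMinCoverage = 10)
    res <- callDmcs(se, groups = c("sperm", "somatic"))
    expect_equal(res$diff[1], -1)
    expect_equal(res$p[1], enumHyperP(0, 20, 20, 0))
    expect_true(res$dmc[1])
    # identical pooled counts -> difference 0, never reported
    expect_equal(res$diff[2], 0)
    expect_false(res$dmc[2])
})

test_that("exact-test p-values equal brute-force enumeration", {
    # sampled margins up to total 60; the exhaustive sweep over every
    # table runs in the acceptance suite
    set.seed(9)
    for (i in 1:300) {
        N <- sample(4:60, 1)
        n1 <- sample(1:(N - 1), 1)
        M <- sample(0:N, 1)
        lo <- max(0, n1 - (N - M)); hi <- min(n1, M)
        m1 <- if (lo == hi) lo else sample(lo:hi, 1)
        p <- methseg:::twoSidedHyperP(m1, n1 - m1, M - m1,
            (N - n1) - (M - m1))
        expect_equal(p, enumHyperP(m1, n1 - m1, M - m1,
            (N - n1) - (M - m1)), tolerance = 1e-12)
    }
})

test_that("null DMC simulation keeps the BH false-positive rate in check", {
    set.seed(21)
    g <- methGenome(c(chr1 = 1e7))
    n <- 4000
    pos <- sort(sample.int(9e6, n))
    mk <- function(id, grp) {
        cov <- rpois(n, 10)
        m <- rbinom(n, cov, 0.75)
        makeMeth(pos, m, cov - m, genome = g, sampleId = id, group = grp)
    }
    se <- buildCommonMatrix(list(mk("a", "sperm"), mk("b", "somatic")),
        siteMinCoverage = 1)
    res <- callDmcs(se)
    expect_lte(mean(res$q < 0.01), 0.01)
})

test_that("element methylation applies the detection-rate filter", {
    g <- methGenome(c(chr1 = 1e5))
    # element with 60 CpG positions, only 5 covered -> fail (<10%)
    idx <- GRanges("chr1", IRanges(seq(1000, by = 10, length.out = 60),
        width = 1))
    sm <- makeMeth(seq(1000, by = 10, length.out = 5),
        rep(2, 5), rep(3, 5), genome = g)
    el <- GRanges("chr1", IRanges(900, 1700))
    r <- elementMethylation(sm, el, cpgIndex = idx, minCoverage = 5)
    expect_false(mcols(r)$pass)
    expect_true(is.na(mcols(r)$level))
    # small element: 10 CpGs, 5 detected pooling 4/20 -> level 0.2, pass
    idx2 <- GRanges("chr1", IRanges(seq(5000, by = 10, length.out = 10),
        width = 1))
    sm2 <- makeMeth(seq(5000, by = 10, length.out = 5),
        c(1, 1, 1, 1, 0), c(3, 3, 3, 3, 4), genome = g)
    el2 <- GRanges("chr1", IRanges(4990, 5100))
    r2 <- elementMethylation(sm2, el2, cpgIndex = idx2, minCoverage = 4)
    expect_true(mcols(r2)$pass)
    expect_equal(mcols(r2)$level, 0.2)
    # element containing no CpG position fails
    el3 <- GRanges("chr1", IRanges(90000, 90100))
    r3 <- elementMethylation(sm2, el3, cpgIndex = idx2)
    expect_false(mcols(r3)$pass)
})

test_that("element methylation is invariant to element order", {
    g <- methGenome(c(chr1 = 1e5))
    set.seed(12)
    pos <- sort(sample.int(9e4, 500))
    sm <- makeMeth(pos, rbinom(500, 8, 0.6), rbinom(500, 8, 0.4),
        genome = g)
    els <- randomIntervals(20, c(chr1 = 1e5), maxLen = 2000)
    r1 <- elementMethylation(sm, els)
    perm <- sample(20)
    r2 <- elementMethylation(sm, els[perm])
    expect_equal(mcols(r2)$level, mcols(r1)$level[perm])
})

test_that("promoters are +/-1 kb around the strand-aware TSS", {
    g <- methGenome(c(chr1 = 1e4))
    genes <- GRanges("chr1", IRanges(c(5001, 2001), c(8000, 5000)),
        strand = c("+", "-"), seqinfo = seqinfo(g))
    mcols(genes)$gene_id <- c("plus", "minus")
    mcols(genes)$tss <- c(5001L, 5000L)
    pr <- promotersFromGenes(genes, g)
    # + gene with txStart 5000 (0-based): promoter [4000, 6000) 0-based
    expect_equal(start(pr)[1], 4001)
    expect_equal(end(pr)[1], 6000)
    # - gene with txEnd 5000: same promoter by strand symmetry
    expect_equal(start(pr)[2], 4001)
    expect_equal(end(pr)[2], 6000)
    # clipping at the chromosome start
    mcols(genes)$tss <- c(501L, 5000L)
    pr2 <- promotersFromGenes(genes, g)
    expect_equal(start(pr2)[1], 1)
    expect_equal(end(pr2)[1], 1500)
    # TSS outside the chromosome is an error
    mcols(genes)$tss <- c(50000L, 5000L)
    expect_error(promotersFromGenes(genes, g), "outside")
})
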