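suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
})

## build a Methylome from plain vectors
makeMeth <- function(pos, meth, unmeth, chrom = "chr1", strand = "+",
                     context = "CpG", genome = NULL, sampleId = "s1",
                     group = "sperm") {
    lv <- if (!is.null(genome)) seqlevels(genome) else unique(chrom)
    gr <- GRanges(factor(chrom, levels = lv), IRanges(pos, width = 1L),
        strand = strand)
    if (!is.null(genome)) seqinfo(gr) <- seqinfo(genome)
    mcols(gr)$n_meth <- as.integer(meth)
    mcols(gr)$n_unmeth <- as.integer(unmeth)
    mcols(gr)$context <- context
    Methylome(gr, sampleId = sampleId, group = group)
}

## binarized window track built directly from a label vector (one
## chromosome), for exercising the HMM in isolation
makeTrack <- function(labels, chrom = "chr1", windowSize = 20000L) {
    n <- length(labels)
    win <- GRanges(chrom, IRanges(seq(1L, by = windowSize, length.out = n),
        width = windowSize))
    mcols(win)$meth <- ifelse(!is.na(labels) & labels == 1L, 90, 30)
    mcols(win)$total <- 100
    mcols(win)$n_cpgs <- ifelse(is.na(labels), 0L, 50L)
    mcols(win)$level <- mcols(win)$meth / mcols(win)$total
    mcols(win)$label <- as.integer(labels)
    mcols(win)$usable <- !is.na(labels)
    win
}

## exhaustive two-sided p for a 2x2 table via direct factorial
## enumeration (independent of dhyper)
enumHyperP <- function(m1, u1, m2, u2) {
    M <- m1 + m2; n1 <- m1 + u1; N <- m1 + u1 + m2 + u2
    lo <- max(0, n1 - (N - M)); hi <- min(n1, M)
    k <- lo:hi
    logp <- lchoose(M, k) + lchoose(N - M, n1 - k) - lchoose(N, n1)
    pr <- exp(logp)
    obs <- pr[k == m1]
    sum(pr[pr <= obs * (1 + 1e-7)])
}

## per-base brute-force counting oracle for interval statistics on a
## small genome: represents each chromosome as a logical mask
maskOf <- function(gr, seqlens) {
    masks <- lapply(names(seqlens), function(ch) {
        m <- logical(seqlens[[ch]])
        g <- gr[as.character(seqnames(gr)) == ch]
        for (i in seq_along(g))
            m[start(g)[i]:min(end(g)[i], seqlens[[ch]])] <- TRUE
        m
    })
    names(masks) <- names(seqlens)
    masks
}

maskBp <- function(masks) sum(vapply(masks, sum, 0))

maskIntersectBp <- function(a, b)
    sum(vapply(names(a), function(ch) sum(a[[ch]] & b[[ch]]), 0))

## random GRanges on a small genome
randomIntervals <- function(n, seqlens, maxLen = 5000L) {
    ch <- sample(names(seqlens), n, replace = TRUE)
    st <- vapply(ch, function(c0) sample.int(seqlens[[c0]] - maxLen, 1), 0)
    w <- sample.int(maxLen, n, replace = TRUE)
    GRanges(ch, IRanges(st, width = w))
}

## shared default-scale simulation, built once per test session
.simCache <- new.env(parent = emptyenv())
cachedSim <- function(key, cfg) {
    if (is.null(.simCache[[key]])) {
        sim <- suppressWarnings(simulateGenome(cfg))
        .simCache[[key]] <- list(cfg = cfg, sim = sim,
            meth = simulateMethylomes(cfg, sim))
    }
    .simCache[[key]]
}

smallSimConfig <- function(seed = 101, ...) {
    base <- list(seed = seed,
        chromLengths = c(chr1 = 1.5e6, chr2 = 1.5e6),
        nGenesPerChrom = 15L, nHmrShared = 10L, nHmrSperm = 5L,
        nHmrSomatic = 5L, nPmds = 3L, pmdLengthRange = c(1e5, 2e5),
        nSatBlocksPerChrom = 1L, satStartLength = 80000L,
        nRepeatsPerChrom = 60L, nYoungSinesNearTss = 8L,
        nDmcSites = 50L)
    do.call(simConfig, utils::modifyList(base, list(...)))
}
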