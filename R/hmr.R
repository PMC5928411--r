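## Per-chromosome prefix-count helpers: number of covered / hypomethylated
## CpGs with position in [a, b], given sorted positions.
countIn <- function(pos, csum, a, b) {
    hi <- findInterval(b, pos)
    lo <- findInterval(a - 1L, pos)
    csum[hi + 1L] - csum[lo + 1L]
}

#' Call hypomethylated regions (HMRs)
#'
#' Seed-and-extend sliding-window caller. Only CpGs with coverage >=
#' `minCoverage` are considered; a CpG is hypomethylated when its level is
#' below `hypoLevel` (default 20%). Seed windows of `seedSize` bp (default
#' 200) are placed at every `step` bp offset (default 50); a seed
#' qualifies when it holds at least 3 covered CpGs of which at least
#' `hypoFraction` (default 80%) are hypomethylated. Qualifying seeds are
#' extended rightward in `step` increments for as long as the window keeps
#' at least that fraction of hypomethylated CpGs (leftward extension is
#' subsumed by seeds starting earlier). Overlapping or book-ended calls
#' are merged, each merged call is trimmed to its outermost hypomethylated
#' CpGs, and calls with fewer than `minCpgs` covered CpGs (default 5) or a
#' hypomethylated fraction below `hypoFraction` after merging are
#' discarded, so every emitted HMR satisfies its own definition.
#'
#' @param sample A [Methylome-class], dyad-merged.
#' @param minCoverage Per-CpG coverage filter (default 5).
#' @param seedSize Seed window width in bp.
#' @param step Slide/extension increment in bp.
#' @param hypoLevel Per-CpG hypomethylation cutoff on the level.
#' @param hypoFraction Minimum fraction of hypomethylated CpGs.
#' @param minCpgs Minimum covered CpGs in a final call.
#' @param minSeedCpgs Minimum covered CpGs for a seed to qualify.
#' @param chromosomes Optional chromosome subset (e.g. the autosomes);
#'   `NULL` means every chromosome in the sample.
#' @return `GRanges` of HMRs with mcols `n_cpgs`, `n_hypo`, `mean_meth`,
#'   `sample_id`.
#' @export
callHmrs <- function(sample, minCoverage = 5L, seedSize = 200L, step = 50L,
                     hypoLevel = 0.20, hypoFraction = 0.80, minCpgs = 5L,
                     minSeedCpgs = 3L, chromosomes = NULL) {
    s <- methSites(sample, context = "CpG")
    if (!is.null(chromosomes))
        s <- s[as.character(seqnames(s)) %in% chromosomes]
    cov <- mcols(s)$n_meth + mcols(s)$n_unmeth
    s <- s[cov >= minCoverage]
    out <- GRanges(seqinfo = seqinfo(s))
    mcols(out) <- DataFrame(n_cpgs = integer(0), n_hypo = integer(0),
        mean_meth = numeric(0), sample_id = character(0))
    if (length(s) == 0L) return(out)
    lev <- mcols(s)$n_meth / (mcols(s)$n_meth + mcols(s)$n_unmeth)
    hypo <- lev < hypoLevel
    sl <- seqlengths(seqinfo(s))
    pieces <- list()
    for (chr in unique(as.character(seqnames(s)))) {
        on <- as.character(seqnames(s)) == chr
        pos <- start(s)[on]
        hy <- hypo[on]
        if (!any(hy)) next
        ccov <- c(0, cumsum(rep(1L, length(pos))))
        chyp <- c(0, cumsum(as.integer(hy)))
        maxpos <- if (!is.na(sl[chr])) sl[chr] else max(pos) + seedSize
        # candidate seed offsets: only near hypomethylated CpGs
        hp <- pos[hy]
        cand <- unique(unlist(lapply(hp, function(p)
            seq(max(0L, (p - seedSize) %/% step * step),
                (p %/% step) * step, by = step))))
        a <- as.integer(sort(cand)) + 1L          # 1-based window start
        b <- pmin(a + seedSize - 1L, maxpos)
        n <- countIn(pos, ccov, a, b)
        h <- countIn(pos, chyp, a, b)
        qual <- n >= minSeedCpgs & h / pmax(n, 1L) >= hypoFraction
        if (!any(qual)) next
        a <- a[qual]; b <- b[qual]
        # round-based rightward extension, vectorized over active seeds
        act <- b < maxpos
        while (any(act)) {
            b2 <- pmin(b[act] + step, maxpos)
            n2 <- countIn(pos, ccov, a[act], b2)
            h2 <- countIn(pos, chyp, a[act], b2)
            ok <- n2 > 0L & h2 / n2 >= hypoFraction
            bact <- b[act]
            bact[ok] <- b2[ok]
            b[act] <- bact
            act[act] <- ok & b2 < maxpos
        }
        pieces[[chr]] <- GRanges(chr, IRanges(a, b))
    }
    if (!length(pieces)) return(out)
    calls <- reduce(suppressWarnings(do.call(c, unname(pieces))))
    seqinfo(calls) <- seqinfo(s)
    # trim each merged call to its outermost hypomethylated CpGs
    hs <- s[hypo]
    hits <- findOverlaps(calls, hs, ignore.strand = TRUE)
    if (!length(hits)) return(out)
    qh <- queryHits(hits)
    p <- start(hs)[subjectHits(hits)]
    lo <- tapply(p, qh, min); hi <- tapply(p, qh, max)
    keep <- as.integer(names(lo))
    trimmed <- GRanges(seqnames(calls)[keep],
        IRanges(as.integer(lo), as.integer(hi)), seqinfo = seqinfo(s))
    # final statistics and definitional filter
    th <- findOverlaps(trimmed, s, ignore.strand = TRUE)
    ncp <- countOverlaps(trimmed, s, ignore.strand = TRUE)
    nhy <- countOverlaps(trimmed, hs, ignore.strand = TRUE)
    meth <- rowsum(as.numeric(mcols(s)$n_meth[subjectHits(th)]),
        queryHits(th))
    tot <- rowsum(as.numeric(
        (mcols(s)$n_meth + mcols(s)$n_unmeth)[subjectHits(th)]),
        queryHits(th))
    mm <- rep(NA_real_, length(trimmed))
    mm[as.integer(rownames(meth))] <- meth[, 1] / tot[, 1]
    ok <- ncp >= minCpgs & nhy / pmax(ncp, 1L) >= hypoFraction
    trimmed <- trimmed[ok]
    mcols(trimmed)$n_cpgs <- ncp[ok]
    mcols(trimmed)$n_hypo <- nhy[ok]
    mcols(trimmed)$mean_meth <- mm[ok]
    mcols(trimmed)$sample_id <- rep(sampleId(sample), length(trimmed))
    GenomicRanges::sort(trimmed, ignore.strand = TRUE)
}

#' Combine per-replicate HMR sets into a group-level set
#'
#' @param calls List of per-sample HMR `GRanges`.
#' @param method `"union"` (default; bp covered by any replicate),
#'   `"intersection"` (bp covered by every replicate) or `"majority"`
#'   (bp covered by more than half of the replicates).
#' @return Merged `GRanges`.
#' @export
combineHmrs <- function(calls, method = c("union", "intersection",
                                          "majority")) {
    method <- match.arg(method)
    grl <- lapply(calls, function(g) reduce(granges(g),
        ignore.strand = TRUE))
    if (method == "union")
        return(reduce(suppressWarnings(do.call(c, unname(grl)))))
    need <- if (method == "intersection") length(grl) else
        floor(length(grl) / 2) + 1L
    allg <- reduce(suppressWarnings(do.call(c, unname(grl))))
    lv <- seqlevels(allg)
    w <- setNames(rep(0L, length(lv)), lv)
    mx <- tapply(end(allg), as.character(seqnames(allg)), max)
    w[names(mx)] <- as.integer(mx)
    sl <- seqlengths(allg)
    w <- ifelse(!is.na(sl[lv]), sl[lv], w)
    cvg <- Reduce(`+`, lapply(grl, function(g) {
        seqlevels(g) <- lv
        GenomicRanges::coverage(g, width = as.list(w))
    }))
    rl <- IRanges::slice(cvg, lower = need, rangesOnly = TRUE)
    GRanges(rep(names(rl), lengths(rl)), unlist(rl, use.names = FALSE))
}

#' Compare two HMR sets at base-pair resolution
#'
#' Reports shared and set-specific bp (the Venn quantities), interval
#' counts, mean and median sizes, and a per-overlapping-pair
#' classification (`identical`, `nested` — one inside the other —, or
#' `partial`). The accounting identity shared + unique = total holds
#' exactly for both sets.
#'
#' @param setA,setB `GRanges` (merged internally).
#' @return List with `shared_bp`, `a_unique_bp`, `b_unique_bp`,
#'   `a_total_bp`, `b_total_bp`, `n_a`, `n_b`, size stats and the pair
#'   classification table.
#' @export
compareHmrSets <- function(setA, setB) {
    A <- reduce(granges(setA), ignore.strand = TRUE)
    B <- reduce(granges(setB), ignore.strand = TRUE)
    shared <- sum(as.numeric(width(GenomicRanges::intersect(A, B,
        ignore.strand = TRUE))))
    atot <- sum(as.numeric(width(A))); btot <- sum(as.numeric(width(B)))
    hits <- findOverlaps(A, B, ignore.strand = TRUE)
    cls <- character(length(hits))
    if (length(hits)) {
        a <- A[queryHits(hits)]; b <- B[subjectHits(hits)]
        same <- start(a) == start(b) & end(a) == end(b)
        bInA <- start(b) >= start(a) & end(b) <= end(a)
        aInB <- start(a) >= start(b) & end(a) <= end(b)
        cls[same] <- "identical"
        cls[!same & (bInA | aInB)] <- "nested"
        cls[!same & !bInA & !aInB] <- "partial"
    }
    list(shared_bp = shared, a_unique_bp = atot - shared,
        b_unique_bp = btot - shared, a_total_bp = atot, b_total_bp = btot,
        n_a = length(A), n_b = length(B),
        a_mean_size = if (length(A)) mean(width(A)) else NA_real_,
        a_median_size = if (length(A)) median(width(A)) else NA_real_,
        b_mean_size = if (length(B)) mean(width(B)) else NA_real_,
        b_median_size = if (length(B)) median(width(B)) else NA_real_,
        pair_classes = table(factor(cls,
            levels = c("identical", "nested", "partial"))))
}

#' Classify nesting of one HMR inside another
#'
#' The inner interval is `nested_both_sides` when it lies inside the
#' outer one with at least `minFlank` bp of margin on both edges,
#' `nested_one_side` when contained with margin on exactly one edge, and
#' `not_nested` otherwise. The margin (default 50 bp, one extension
#' step) distinguishes genuine nesting from coincident boundaries.
#'
#' @param inner,outer Single-interval `GRanges` on the same chromosome.
#' @param minFlank Minimum margin in bp.
#' @return One of `"nested_both_sides"`, `"nested_one_side"`,
#'   `"not_nested"`.
#' @export
classifyNesting <- function(inner, outer, minFlank = 50L) {
    stopifnot(length(inner) == 1L, length(outer) == 1L)
    if (as.character(seqnames(inner)) != as.character(seqnames(outer)))
        stop("intervals on different chromosomes")
    if (start(inner) < start(outer) || end(inner) > end(outer))
        return("not_nested")
    leftOk <- start(inner) - start(outer) >= minFlank
    rightOk <- end(outer) - end(inner) >= minFlank
    if (leftOk && rightOk) "nested_both_sides"
    else if (leftOk || rightOk) "nested_one_side"
    else "not_nested"
}

#' Strand-oriented methylation metaprofile around TSS
#'
#' Pools coverage-weighted methylation into fixed offset bins around
#' every TSS, oriented by gene strand (negative offsets upstream of the
#' TSS). Samples are pooled by group label.
#'
#' @param samples List of [Methylome-class] objects.
#' @param genes Gene `GRanges` with `tss` mcol and strand.
#' @param flank Half-window around the TSS in bp (default 2000).
#' @param bin Bin width in bp; must divide `flank`.
#' @param restrictTo Optional `GRanges`; only genes whose TSS falls
#'   inside it are profiled.
#' @param minCoverage Per-CpG coverage filter.
#' @return `data.frame` with columns `offset` (bin start), `group`,
#'   `mean_meth`, `n_cpgs`.
#' @export
tssMetaprofile <- function(samples, genes, flank = 2000L, bin = 100L,
                           restrictTo = NULL, minCoverage = 1L) {
    stopifnot(flank %% bin == 0)
    if (!is.null(restrictTo)) {
        tss <- GRanges(seqnames(genes), IRanges(mcols(genes)$tss, width = 1L))
        genes <- genes[overlapsAny(tss, restrictTo, ignore.strand = TRUE)]
        if (length(genes) == 0L)
            stop("no gene TSS falls in the restriction set")
    }
    tsspos <- mcols(genes)$tss
    win <- GRanges(seqnames(genes),
        IRanges(pmax(1L, tsspos - flank), tsspos + flank - 1L))
    neg <- as.character(strand(genes)) == "-"
    res <- list()
    for (sm in samples) {
        s <- methSites(sm, context = "CpG")
        cov <- mcols(s)$n_meth + mcols(s)$n_unmeth
        s <- s[cov >= minCoverage]
        hits <- findOverlaps(win, s, ignore.strand = TRUE)
        if (!length(hits)) next
        gi <- queryHits(hits); si <- subjectHits(hits)
        off <- start(s)[si] - tsspos[gi]
        off[neg[gi]] <- -off[neg[gi]]
        keep <- off >= -flank & off < flank
        off <- off[keep]; si <- si[keep]
        bidx <- floor(off / bin) * bin
        res[[sampleId(sm)]] <- data.frame(offset = bidx,
            meth = mcols(s)$n_meth[si],
            tot = mcols(s)$n_meth[si] + mcols(s)$n_unmeth[si],
            group = sampleGroup(sm))
    }
    if (!length(res)) stop("no CpG contributes to the profile")
    dd <- do.call(rbind, res)
    agg <- stats::aggregate(cbind(meth, tot, n = 1) ~ offset + group,
        data = dd, FUN = sum)
    data.frame(offset = agg$offset, group = agg$group,
        mean_meth = agg$meth / agg$tot, n_cpgs = agg$n)
}

#' Assign genes to HMR sets by TSS overlap
#'
#' A gene belongs to a group's set when its TSS point lies inside any
#' HMR of that group; set algebra yields shared and group-specific gene
#' lists.
#'
#' @param hmrsA,hmrsB Group-level HMR `GRanges`.
#' @param genes Gene `GRanges` with `gene_id` and `tss`.
#' @return List with `shared`, `a_specific`, `b_specific` gene-id
#'   vectors.
#' @export
hmrTssGeneSets <- function(hmrsA, hmrsB, genes) {
    tss <- GRanges(seqnames(genes), IRanges(mcols(genes)$tss, width = 1L))
    inA <- overlapsAny(tss, hmrsA, ignore.strand = TRUE)
    inB <- overlapsAny(tss, hmrsB, ignore.strand = TRUE)
    ids <- mcols(genes)$gene_id
    list(shared = ids[inA & inB], a_specific = ids[inA & !inB],
        b_specific = ids[!inA & inB])
}
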