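#' Window-level methylation track
#'
#' Tiles every chromosome into non-overlapping windows (default 20 kb; the
#' trailing partial window is kept) and computes the coverage-weighted
#' methylation level per window over CpGs with coverage >= `minCoverage`.
#' Windows with fewer than `minCpgs` covered CpGs are marked excluded
#' (`NA` label) — they later split the HMM sequence so that a PMD can
#' never bridge an uncovered gap.
#'
#' @param sample A [Methylome-class], dyad-merged.
#' @param genome A [MethGenome-class].
#' @param windowSize Window width in bp (default 20000).
#' @param minCoverage Per-CpG coverage filter (default 5).
#' @param minCpgs Minimum covered CpGs for a window to be usable
#'   (default 10).
#' @param chromosomes Chromosomes to tile (default: the autosomes, so
#'   spike-in and sex chromosomes stay out of the segmentation).
#' @return `GRanges` of windows with mcols `meth`, `total`, `n_cpgs`,
#'   `level`, `label` (`NA` until binarized / `NA` = excluded).
#' @export
windowMethylation <- function(sample, genome, windowSize = 20000L,
                              minCoverage = 5L, minCpgs = 10L,
                              chromosomes = autosomes(genome)) {
    stopifnot(windowSize > 0)
    win <- tileGenome(seqlengths(genome), tilewidth = windowSize,
        cut.last.tile.in.chrom = TRUE)
    win <- win[as.character(seqnames(win)) %in% chromosomes]
    s <- methSites(sample, context = "CpG")
    cov <- mcols(s)$n_meth + mcols(s)$n_unmeth
    s <- s[cov >= minCoverage]
    hits <- findOverlaps(win, s, ignore.strand = TRUE)
    meth <- total <- numeric(length(win))
    n <- countOverlaps(win, s, ignore.strand = TRUE)
    if (length(hits)) {
        ms <- rowsum(as.numeric(mcols(s)$n_meth[subjectHits(hits)]),
            queryHits(hits))
        cs <- rowsum(as.numeric(
            (mcols(s)$n_meth + mcols(s)$n_unmeth)[subjectHits(hits)]),
            queryHits(hits))
        idx <- as.integer(rownames(ms))
        meth[idx] <- ms[, 1]; total[idx] <- cs[, 1]
    }
    level <- ifelse(total > 0, meth / total, NA_real_)
    mcols(win)$meth <- meth
    mcols(win)$total <- total
    mcols(win)$n_cpgs <- n
    mcols(win)$level <- level
    mcols(win)$label <- NA_integer_
    mcols(win)$usable <- n >= minCpgs
    win
}

#' Binarize window methylation
#'
#' Windows with level strictly greater than `threshold` (default 60%) get
#' label 1 (methylated background); windows at or below get label 0
#' (candidate PMD windows). A level of exactly the threshold is assigned
#' 0 — a documented convention, since only strict `>` and `<` are defined
#' by the rule. Excluded windows keep an `NA` label.
#'
#' @param track Result of [windowMethylation()].
#' @param threshold Binarization threshold on the level (default 0.60).
#' @return The track with the `label` mcol filled in.
#' @export
binarizeWindows <- function(track, threshold = 0.60) {
    lab <- ifelse(mcols(track)$level > threshold, 1L, 0L)
    lab[!mcols(track)$usable] <- NA_integer_
    mcols(track)$label <- lab
    mcols(track)$threshold <- threshold
    track
}

#' HMM parameters for PMD segmentation
#'
#' Two hidden states, `PMD` and `background`, emitting the binary window
#' labels. Defaults: stay probability 0.9 in both states; P(label 0 | PMD)
#' = 0.9 and P(label 0 | background) = 0.1; uniform initial distribution.
#' With these values an isolated run of three or more 0-labelled windows
#' decodes as PMD while a single isolated 0 does not (verifiable by hand
#' Viterbi). Optional Baum-Welch refinement re-estimates transitions and
#' emissions before decoding (deterministic given the starting values).
#'
#' @param transition 2x2 row-stochastic matrix, rows/cols = (PMD,
#'   background).
#' @param emission 2x2 matrix `emission[state, label+1]` =
#'   P(label | state), rows = (PMD, background), cols = labels (0, 1).
#' @param init Initial state distribution.
#' @param train `"fixed"` (default) or `"baum_welch"`.
#' @param maxIter,tol Baum-Welch iteration cap and log-likelihood
#'   tolerance.
#' @return An object of class `HmmParams`.
#' @export
hmmParams <- function(transition = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                          byrow = TRUE),
                      emission = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                          byrow = TRUE),
                      init = c(0.5, 0.5),
                      train = c("fixed", "baum_welch"),
                      maxIter = 100L, tol = 1e-6) {
    train <- match.arg(train)
    stopifnot(all(abs(rowSums(transition) - 1) < 1e-8),
        all(emission > 0 & emission < 1), all(init > 0),
        abs(sum(init) - 1) < 1e-8)
    structure(list(transition = transition, emission = emission,
        init = init, train = train, maxIter = maxIter, tol = tol),
        class = "HmmParams")
}

## Viterbi decoding of a binary label vector; returns state path
## (1 = PMD, 2 = background). Ties are resolved toward background so
## that an ambiguous window never creates a PMD on its own.
viterbiBinary <- function(labels, p) {
    n <- length(labels)
    lt <- log(p$transition); le <- log(p$emission); li <- log(p$init)
    v <- matrix(-Inf, 2, n)
    bp <- matrix(1L, 2, n)
    v[, 1] <- li + le[, labels[1] + 1L]
    if (n > 1) for (t in 2:n) {
        for (s in 1:2) {
            cand <- v[, t - 1] + lt[, s]
            # prefer coming from background (state 2) on exact ties
            best <- if (cand[1] > cand[2]) 1L else 2L
            bp[s, t] <- best
            v[s, t] <- cand[best] + le[s, labels[t] + 1L]
        }
    }
    path <- integer(n)
    path[n] <- if (v[1, n] > v[2, n]) 1L else 2L
    if (n > 1) for (t in n:2) path[t - 1] <- bp[path[t], t]
    path
}

## One scaled forward-backward pass; returns updated params and loglik.
baumWelchStep <- function(labels, p) {
    n <- length(labels); A <- p$transition; B <- p$emission; pi0 <- p$init
    al <- matrix(0, 2, n); be <- matrix(0, 2, n); sc <- numeric(n)
    al[, 1] <- pi0 * B[, labels[1] + 1L]
    sc[1] <- sum(al[, 1]); al[, 1] <- al[, 1] / sc[1]
    if (n > 1) for (t in 2:n) {
        al[, t] <- (t(A) %*% al[, t - 1]) * B[, labels[t] + 1L]
        sc[t] <- sum(al[, t]); al[, t] <- al[, t] / sc[t]
    }
    be[, n] <- 1
    if (n > 1) for (t in (n - 1):1)
        be[, t] <- (A %*% (B[, labels[t + 1] + 1L] * be[, t + 1])) / sc[t + 1]
    g <- al * be; g <- sweep(g, 2, colSums(g), "/")
    xi <- matrix(0, 2, 2)
    if (n > 1) for (t in 1:(n - 1)) {
        x <- (al[, t] %o% (B[, labels[t + 1] + 1L] * be[, t + 1])) * A
        xi <- xi + x / sum(x)
    }
    Anew <- if (n > 1) xi / rowSums(xi) else A
    Bnew <- B
    for (k in 0:1) Bnew[, k + 1] <- rowSums(g[, labels == k, drop = FALSE])
    Bnew <- Bnew / rowSums(Bnew)
    eps <- 1e-6
    Anew <- pmin(pmax(Anew, eps), 1 - eps); Anew <- Anew / rowSums(Anew)
    Bnew <- pmin(pmax(Bnew, eps), 1 - eps); Bnew <- Bnew / rowSums(Bnew)
    initNew <- pmin(pmax(g[, 1], eps), 1 - eps)
    initNew <- initNew / sum(initNew)
    list(params = hmmParams(Anew, Bnew, initNew, train = p$train,
        maxIter = p$maxIter, tol = p$tol), loglik = sum(log(sc)))
}

#' Segment binarized windows into per-sample PMDs
#'
#' Runs Viterbi decoding of the two-state HMM over each chromosome's
#' binary label sequence. Excluded (low-coverage) windows split the
#' sequence: each maximal stretch of usable windows is decoded
#' independently, so no PMD spans an excluded window. Maximal runs of
#' PMD-state windows are stitched into intervals. With
#' `train = "baum_welch"` the parameters are refined on the concatenated
#' usable labels first (deterministic; capped iterations).
#'
#' @param track Result of [binarizeWindows()].
#' @param params An [hmmParams()] object.
#' @return `GRanges` of per-sample PMD intervals with mcols `n_windows`,
#'   `meth`, `total`, `level`.
#' @export
hmmSegment <- function(track, params = hmmParams()) {
    if (params$train == "baum_welch") {
        labs <- mcols(track)$label
        labs <- labs[!is.na(labs)]
        if (length(labs) > 1) {
            prev <- -Inf
            for (i in seq_len(params$maxIter)) {
                st <- baumWelchStep(labs, params)
                params <- st$params
                if (is.finite(prev) && abs(st$loglik - prev) < params$tol)
                    break
                prev <- st$loglik
            }
        }
    }
    lab <- mcols(track)$label
    chrom <- as.integer(seqnames(track))
    # segment id: contiguous usable windows on one chromosome
    usable <- !is.na(lab)
    brk <- c(TRUE, diff(chrom) != 0 | diff(as.integer(usable)) != 0)
    seg <- cumsum(brk)
    state <- rep(NA_integer_, length(track))
    for (sg in unique(seg[usable])) {
        idx <- which(seg == sg)
        state[idx] <- viterbiBinary(lab[idx], params)
    }
    inPmd <- !is.na(state) & state == 1L
    if (!any(inPmd)) {
        out <- GRanges(seqinfo = seqinfo(track))
        mcols(out)$n_windows <- integer(0); mcols(out)$meth <- numeric(0)
        mcols(out)$total <- numeric(0); mcols(out)$level <- numeric(0)
        return(out)
    }
    runbrk <- c(TRUE, diff(which(inPmd)) != 1 |
        diff(chrom[inPmd]) != 0)
    rid <- cumsum(runbrk)
    w <- which(inPmd)
    first <- w[!duplicated(rid)]
    last <- w[!duplicated(rid, fromLast = TRUE)]
    out <- GRanges(seqnames(track)[first],
        IRanges(start(track)[first], end(track)[last]),
        seqinfo = seqinfo(track))
    mcols(out)$n_windows <- as.integer(table(rid))
    mcols(out)$meth <- rowsum(mcols(track)$meth[w], rid)[, 1]
    mcols(out)$total <- rowsum(mcols(track)$total[w], rid)[, 1]
    mcols(out)$level <- mcols(out)$meth / pmax(mcols(out)$total, 1)
    out
}

#' Multi-sample consensus PMDs
#'
#' Counts, for every genome window, how many samples call it inside a
#' PMD, and keeps maximal runs of windows supported by at least
#' `minSamples` samples; runs shorter than `minWindows` windows are
#' dropped (defaults: at least 3 supporting samples, combined from at
#' least 3 windows). Support is counted per window, which makes the
#' consensus order-independent and monotone in the sample set.
#'
#' @param calls List of per-sample PMD `GRanges` (from [hmmSegment()]).
#' @param genome A [MethGenome-class].
#' @param windowSize Window width used for segmentation.
#' @param minSamples Minimum supporting samples per window.
#' @param minWindows Minimum run length in windows.
#' @param chromosomes Chromosomes considered (default autosomes).
#' @return `GRanges` of consensus PMDs with mcols `n_windows`, `support`
#'   (max per-window support in the run) and `samples` (comma-separated
#'   ids of samples overlapping the run).
#' @export
consensusPmds <- function(calls, genome, windowSize = 20000L,
                          minSamples = 3L, minWindows = 3L,
                          chromosomes = autosomes(genome)) {
    if (length(calls) < minSamples)
        stop("need at least ", minSamples, " samples, got ", length(calls))
    win <- tileGenome(seqlengths(genome), tilewidth = windowSize,
        cut.last.tile.in.chrom = TRUE)
    win <- win[as.character(seqnames(win)) %in% chromosomes]
    supp <- matrix(FALSE, length(win), length(calls))
    for (j in seq_along(calls))
        supp[, j] <- overlapsAny(win, calls[[j]], ignore.strand = TRUE)
    nsupp <- rowSums(supp)
    keep <- nsupp >= minSamples
    if (!any(keep)) {
        out <- GRanges(seqinfo = seqinfo(win))
        mcols(out)$n_windows <- integer(0); mcols(out)$support <- integer(0)
        mcols(out)$samples <- character(0)
        return(out)
    }
    chrom <- as.integer(seqnames(win))
    w <- which(keep)
    runbrk <- c(TRUE, diff(w) != 1 | diff(chrom[w]) != 0)
    rid <- cumsum(runbrk)
    len <- as.integer(table(rid))
    first <- w[!duplicated(rid)]
    last <- w[!duplicated(rid, fromLast = TRUE)]
    ok <- len >= minWindows
    out <- GRanges(seqnames(win)[first[ok]],
        IRanges(start(win)[first[ok]], end(win)[last[ok]]),
        seqinfo = seqinfo(win))
    mcols(out)$n_windows <- len[ok]
    mcols(out)$support <- vapply(which(ok), function(r)
        max(nsupp[w[rid == r]]), 0)
    ids <- names(calls)
    if (is.null(ids)) ids <- paste0("sample", seq_along(calls))
    mcols(out)$samples <- vapply(seq_along(out), function(i) {
        hit <- vapply(calls, function(g)
            any(overlapsAny(out[i], g, ignore.strand = TRUE)), TRUE)
        paste(ids[hit], collapse = ",")
    }, "")
    out
}

#' Satellite density of regions
#'
#' Total satellite bp overlapping each region divided by the region
#' length. Satellite records are merged first, so fragmented annotation
#' rows cannot inflate the density; the result is always in \[0, 1\].
#'
#' @param regions `GRanges`.
#' @param satellites `GRanges` of satellite elements.
#' @return Numeric vector of densities, one per region.
#' @export
satelliteDensity <- function(regions, satellites) {
    sat <- reduce(granges(satellites), ignore.strand = TRUE)
    hits <- suppressWarnings(findOverlaps(regions, sat,
        ignore.strand = TRUE))
    ov <- suppressWarnings(width(pintersect(
        granges(regions)[queryHits(hits)], sat[subjectHits(hits)])))
    d <- numeric(length(regions))
    if (length(hits)) {
        sums <- rowsum(as.numeric(ov), queryHits(hits))
        d[as.integer(rownames(sums))] <- sums[, 1]
    }
    d / width(regions)
}

#' Correlation between PMD satellite density and methylation
#'
#' For each sample, computes the Pearson correlation (with a two-sided
#' test) between the per-PMD satellite density and the per-PMD
#' coverage-weighted methylation level of that sample. In sperm this
#' relationship is strongly negative: satellite-dense domains are the
#' least methylated.
#'
#' @param pmds `GRanges` of PMDs (e.g. consensus).
#' @param samples List of [Methylome-class] objects.
#' @param satellites Satellite `GRanges`.
#' @param minCoverage Regional per-CpG coverage filter (default 5).
#' @return `data.frame` with one row per sample: `sample`, `r`, `p`,
#'   `n`; `r`/`p` are `NA` (flagged) when density or level has zero
#'   variance.
#' @export
pmdSatelliteCorrelation <- function(pmds, samples, satellites,
                                    minCoverage = 5L) {
    if (length(pmds) < 3L) stop("need at least 3 PMDs")
    dens <- satelliteDensity(pmds, satellites)
    res <- lapply(samples, function(sm) {
        s <- methSites(sm, context = "CpG")
        cov <- mcols(s)$n_meth + mcols(s)$n_unmeth
        s <- s[cov >= minCoverage]
        hits <- findOverlaps(pmds, s, ignore.strand = TRUE)
        meth <- tot <- numeric(length(pmds))
        if (length(hits)) {
            ms <- rowsum(as.numeric(mcols(s)$n_meth[subjectHits(hits)]),
                queryHits(hits))
            cs <- rowsum(as.numeric(
                (mcols(s)$n_meth + mcols(s)$n_unmeth)[subjectHits(hits)]),
                queryHits(hits))
            idx <- as.integer(rownames(ms))
            meth[idx] <- ms[, 1]; tot[idx] <- cs[, 1]
        }
        lev <- ifelse(tot > 0, meth / tot, NA_real_)
        ok <- !is.na(lev)
        if (sum(ok) < 3L || stats::sd(dens[ok]) == 0 ||
            stats::sd(lev[ok]) == 0)
            return(data.frame(sample = sampleId(sm), r = NA_real_,
                p = NA_real_, n = sum(ok)))
        ct <- cor.test(dens[ok], lev[ok], method = "pearson")
        data.frame(sample = sampleId(sm), r = unname(ct$estimate),
            p = ct$p.value, n = sum(ok))
    })
    do.call(rbind, res)
}

#' Differential methylation of genes inside PMDs
#'
#' For every gene body overlapping a PMD, the per-sample
#' coverage-weighted gene methylation level is computed (element
#' detection filters of [elementMethylation()] apply; genes failing the
#' filter in any sample are skipped). Group means are compared with a
#' two-sample Student t test and BH-adjusted. A gene is reported
#' significant when the absolute group difference exceeds
#' `diffThreshold` (default 20%) and q < `qThreshold` (default 0.01).
#' Genes are additionally flagged hypomethylated (group level < 20%) or
#' hypermethylated (> 80%) per group.
#'
#' @param pmds `GRanges` of PMDs.
#' @param genes Gene `GRanges` with `gene_id`.
#' @param samples List of [Methylome-class] objects spanning two groups.
#' @param cpgIndex Optional `GRanges` of all CpG positions.
#' @param groups Length-2 character of group labels (difference =
#'   groups\[1\] - groups\[2\]); defaults to the labels present.
#' @param minCoverage Regional coverage filter.
#' @param diffThreshold,qThreshold Reporting thresholds.
#' @return `data.frame` per tested gene with per-group mean levels,
#'   difference, p, q, `significant`, `hypo_a/b`, `hyper_a/b`.
#' @export
pmdGeneDiff <- function(pmds, genes, samples, cpgIndex = NULL,
                        groups = NULL, minCoverage = 5L,
                        diffThreshold = 0.20, qThreshold = 0.01) {
    grp <- vapply(samples, sampleGroup, "")
    if (is.null(groups)) groups <- unique(grp)
    if (length(groups) != 2L) stop("need exactly two groups")
    if (sum(grp == groups[1]) < 2L || sum(grp == groups[2]) < 2L)
        stop("need >= 2 replicates per group")
    g <- genes[overlapsAny(genes, pmds, ignore.strand = TRUE)]
    if (length(g) == 0L)
        return(data.frame(gene_id = character(0)))
    lev <- vapply(samples, function(sm)
        mcols(elementMethylation(sm, g, cpgIndex = cpgIndex,
            minCoverage = minCoverage))$level, numeric(length(g)))
    lev <- matrix(lev, nrow = length(g))
    ok <- rowSums(is.na(lev)) == 0L
    g <- g[ok]; lev <- lev[ok, , drop = FALSE]
    if (length(g) == 0L) return(data.frame(gene_id = character(0)))
    a <- grp == groups[1]; b <- grp == groups[2]
    stat <- t(apply(lev, 1, function(x) {
        xa <- x[a]; xb <- x[b]
        if (sd(xa) == 0 && sd(xb) == 0) {
            p <- if (mean(xa) == mean(xb)) 1 else 0
            return(c(mean(xa), mean(xb), p))
        }
        c(mean(xa), mean(xb),
            t.test(xa, xb, var.equal = TRUE)$p.value)
    }))
    q <- p.adjust(stat[, 3], method = "BH")
    diff <- stat[, 1] - stat[, 2]
    out <- data.frame(gene_id = mcols(g)$gene_id,
        chrom = as.character(seqnames(g)), start = start(g), end = end(g),
        level_a = stat[, 1], level_b = stat[, 2], diff = diff,
        p = stat[, 3], q = q,
        significant = abs(diff) > diffThreshold & q < qThreshold,
        hypo_a = stat[, 1] < 0.20, hyper_a = stat[, 1] > 0.80,
        hypo_b = stat[, 2] < 0.20, hyper_b = stat[, 2] > 0.80)
    names(out)[5:6] <- paste0("level_", groups)
    names(out)[11:14] <- c(paste0(c("hypo_", "hyper_"), groups[1]),
        paste0(c("hypo_", "hyper_"), groups[2]))
    attr(out, "groups") <- groups
    out
}
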