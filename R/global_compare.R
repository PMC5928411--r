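#' Build the common-CpG matrix across samples
#'
#' Site-level comparisons use only CpGs covered deeply in *every* sample:
#' the intersection of sites with coverage >= `siteMinCoverage` (default
#' 10) across all samples, optionally restricted to autosomes. The result
#' is a `RangedSummarizedExperiment` with assays `meth`, `cov` and `level`
#' and per-sample `group` labels in `colData`.
#'
#' @param samples List of [Methylome-class] objects (dyad-merged CpGs
#'   recommended).
#' @param siteMinCoverage Per-site minimum coverage in every sample.
#' @param genome Optional [MethGenome-class]; required when
#'   `autosomesOnly = TRUE`.
#' @param autosomesOnly Restrict to autosomes.
#' @return A `RangedSummarizedExperiment`.
#' @export
buildCommonMatrix <- function(samples, siteMinCoverage = 10L, genome = NULL,
                              autosomesOnly = FALSE) {
    if (length(samples) < 2L) stop("need at least 2 samples")
    keyed <- lapply(samples, function(sm) {
        s <- methSites(sm, context = "CpG")
        if (autosomesOnly) {
            if (is.null(genome)) stop("autosomesOnly requires a genome")
            s <- s[as.character(seqnames(s)) %in% autosomes(genome)]
        }
        cov <- mcols(s)$n_meth + mcols(s)$n_unmeth
        s <- s[cov >= siteMinCoverage]
        if (length(s) == 0L)
            stop("sample ", sampleId(sm), " has no site passing coverage ",
                siteMinCoverage)
        setNames(list(s), NULL)[[1]]
    })
    keys <- lapply(keyed, function(s)
        paste0(as.character(seqnames(s)), ":", start(s)))
    common <- Reduce(intersect, keys)
    if (length(common) == 0L)
        stop("no common site passes coverage ", siteMinCoverage,
            " in all samples; lower the threshold")
    ord <- NULL
    meth <- cov <- matrix(0L, nrow = length(common), ncol = length(samples))
    for (j in seq_along(keyed)) {
        idx <- match(common, keys[[j]])
        s <- keyed[[j]][idx]
        if (j == 1L) ord <- s
        meth[, j] <- mcols(s)$n_meth
        cov[, j] <- mcols(s)$n_meth + mcols(s)$n_unmeth
    }
    o <- order(as.integer(seqnames(ord)), start(ord))
    ord <- granges(ord)[o]; meth <- meth[o, , drop = FALSE]
    cov <- cov[o, , drop = FALSE]
    ids <- vapply(samples, sampleId, "")
    colnames(meth) <- colnames(cov) <- ids
    SummarizedExperiment::SummarizedExperiment(
        assays = list(meth = meth, cov = cov, level = meth / cov),
        rowRanges = ord,
        colData = DataFrame(sample_id = ids,
            group = vapply(samples, sampleGroup, ""), row.names = ids))
}

#' Pairwise sample correlation over common CpGs
#'
#' Pearson (default) or Spearman correlation of the per-site methylation
#' levels for every sample pair. Zero-variance samples yield `NA` entries
#' and a warning; the diagonal is 1.
#'
#' @param se Result of [buildCommonMatrix()].
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwiseCorrelation <- function(se, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    lev <- SummarizedExperiment::assay(se, "level")
    if (nrow(lev) < 2L) stop("need >= 2 common sites")
    v <- apply(lev, 2, stats::var)
    r <- suppressWarnings(cor(lev, method = method))
    if (any(v == 0)) {
        warning("zero-variance sample(s): ",
            paste(colnames(lev)[v == 0], collapse = ", "))
        r[v == 0, ] <- NA; r[, v == 0] <- NA
    }
    diag(r) <- 1
    r
}

## Two-sided exact conditional p-value for a 2x2 table, conditioning on
## both margins (hypergeometric null). Tables as likely or less likely
## than the observed one (relative tolerance 1 + 1e-7, matching the
## convention of stats::fisher.test) contribute to p.
twoSidedHyperP <- function(m1, u1, m2, u2) {
    M <- m1 + m2; n1 <- m1 + u1; N <- m1 + u1 + m2 + u2
    lo <- max(0L, n1 - (N - M)); hi <- min(n1, M)
    d <- dhyper(lo:hi, M, N - M, n1)
    sum(d[d <= d[m1 - lo + 1L] * (1 + 1e-7)])
}

#' Call differentially methylated cytosines (DMCs)
#'
#' Counts are pooled within each group at every common site and compared
#' by a two-sided exact conditional test on the 2x2 table
#' (methylated/unmethylated x group), with Benjamini-Hochberg adjusted
#' q-values. A site is reported as a DMC when the pooled-level difference
#' exceeds `diffThreshold` in absolute value and q < `qThreshold`
#' (defaults: difference > 30% and q < 0.01). Sites with zero pooled
#' coverage in either group are skipped and counted in the `skipped`
#' attribute.
#'
#' @param se Result of [buildCommonMatrix()].
#' @param groups Length-2 character: the two group labels to contrast;
#'   the reported difference is level(groups\[1\]) - level(groups\[2\]).
#'   Defaults to the two labels in `colData(se)$group`.
#' @param diffThreshold Minimum absolute pooled-level difference.
#' @param qThreshold BH q-value cutoff.
#' @return `data.frame` with one row per tested site: chrom, pos, pooled
#'   group levels, difference, p, q and the logical `dmc` flag. The
#'   thresholds and skipped-site count are attached as attributes.
#' @export
callDmcs <- function(se, groups = NULL, diffThreshold = 0.30,
                     qThreshold = 0.01) {
    grp <- SummarizedExperiment::colData(se)$group
    if (is.null(groups)) groups <- unique(grp)
    if (length(groups) != 2L || !all(groups %in% grp))
        stop("need exactly two groups present in the data")
    meth <- SummarizedExperiment::assay(se, "meth")
    cov <- SummarizedExperiment::assay(se, "cov")
    a <- grp == groups[1]; b <- grp == groups[2]
    if (!any(a) || !any(b)) stop("both groups must be non-empty")
    m1 <- rowSums(meth[, a, drop = FALSE]); c1 <- rowSums(cov[, a, drop = FALSE])
    m2 <- rowSums(meth[, b, drop = FALSE]); c2 <- rowSums(cov[, b, drop = FALSE])
    ok <- c1 > 0 & c2 > 0
    nskip <- sum(!ok)
    if (nskip) message("callDmcs: skipped ", nskip,
        " sites with zero pooled coverage in a group")
    rr <- SummarizedExperiment::rowRanges(se)[ok]
    m1 <- m1[ok]; c1 <- c1[ok]; m2 <- m2[ok]; c2 <- c2[ok]
    p <- vapply(seq_along(m1), function(i)
        twoSidedHyperP(m1[i], c1[i] - m1[i], m2[i], c2[i] - m2[i]), 0)
    q <- p.adjust(p, method = "BH")
    l1 <- m1 / c1; l2 <- m2 / c2
    out <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
        level_a = l1, level_b = l2, diff = l1 - l2, p = p, q = q,
        dmc = abs(l1 - l2) > diffThreshold & q < qThreshold)
    names(out)[3:4] <- paste0("level_", groups)
    attr(out, "groups") <- groups
    attr(out, "thresholds") <- c(diff = diffThreshold, q = qThreshold)
    attr(out, "skipped") <- nskip
    attr(out, "test") <- "pooled two-sided exact conditional (hypergeometric), BH"
    out
}

#' Per-element methylation over an annotation track
#'
#' For each element (gene body, promoter, CGI, repeat...) the
#' coverage-weighted methylation level is computed over the CpGs with
#' coverage >= `minCoverage` inside the element. Elements are flagged
#' `pass = FALSE` when too little of their CpG complement is detected:
#' elements with more than 50 CpGs need a detection rate of at least 10%,
#' elements with at most 50 CpGs need at least 5 CpGs detected. Failing
#' elements carry `NA` levels.
#'
#' @param sample A [Methylome-class] (dyad-merged CpGs recommended).
#' @param track `GRanges` of elements.
#' @param cpgIndex Optional `GRanges` of all CpG positions in the genome;
#'   when supplied, the per-element total CpG count comes from it,
#'   otherwise from the sample's site list (any coverage).
#' @param minCoverage Per-CpG coverage filter (default 5).
#' @return `track` with added mcols `level`, `n_detected`, `n_total`,
#'   `pass`.
#' @export
elementMethylation <- function(sample, track, cpgIndex = NULL,
                               minCoverage = 5L) {
    s <- methSites(sample, context = "CpG")
    cov <- mcols(s)$n_meth + mcols(s)$n_unmeth
    det <- s[cov >= minCoverage]
    idx <- if (is.null(cpgIndex)) granges(s) else granges(cpgIndex)
    n_total <- countOverlaps(track, idx, ignore.strand = TRUE)
    n_det <- countOverlaps(track, det, ignore.strand = TRUE)
    hits <- findOverlaps(track, det, ignore.strand = TRUE)
    msum <- rowsum(as.numeric(mcols(det)$n_meth[subjectHits(hits)]),
        queryHits(hits))
    csum <- rowsum(as.numeric(
        mcols(det)$n_meth + mcols(det)$n_unmeth)[subjectHits(hits)],
        queryHits(hits))
    level <- rep(NA_real_, length(track))
    level[as.integer(rownames(msum))] <- msum[, 1] / csum[, 1]
    pass <- ifelse(n_total > 50L, n_det / pmax(n_total, 1L) >= 0.10,
        n_det >= 5L)
    level[!pass] <- NA_real_
    out <- track
    mcols(out)$level <- level
    mcols(out)$n_detected <- n_det
    mcols(out)$n_total <- n_total
    mcols(out)$pass <- pass
    out
}

#' Promoters from a gene track
#'
#' Promoters are the +/- `flank` bp (default 1000) around each
#' transcription start site, clipped to chromosome bounds. The TSS is the
#' transcript start for `+` strand genes and the transcript end for `-`
#' strand genes (the `tss` mcol set by [readGenePred()] or the simulator).
#'
#' @param genes `GRanges` with `tss` mcol and strand.
#' @param genome Optional [MethGenome-class] used for clipping bounds.
#' @param flank Half-width in bp.
#' @return `GRanges` of promoters carrying `gene_id` and `tss`.
#' @export
promotersFromGenes <- function(genes, genome = NULL, flank = 1000L) {
    tss <- mcols(genes)$tss
    if (is.null(tss)) stop("gene track must carry a 'tss' mcol")
    sl <- if (!is.null(genome)) seqlengths(genome) else
        seqlengths(seqinfo(genes))
    lens <- sl[as.character(seqnames(genes))]
    if (any(!is.na(lens) & (tss < 1 | tss > lens)))
        stop("TSS outside chromosome bounds")
    # +/- flank around the TSS boundary; on the minus strand the TSS is
    # the rightmost transcribed base, so the window shifts by one to
    # stay strand-symmetric
    neg <- as.character(strand(genes)) == "-"
    start <- ifelse(neg, tss - flank + 1L, tss - flank)
    end <- ifelse(neg, tss + flank, tss + flank - 1L)
    start <- pmax(1L, start)
    if (any(!is.na(lens))) end <- pmin(end, ifelse(is.na(lens), end, lens))
    out <- GRanges(seqnames(genes), IRanges(start, end),
        strand = strand(genes))
    if (!is.null(genome)) seqinfo(out) <- seqinfo(genome)
    mcols(out)$gene_id <- mcols(genes)$gene_id
    mcols(out)$tss <- tss
    out
}
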