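#' Observed/expected feature enrichment in a region set
#'
#' Densities are base-pair based: observed = feature bp inside the
#' regions per region bp; expected = feature bp on the autosomes per
#' autosome bp; the ratio O/E measures enrichment. Feature records are
#' merged first, so the statistic is invariant to annotation
#' fragmentation. With `autosomesOnly = TRUE` (default) both regions and
#' features are clipped to the autosomes before counting.
#'
#' @param regions `GRanges` region set (e.g. consensus PMDs).
#' @param features `GRanges` of one feature class, or a named list of
#'   such for a multi-row result.
#' @param genome A [MethGenome-class].
#' @param autosomesOnly Restrict to autosomes.
#' @return `data.frame` with `feature`, `observed`, `expected`,
#'   `oe_ratio` (NA, flagged via `expected = 0`, when the feature is
#'   absent from the autosomes).
#' @export
oeEnrichment <- function(regions, features, genome, autosomesOnly = TRUE) {
    if (!is.list(features)) features <- list(feature = features)
    auto <- GRanges(autosomes(genome),
        IRanges(1L, seqlengths(genome)[autosomes(genome)]))
    denomSpace <- if (autosomesOnly) auto else
        GRanges(seqlevels(genome), IRanges(1L, seqlengths(genome)))
    reg <- reduce(granges(regions), ignore.strand = TRUE)
    if (autosomesOnly)
        reg <- suppressWarnings(GenomicRanges::intersect(reg, auto,
            ignore.strand = TRUE))
    regBp <- sum(as.numeric(width(reg)))
    if (regBp == 0) stop("regions have zero total length")
    spaceBp <- sum(as.numeric(width(denomSpace)))
    out <- lapply(names(features), function(nm) {
        f <- reduce(granges(features[[nm]]), ignore.strand = TRUE)
        f <- suppressWarnings(GenomicRanges::intersect(f, denomSpace,
            ignore.strand = TRUE))
        obs <- sum(as.numeric(width(suppressWarnings(
            GenomicRanges::intersect(f, reg,
                ignore.strand = TRUE))))) / regBp
        expd <- sum(as.numeric(width(f))) / spaceBp
        data.frame(feature = nm, observed = obs, expected = expd,
            oe_ratio = if (expd > 0) obs / expd else NA_real_)
    })
    do.call(rbind, out)
}

#' Fraction of query intervals overlapping a subject track
#'
#' Counts query intervals with at least `minOverlap` bp of overlap
#' against the merged subject set.
#'
#' @param query,subject `GRanges`.
#' @param minOverlap Minimum overlap in bp.
#' @return List with `n_query`, `n_overlapping`, `fraction`,
#'   `overlap_bp`.
#' @export
overlapFraction <- function(query, subject, minOverlap = 1L) {
    if (length(query) == 0L) stop("empty query set")
    sub <- reduce(granges(subject), ignore.strand = TRUE)
    hits <- findOverlaps(query, sub, minoverlap = minOverlap,
        ignore.strand = TRUE)
    n_over <- length(unique(queryHits(hits)))
    ovbp <- sum(as.numeric(width(GenomicRanges::intersect(
        reduce(granges(query), ignore.strand = TRUE), sub,
        ignore.strand = TRUE))))
    list(n_query = length(query), n_overlapping = n_over,
        fraction = n_over / length(query), overlap_bp = ovbp)
}

#' Two-group comparison of overlap fractions
#'
#' Student two-sample two-sided t test on per-sample overlap fractions
#' (e.g. nucleosome-peak overlap with each sample's HMRs, sperm vs
#' somatic). When both groups are constant and equal the convention
#' t = 0, p = 1 is returned with `degenerate = TRUE`.
#'
#' @param fractionsA,fractionsB Numeric vectors (>= 2 values each).
#' @return List with `t`, `p`, `mean_a`, `mean_b`, `degenerate`.
#' @export
overlapEnrichmentTest <- function(fractionsA, fractionsB) {
    if (length(fractionsA) < 2L || length(fractionsB) < 2L)
        stop("need at least 2 values per group")
    if (sd(fractionsA) == 0 && sd(fractionsB) == 0) {
        eq <- mean(fractionsA) == mean(fractionsB)
        return(list(t = if (eq) 0 else Inf, p = if (eq) 1 else 0,
            mean_a = mean(fractionsA), mean_b = mean(fractionsB),
            degenerate = TRUE))
    }
    tt <- t.test(fractionsA, fractionsB, var.equal = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value,
        mean_a = mean(fractionsA), mean_b = mean(fractionsB),
        degenerate = FALSE)
}

#' TSS-proximity enrichment of elements
#'
#' Fold enrichment of elements near transcription start sites: the
#' fraction of elements overlapping any TSS +/- `flank` window, divided
#' by the fraction of autosomal bp those windows occupy (the
#' uniform-placement expectation).
#'
#' @param elements `GRanges` of elements (e.g. hypomethylated repeats).
#' @param genes Gene `GRanges` with `tss`.
#' @param genome A [MethGenome-class].
#' @param flank Half-window in bp (default 2000).
#' @return List with `fold`, `observed_fraction`, `expected_fraction`,
#'   `n_elements`.
#' @export
tssProximityEnrichment <- function(elements, genes, genome,
                                   flank = 2000L) {
    if (length(elements) == 0L) stop("no elements")
    auto <- GRanges(autosomes(genome),
        IRanges(1L, seqlengths(genome)[autosomes(genome)]))
    tsspos <- mcols(genes)$tss
    win <- GRanges(seqnames(genes),
        IRanges(pmax(1L, tsspos - flank), tsspos + flank - 1L))
    win <- GenomicRanges::intersect(reduce(win, ignore.strand = TRUE),
        auto, ignore.strand = TRUE)
    el <- elements[as.character(seqnames(elements)) %in% autosomes(genome)]
    if (length(el) == 0L) stop("no elements on autosomes")
    obs <- mean(overlapsAny(el, win, ignore.strand = TRUE))
    expd <- sum(as.numeric(width(win))) / sum(as.numeric(width(auto)))
    list(fold = if (expd > 0) obs / expd else NA_real_,
        observed_fraction = obs, expected_fraction = expd,
        n_elements = length(el))
}
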