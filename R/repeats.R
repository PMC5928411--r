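#' Extract repeat elements hypomethylated in at least one sample
#'
#' Element methylation is computed per sample with
#' [elementMethylation()] (coverage and detection-rate filters apply).
#' An element joins the set when its level is below `hypoLevel`
#' (default 20%) in at least one sample that passes the detection
#' filter. Per-sample levels, the number of hypomethylated samples, the
#' cross-sample variance, CpG density (CpGs per bp, from the site
#' index) and an optional CGI-proximity flag are annotated.
#'
#' @param track Repeat `GRanges` (mcols `name`, `class`, `family`,
#'   `milliDiv` as from [readRepeatMaskerOut()]).
#' @param samples List of [Methylome-class] objects.
#' @param cpgIndex Optional `GRanges` of all CpG positions.
#' @param cgis Optional CGI `GRanges` for the proximity flag.
#' @param hypoLevel Hypomethylation cutoff.
#' @param minCoverage Regional per-CpG coverage filter.
#' @param cgiFlank Distance (bp) within which an element counts as near
#'   a CGI.
#' @return `GRanges` subset of `track` with added mcols
#'   `level.<sample>`, `n_hypo_samples`, `level_var`, `cg_density` and
#'   (when `cgis` given) `near_cgi`.
#' @export
extractHypoElements <- function(track, samples, cpgIndex = NULL,
                                cgis = NULL, hypoLevel = 0.20,
                                minCoverage = 5L, cgiFlank = 2000L) {
    levs <- vapply(samples, function(sm)
        mcols(elementMethylation(sm, track, cpgIndex = cpgIndex,
            minCoverage = minCoverage))$level, numeric(length(track)))
    levs <- matrix(levs, nrow = length(track),
        dimnames = list(NULL, vapply(samples, sampleId, "")))
    nhypo <- rowSums(levs < hypoLevel, na.rm = TRUE)
    allFail <- rowSums(!is.na(levs)) == 0L
    if (any(allFail))
        message("extractHypoElements: ", sum(allFail),
            " elements failed the detection filter in every sample")
    keep <- nhypo >= 1L & !allFail
    out <- track[keep]
    lv <- levs[keep, , drop = FALSE]
    for (j in colnames(lv))
        mcols(out)[[paste0("level.", j)]] <- lv[, j]
    mcols(out)$n_hypo_samples <- nhypo[keep]
    mcols(out)$level_var <- apply(lv, 1, stats::var, na.rm = TRUE)
    if (!is.null(cpgIndex))
        mcols(out)$cg_density <- countOverlaps(out, cpgIndex,
            ignore.strand = TRUE) / width(out)
    if (!is.null(cgis)) {
        near <- suppressWarnings(GenomicRanges::resize(granges(out),
            width(out) + 2L * cgiFlank, fix = "center"))
        near <- IRanges::trim(near)
        mcols(out)$near_cgi <- overlapsAny(near, cgis,
            ignore.strand = TRUE)
    }
    out
}

#' Divergence (age) versus methylation for repeat elements
#'
#' Bins elements by milliDiv (RepeatMasker substitutions per 1000 bp
#' against the family consensus, a proxy for element age), reports the
#' mean element methylation per bin, and the Pearson correlation
#' between per-element milliDiv and level.
#'
#' @param track Repeat `GRanges` carrying `milliDiv` and a `level` mcol
#'   (e.g. from [elementMethylation()]).
#' @param bins Numeric vector of milliDiv bin edges.
#' @return List with `table` (bin, n, mean_level), `r`, `p` and
#'   `low_n` flag (TRUE when fewer than 10 elements enter the
#'   correlation). `r` is `NA` when all elements fall in one bin
#'   carries no spread.
#' @export
divergenceMethylation <- function(track, bins = seq(0, 400, by = 40)) {
    md <- mcols(track)$milliDiv
    lev <- mcols(track)$level
    ok <- !is.na(md) & !is.na(lev)
    md <- md[ok]; lev <- lev[ok]
    if (!length(md)) stop("no element with both milliDiv and level")
    bidx <- cut(md, breaks = bins, include.lowest = TRUE, right = FALSE)
    means <- tapply(lev, bidx, mean)
    tab <- data.frame(bin = levels(bidx), n = as.integer(table(bidx)),
        mean_level = as.numeric(means))
    nonEmpty <- sum(tab$n > 0)
    r <- p <- NA_real_
    # with all elements in a single bin the correlation is skipped and
    # only the binned table is reported
    if (nonEmpty >= 2L && length(md) >= 3L && sd(md) > 0 && sd(lev) > 0) {
        ct <- cor.test(md, lev, method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
    }
    list(table = tab, r = r, p = p, n = length(md),
        low_n = length(md) < 10L)
}

#' Select young hypomethylated SINE elements
#'
#' From a hypomethylated-element set, keeps elements of the given class
#' (default SINE) whose divergence is below `maxDivergence`. Divergence
#' is interpreted as milliDiv by default (`unit = "milliDiv"`, so 50
#' means <5% substitutions — the "young" end of the distribution);
#' `unit = "percent"` interprets the threshold as percent substitutions
#' instead. The repeat-name composition (fraction of the selection per
#' name, e.g. the BOV-A2 share) and, when present, the
#' consensus-length-fraction distribution are reported.
#'
#' @param hypoSet `GRanges` from [extractHypoElements()].
#' @param family Repeat class to keep.
#' @param maxDivergence Strict upper bound on divergence.
#' @param unit `"milliDiv"` or `"percent"`.
#' @param nameFilter Optional repeat-name filter applied after
#'   selection.
#' @return List with `elements` (`GRanges`), `composition` (named
#'   fractions per repeat name) and `consensus_fraction` (numeric or
#'   NULL).
#' @export
selectYoungSine <- function(hypoSet, family = "SINE", maxDivergence = 50,
                            unit = c("milliDiv", "percent"),
                            nameFilter = NULL) {
    unit <- match.arg(unit)
    cut <- if (unit == "percent") maxDivergence * 10 else maxDivergence
    sel <- hypoSet[mcols(hypoSet)$class == family &
        !is.na(mcols(hypoSet)$milliDiv) & mcols(hypoSet)$milliDiv < cut]
    comp <- if (length(sel))
        sort(table(mcols(sel)$name) / length(sel), decreasing = TRUE)
    else table(character(0))
    if (!is.null(nameFilter)) sel <- sel[mcols(sel)$name %in% nameFilter]
    cf <- mcols(sel)$consensus_fraction
    list(elements = sel, composition = comp,
        consensus_fraction = if (is.null(cf)) NULL else cf,
        selection = list(family = family, maxDivergence = maxDivergence,
            unit = unit))
}

#' Genes with a candidate element near their TSS
#'
#' Pairs every gene with every element overlapping its TSS +/- `flank`
#' window (default 2 kb). One row per (gene, element) pair; per-sample
#' element levels travel along when present.
#'
#' @param elements `GRanges` of elements (e.g. young hypomethylated
#'   SINEs).
#' @param genes Gene `GRanges` with `gene_id` and `tss`.
#' @param flank Half-window in bp.
#' @return `data.frame` with gene, element coordinates, name and any
#'   `level.*` columns.
#' @export
promoterProximalRepeatGenes <- function(elements, genes, flank = 2000L) {
    tsspos <- mcols(genes)$tss
    win <- GRanges(seqnames(genes),
        IRanges(pmax(1L, tsspos - flank), tsspos + flank - 1L))
    hits <- findOverlaps(win, elements, ignore.strand = TRUE)
    if (!length(hits))
        return(data.frame(gene_id = character(0), element = character(0),
            chrom = character(0), start = integer(0), end = integer(0)))
    gi <- queryHits(hits); ei <- subjectHits(hits)
    out <- data.frame(gene_id = mcols(genes)$gene_id[gi],
        element = if (!is.null(mcols(elements)$name))
            mcols(elements)$name[ei] else NA_character_,
        chrom = as.character(seqnames(elements))[ei],
        start = start(elements)[ei], end = end(elements)[ei])
    mc <- mcols(elements)
    for (cn in grep("^level\\.", colnames(mc), value = TRUE))
        out[[cn]] <- mc[[cn]][ei]
    out
}
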