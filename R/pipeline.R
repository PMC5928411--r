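#' Default analysis thresholds
#'
#' All tunable thresholds of the pipeline in one list: site-level
#' comparisons use CpGs covered >= 10x in every sample, region-level
#' summaries use CpGs covered >= 5x, DMCs require a pooled-level
#' difference > 30% at q < 0.01, PMD segmentation uses 20-kb windows
#' binarized at 60% with a consensus of >= 3 samples over >= 3 windows,
#' HMRs use 200-bp seeds extended in 50-bp steps with >= 80%
#' hypomethylated (< 20%) CpGs and >= 5 covered CpGs, genes in PMDs are
#' reported at > 20% difference and q < 0.01, TSS windows span +/- 2 kb
#' and young SINEs are selected below milliDiv 50.
#'
#' @return Named list of thresholds.
#' @export
defaultThresholds <- function() {
    list(site_min_coverage = 10L, region_min_coverage = 5L,
        dmc_diff = 0.30, dmc_q = 0.01,
        pmd_window = 20000L, pmd_threshold = 0.60, pmd_min_samples = 3L,
        pmd_min_windows = 3L, pmd_window_min_cpgs = 10L,
        hmr_seed = 200L, hmr_step = 50L, hmr_hypo_level = 0.20,
        hmr_hypo_fraction = 0.80, hmr_min_cpgs = 5L,
        gene_diff = 0.20, gene_q = 0.01,
        tss_flank = 2000L, sine_max_divergence = 50)
}

writeTsv <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full comparison pipeline
#'
#' Orchestrates the stages end to end on a set of samples from two
#' groups: global comparison (common-CpG matrix, pairwise correlation,
#' DMCs), PMD segmentation of the PMD-carrier group with consensus and
#' satellite/gene statistics, HMR calling with group comparison and TSS
#' gene sets, observed/expected feature enrichment in the consensus
#' PMDs, and repeat hypomethylation analysis. Stages whose annotation
#' input is missing are skipped with a logged reason. All thresholds
#' and skipped stages are echoed into `manifest.json`, which fully
#' determines the outputs: two runs with equal manifests and inputs
#' give equal results.
#'
#' @param samples List of [Methylome-class] objects (raw; dyads are
#'   merged internally).
#' @param genome A [MethGenome-class].
#' @param annotations List with optional elements `genes`, `cgis`,
#'   `satellites`, `repeats`, `nucleosomes`, `cpgIndex` (`GRanges`).
#' @param outDir Output directory.
#' @param thresholds See [defaultThresholds()]; partial overrides
#'   allowed.
#' @param pmdGroup Group whose samples are segmented for PMDs.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(samples, genome, annotations = list(),
                        outDir, thresholds = list(),
                        pmdGroup = "sperm") {
    th <- utils::modifyList(defaultThresholds(), thresholds)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    skipped <- list()
    groups <- unique(vapply(samples, sampleGroup, ""))
    samples <- lapply(samples, mergeCpGDyads)
    ann <- annotations
    # -- per-sample summary (Table-1 style) --
    summary <- do.call(rbind, lapply(samples, function(sm) {
        data.frame(sample = sampleId(sm), group = sampleGroup(sm),
            n_cpg_sites = length(methSites(sm, "CpG")),
            meth_level = weightedMethLevel(methSites(sm, "CpG"),
                th$region_min_coverage),
            mean_coverage = mean(siteCoverage(sm)))
    }))
    writeTsv(summary, file.path(outDir, "sample_summary.tsv"))
    # -- global comparison --
    se <- buildCommonMatrix(samples, th$site_min_coverage,
        genome = genome, autosomesOnly = TRUE)
    writeTsv(as.data.frame(pairwiseCorrelation(se)),
        file.path(outDir, "correlation.tsv"))
    dmc <- callDmcs(se, diffThreshold = th$dmc_diff,
        qThreshold = th$dmc_q)
    writeTsv(dmc, file.path(outDir, "dmc.tsv"))
    # -- PMDs --
    pmdSamples <- samples[vapply(samples, sampleGroup, "") == pmdGroup]
    pmd <- NULL
    if (length(pmdSamples) >= th$pmd_min_samples) {
        calls <- lapply(pmdSamples, function(sm) {
            tr <- binarizeWindows(windowMethylation(sm, genome,
                th$pmd_window, th$region_min_coverage,
                th$pmd_window_min_cpgs), th$pmd_threshold)
            hmmSegment(tr)
        })
        pmd <- consensusPmds(calls, genome, th$pmd_window,
            th$pmd_min_samples, th$pmd_min_windows)
        writeBed(pmd, file.path(outDir, "pmd_consensus.bed"),
            scoreCol = "support")
        if (!is.null(ann$satellites) && length(pmd) >= 3) {
            writeTsv(pmdSatelliteCorrelation(pmd, samples,
                ann$satellites, th$region_min_coverage),
                file.path(outDir, "pmd_satellite_correlation.tsv"))
        } else skipped$pmd_satellite <-
            "no satellite track or fewer than 3 PMDs"
        if (!is.null(ann$genes) && length(pmd) &&
            all(table(vapply(samples, sampleGroup, "")) >= 2)) {
            writeTsv(pmdGeneDiff(pmd, ann$genes, samples,
                cpgIndex = ann$cpgIndex, groups = groups,
                minCoverage = th$region_min_coverage,
                diffThreshold = th$gene_diff, qThreshold = th$gene_q),
                file.path(outDir, "pmd_gene_diff.tsv"))
        } else skipped$pmd_gene_diff <- "no gene track or no PMDs"
    } else skipped$pmd <- sprintf("fewer than %d %s samples",
        th$pmd_min_samples, pmdGroup)
    # -- HMRs --
    hmrCalls <- lapply(samples, function(sm)
        callHmrs(sm, th$region_min_coverage, th$hmr_seed, th$hmr_step,
            th$hmr_hypo_level, th$hmr_hypo_fraction, th$hmr_min_cpgs))
    for (nm in names(hmrCalls))
        writeBed(hmrCalls[[nm]],
            file.path(outDir, paste0("hmr_", nm, ".bed")),
            scoreCol = "n_cpgs")
    grp <- vapply(samples, sampleGroup, "")
    groupHmrs <- lapply(setNames(groups, groups), function(g)
        combineHmrs(hmrCalls[grp == g], method = "union"))
    cmp <- NULL
    if (length(groups) == 2L) {
        cmp <- compareHmrSets(groupHmrs[[1]], groupHmrs[[2]])
        writeTsv(data.frame(metric = names(cmp)[1:11],
            value = unlist(cmp[1:11], use.names = FALSE)),
            file.path(outDir, "hmr_comparison.tsv"))
        if (!is.null(ann$genes)) {
            sets <- hmrTssGeneSets(groupHmrs[[1]], groupHmrs[[2]],
                ann$genes)
            writeTsv(data.frame(
                set = rep(names(sets), lengths(sets)),
                gene_id = unlist(sets, use.names = FALSE)),
                file.path(outDir, "hmr_tss_gene_sets.tsv"))
            writeTsv(tssMetaprofile(samples, ann$genes,
                flank = th$tss_flank),
                file.path(outDir, "tss_metaprofile.tsv"))
        } else skipped$hmr_tss <- "no gene track"
    } else skipped$hmr_compare <- "need exactly two groups"
    # -- nucleosome-peak overlap --
    if (!is.null(ann$nucleosomes)) {
        fr <- vapply(hmrCalls, function(h)
            overlapFraction(ann$nucleosomes, h)$fraction, 0)
        writeTsv(data.frame(sample = names(fr), group = grp,
            fraction = fr), file.path(outDir, "nucleosome_overlap.tsv"))
    } else skipped$nucleosomes <- "no nucleosome peak track"
    # -- enrichment in consensus PMDs --
    feats <- ann[intersect(names(ann),
        c("genes", "cgis", "satellites", "repeats"))]
    if (!is.null(pmd) && length(pmd) && length(feats)) {
        writeTsv(oeEnrichment(pmd, feats, genome),
            file.path(outDir, "pmd_enrichment.tsv"))
    } else skipped$enrichment <- "no consensus PMDs or no feature tracks"
    # -- repeats --
    if (!is.null(ann$repeats)) {
        hypo <- extractHypoElements(ann$repeats, samples,
            cpgIndex = ann$cpgIndex, cgis = ann$cgis,
            hypoLevel = th$hmr_hypo_level,
            minCoverage = th$region_min_coverage)
        writeTsv(as.data.frame(hypo),
            file.path(outDir, "hypo_elements.tsv"))
        ys <- selectYoungSine(hypo,
            maxDivergence = th$sine_max_divergence)
        writeTsv(as.data.frame(ys$elements),
            file.path(outDir, "young_sines.tsv"))
        if (!is.null(ann$genes))
            writeTsv(promoterProximalRepeatGenes(ys$elements,
                ann$genes, th$tss_flank),
                file.path(outDir, "young_sine_genes.tsv"))
    } else skipped$repeats <- "no repeat table"
    manifest <- list(package = "methseg",
        version = as.character(utils::packageVersion("methseg")),
        thresholds = th, groups = groups, pmd_group = pmdGroup,
        n_samples = length(samples),
        samples = vapply(samples, sampleId, ""),
        dmc_test = attr(dmc, "test"),
        region_level = "coverage-weighted (pooled) methylation",
        skipped = if (length(skipped)) skipped else
            setNames(list(), character(0)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}
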