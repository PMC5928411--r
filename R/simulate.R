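#' Configuration for the synthetic methylome generator
#'
#' The generator plants fully-known structure — megabase partially
#' methylated domains, promoter hypomethylated regions, group-specific
#' satellite blocks, young hypomethylated SINEs near TSS and single-site
#' DMCs — on a high-methylation background, and draws per-CpG binomial
#' counts under Poisson coverage. Defaults mirror the study design this
#' generator emulates: a 4-sperm / 6-somatic (two replicates each of
#' three tissues) contrast, ~6x mean CpG coverage, ~78% background
#' methylation, PMDs at ~35% and promoter HMRs at ~5% methylation,
#' satellites hypomethylated in sperm but methylated in soma.
#'
#' @param seed Integer seed; every random stream derives from it.
#' @param chromLengths Named vector of chromosome lengths.
#' @param cpgRate,cgiCpgRate,satCpgRate CpG placement rates per bp for
#'   background, CGI blocks and satellite blocks.
#' @param nGenesPerChrom,geneLengthRange Gene count per chromosome and
#'   body length range.
#' @param cgiProb,cgiHalfWidthRange Fraction of promoters with a CGI and
#'   the CGI half-width range.
#' @param nHmrShared,nHmrSperm,nHmrSomatic Planted promoter-HMR counts
#'   (shared between groups / group-specific).
#' @param hmrHalfWidthRange,hmrLevel HMR half-width range and planted
#'   methylation level.
#' @param nPmds,pmdLengthRange,pmdLevel,pmdGroup Planted PMD count,
#'   length range, level and carrier group.
#' @param satStartLength,nSatBlocksPerChrom,satBlockLengthRange,satLevels
#'   Pericentromeric satellite block length (0 disables), interstitial
#'   block count, their length range, and per-group satellite levels.
#' @param nRepeatsPerChrom Scattered (old, background-methylated)
#'   repeat elements per chromosome.
#' @param nYoungSinesNearTss,youngSineLevels,bovA2Fraction Planted young
#'   SINEs within 2 kb of a TSS, their per-group levels, and the
#'   fraction named BOV-A2.
#' @param ageMethSlope Optional `c(intercept, slope)`: when given, every
#'   scattered repeat's true level is
#'   `clamp(intercept + slope * milliDiv)`.
#' @param nDmcSites Planted single-CpG DMCs (sperm 0.05 vs somatic
#'   0.95) at background CpGs.
#' @param backgroundLevel,backgroundConc Background Beta mean and
#'   concentration for per-site true levels.
#' @param replicateConc Beta concentration of per-replicate jitter
#'   around the group truth (overdispersion beyond binomial noise).
#' @param coverageMean Mean of the Poisson per-CpG coverage.
#' @param design `data.frame` with columns `sample_id`, `group`,
#'   `tissue`.
#' @param spikein,spikeinLength,spikeinSites,conversionError Include an
#'   unmethylated lambda-like spike-in contig (`chrL`) with the given
#'   number of cytosines and conversion-failure rate.
#' @return A `simConfig` list.
#' @export
simConfig <- function(seed = 1L,
                      chromLengths = c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6),
                      cpgRate = 0.01, cgiCpgRate = 0.10, satCpgRate = 0.02,
                      nGenesPerChrom = 40L, geneLengthRange = c(5e3, 2e4),
                      cgiProb = 0.7, cgiHalfWidthRange = c(300, 800),
                      nHmrShared = 40L, nHmrSperm = 15L, nHmrSomatic = 15L,
                      hmrHalfWidthRange = c(200, 500), hmrLevel = 0.05,
                      nPmds = 10L, pmdLengthRange = c(1e5, 5e5),
                      pmdLevel = 0.35, pmdGroup = "sperm",
                      satStartLength = 150000L, nSatBlocksPerChrom = 2L,
                      satBlockLengthRange = c(3e4, 8e4),
                      satLevels = c(sperm = 0.15, somatic = 0.85),
                      nRepeatsPerChrom = 150L,
                      nYoungSinesNearTss = 20L,
                      youngSineLevels = c(sperm = 0.10, somatic = 0.85),
                      bovA2Fraction = 0.95,
                      ageMethSlope = NULL,
                      nDmcSites = 200L,
                      backgroundLevel = 0.78, backgroundConc = 30,
                      replicateConc = 100,
                      coverageMean = 6,
                      design = NULL,
                      spikein = TRUE, spikeinLength = 48502L,
                      spikeinSites = 500L, conversionError = 0.005) {
    if (is.null(design))
        design <- data.frame(
            sample_id = c("Sperm1A", "Sperm1B", "Sperm2A", "Sperm2B",
                "CORTEX1", "CORTEX2", "MAM1", "MAM2", "WBC1", "WBC2"),
            group = c(rep("sperm", 4), rep("somatic", 6)),
            tissue = c(rep("sperm", 4), "cortex", "cortex", "mammary",
                "mammary", "blood", "blood"))
    cfg <- as.list(environment())
    stopifnot(all(chromLengths > 0), hmrLevel >= 0, hmrLevel <= 1,
        pmdLevel >= 0, pmdLevel <= 1, seed == floor(seed))
    class(cfg) <- "simConfig"
    cfg
}

## deterministic stream seeds derived from the master seed
streamSeed <- function(seed, ...) {
    ix <- c(...)
    s <- (as.numeric(seed) * 2654435761 + sum(ix * 97003^seq_along(ix))) %%
        2147483646
    as.integer(s) + 1L
}

## place non-overlapping intervals of given lengths inside [lo, hi],
## avoiding existing intervals (numeric start/end matrix), with a gap
placeIntervals <- function(chr, lo, hi, lens, avoid, gap = 50000L) {
    av <- if (length(avoid)) cbind(start(avoid), end(avoid)) else
        matrix(numeric(0), 0, 2)
    starts <- ends <- numeric(0)
    for (len in lens) {
        for (try in 1:200) {
            s <- floor(runif(1, lo, hi - len)); e <- s + len - 1
            clash <- any(av[, 1] <= e + gap & av[, 2] >= s - gap)
            if (!clash) {
                av <- rbind(av, c(s, e))
                starts <- c(starts, s); ends <- c(ends, e)
                break
            }
        }
    }
    if (!length(starts)) return(GRanges())
    GRanges(chr, IRanges(as.integer(starts), as.integer(ends)))
}

#' Simulate a genome with annotation and planted structure
#'
#' Generates chromosome sizes, CpG positions (denser in CGI blocks),
#' genes with TSS and strand, CpG islands, satellite blocks, a repeat
#' catalogue with milliDiv divergences, and the planted PMD/HMR/DMC
#' truth intervals. Fully deterministic given `config$seed`.
#'
#' @param config A [simConfig()].
#' @return List with `genome` ([MethGenome-class]), `cpgs` (`GRanges`
#'   of CpG positions, one record per dyad), `genes`, `cgis`,
#'   `satellites`, `repeats` (`GRanges` tracks) and `truth` (planted
#'   intervals: `pmds`, `hmrs` per group, `satellites`, `dmcs`,
#'   `youngSines`, `proximalPairs`).
#' @export
simulateGenome <- function(config) {
    cfg <- config
    sl <- cfg$chromLengths
    if (cfg$spikein) sl <- c(sl, chrL = cfg$spikeinLength)
    genome <- methGenome(sl, autosomes = names(cfg$chromLengths))
    si <- seqinfo(genome)
    chroms <- names(cfg$chromLengths)
    set.seed(streamSeed(cfg$seed, 1))
    sat <- genes <- cgis <- hmrAll <- GRanges()
    pmds <- GRanges()
    # --- satellite blocks ---
    for (ci in seq_along(chroms)) {
        chr <- chroms[ci]; L <- cfg$chromLengths[ci]
        blocks <- GRanges()
        if (cfg$satStartLength > 0)
            blocks <- GRanges(chr, IRanges(1L, cfg$satStartLength))
        if (cfg$nSatBlocksPerChrom > 0) {
            lens <- floor(runif(cfg$nSatBlocksPerChrom,
                cfg$satBlockLengthRange[1], cfg$satBlockLengthRange[2]))
            blocks <- c(blocks, placeIntervals(chr, 0.25 * L, 0.95 * L,
                lens, blocks, gap = 100000L))
        }
        sat <- c(sat, blocks)
    }
    # --- PMDs (round-robin over chromosomes, avoiding satellites) ---
    if (cfg$nPmds > 0) {
        lens <- floor(runif(cfg$nPmds, cfg$pmdLengthRange[1],
            cfg$pmdLengthRange[2]))
        for (k in seq_len(cfg$nPmds)) {
            ci <- ((k - 1L) %% length(chroms)) + 1L
            chr <- chroms[ci]; L <- cfg$chromLengths[ci]
            avoid <- c(sat[seqnames(sat) == chr],
                pmds[seqnames(pmds) == chr])
            p <- placeIntervals(chr, 0.2 * L, 0.98 * L, lens[k], avoid,
                gap = 100000L)
            pmds <- c(pmds, p)
        }
    }
    # --- genes, CGIs, planted promoter HMRs ---
    nHmr <- cfg$nHmrShared + cfg$nHmrSperm + cfg$nHmrSomatic
    nGenes <- max(cfg$nGenesPerChrom * length(chroms), nHmr + 10L)
    perChrom <- ceiling(nGenes / length(chroms))
    gid <- 0L
    for (ci in seq_along(chroms)) {
        chr <- chroms[ci]; L <- cfg$chromLengths[ci]
        satChr <- sat[as.character(seqnames(sat)) == chr]
        cand <- floor(runif(8L * perChrom, 5e4, L - 5e4))
        if (length(satChr)) {
            ss <- start(satChr); se <- end(satChr)
            bad <- vapply(cand, function(p)
                any(ss <= p + 3000 & se >= p - 3000), TRUE)
            cand <- cand[!bad]
        }
        # greedy spacing filter (>= 8 kb between TSS)
        cand <- sort(unique(cand))
        keep <- logical(length(cand)); last <- -Inf
        for (i in seq_along(cand)) {
            if (cand[i] - last >= 8000) { keep[i] <- TRUE; last <- cand[i] }
        }
        tss <- head(cand[keep], perChrom)
        str <- sample(c("+", "-"), length(tss), replace = TRUE)
        len <- floor(runif(length(tss), cfg$geneLengthRange[1],
            cfg$geneLengthRange[2]))
        gs <- ifelse(str == "+", tss, pmax(1L, tss - len + 1L))
        ge <- ifelse(str == "+", pmin(L, tss + len - 1L), tss)
        g <- GRanges(chr, IRanges(as.integer(gs), as.integer(ge)),
            strand = str)
        mcols(g)$gene_id <- sprintf("gene%04d", gid + seq_along(g))
        mcols(g)$tss <- as.integer(tss)
        gid <- gid + length(g)
        genes <- c(genes, g)
    }
    # planted HMR genes first (so they always carry a CGI wide enough)
    ord <- sample(seq_along(genes))
    hmrGenes <- ord[seq_len(min(nHmr, length(genes)))]
    hmrKind <- rep(c("shared", "sperm", "somatic"),
        times = c(cfg$nHmrShared, cfg$nHmrSperm, cfg$nHmrSomatic))
    hmrKind <- hmrKind[seq_along(hmrGenes)]
    h1 <- floor(runif(length(hmrGenes), cfg$hmrHalfWidthRange[1],
        cfg$hmrHalfWidthRange[2]))
    h2 <- floor(runif(length(hmrGenes), cfg$hmrHalfWidthRange[1],
        cfg$hmrHalfWidthRange[2]))
    tssH <- mcols(genes)$tss[hmrGenes]
    hmrAll <- GRanges(seqnames(genes)[hmrGenes],
        IRanges(pmax(1L, tssH - h1), tssH + h2))
    mcols(hmrAll)$kind <- hmrKind
    mcols(hmrAll)$gene_id <- mcols(genes)$gene_id[hmrGenes]
    # CGIs: every HMR gene gets one covering the HMR; others with cgiProb
    cgiGenes <- union(hmrGenes,
        which(runif(length(genes)) < cfg$cgiProb))
    hw <- floor(runif(length(cgiGenes), cfg$cgiHalfWidthRange[1],
        cfg$cgiHalfWidthRange[2]))
    need <- match(cgiGenes, hmrGenes)
    extra <- ifelse(is.na(need), 0L, pmax(h1[need], h2[need]) + 50L)
    hw <- pmax(hw, extra)
    tssC <- mcols(genes)$tss[cgiGenes]
    cgis <- GRanges(seqnames(genes)[cgiGenes],
        IRanges(pmax(1L, tssC - hw), tssC + hw))
    # --- repeat catalogue ---
    classes <- c("SINE", "LINE", "LTR", "DNA")
    lenRange <- list(SINE = c(150, 350), LINE = c(1000, 6000),
        LTR = c(300, 1000), DNA = c(200, 1500))
    reps <- GRanges()
    for (ci in seq_along(chroms)) {
        if (cfg$nRepeatsPerChrom < 1L) break
        chr <- chroms[ci]; L <- cfg$chromLengths[ci]
        cls <- sample(classes, cfg$nRepeatsPerChrom, replace = TRUE)
        rl <- vapply(cls, function(cl)
            floor(runif(1, lenRange[[cl]][1], lenRange[[cl]][2])), 0)
        rs <- floor(runif(cfg$nRepeatsPerChrom, 1, L - max(rl)))
        r <- GRanges(chr, IRanges(as.integer(rs),
            as.integer(rs + rl - 1L)))
        mcols(r)$name <- paste0(cls, "-old")
        mcols(r)$class <- cls
        mcols(r)$family <- cls
        mcols(r)$milliDiv <- runif(length(r), 60, 350)
        mcols(r)$consensus_fraction <- runif(length(r), 0.3, 1.0)
        reps <- c(reps, r)
    }
    # young SINEs planted within 2 kb of TSS of non-HMR genes
    ysGenes <- setdiff(seq_along(genes), hmrGenes)
    ysGenes <- ysGenes[sample.int(length(ysGenes),
        min(cfg$nYoungSinesNearTss, length(ysGenes)))]
    ys <- GRanges()
    if (length(ysGenes)) {
        tssY <- mcols(genes)$tss[ysGenes]
        ylen <- floor(runif(length(ysGenes), 180, 280))
        off <- floor(runif(length(ysGenes), -1500, 1500 - 280))
        ys <- GRanges(seqnames(genes)[ysGenes],
            IRanges(pmax(1L, tssY + off), tssY + off + ylen - 1L))
        mcols(ys)$name <- ifelse(runif(length(ys)) < cfg$bovA2Fraction,
            "BOV-A2", "SINE-oth")
        mcols(ys)$class <- "SINE"
        mcols(ys)$family <- "BovA"
        mcols(ys)$milliDiv <- runif(length(ys), 5, 45)
        mcols(ys)$consensus_fraction <- runif(length(ys), 0.9, 1.0)
    }
    # satellite blocks also appear in the repeat table
    satRep <- granges(sat)
    if (length(satRep)) {
        mcols(satRep)$name <- "SAT1"
        mcols(satRep)$class <- "Satellite"
        mcols(satRep)$family <- "Satellite"
        mcols(satRep)$milliDiv <- runif(length(satRep), 100, 300)
        mcols(satRep)$consensus_fraction <- runif(length(satRep), 0.5, 1)
    }
    reps <- c(reps, ys, satRep)
    # --- CpG positions ---
    cpgs <- GRanges()
    for (ci in seq_along(chroms)) {
        chr <- chroms[ci]; L <- cfg$chromLengths[ci]
        nbg <- rbinom(1, L, cfg$cpgRate)
        pos <- sort(sample.int(L - 1L, nbg))
        addIn <- function(track, rate) {
            tr <- reduce(track[seqnames(track) == chr])
            if (!length(tr) || rate <= 0) return(integer(0))
            unlist(lapply(seq_along(tr), function(i) {
                w <- width(tr)[i]
                n <- rbinom(1, w, rate)
                if (n == 0) return(integer(0))
                start(tr)[i] + sample.int(w, n) - 1L
            }))
        }
        pos <- sort(unique(c(pos,
            addIn(cgis, cfg$cgiCpgRate - cfg$cpgRate),
            addIn(ys, cfg$cgiCpgRate - cfg$cpgRate),
            addIn(sat, cfg$satCpgRate - cfg$cpgRate))))
        pos <- pos[pos >= 1L & pos < L]
        cpgs <- c(cpgs, GRanges(chr, IRanges(pos, width = 1L)))
    }
    seqinfo(cpgs) <- si
    for (nm in c("sat", "genes", "cgis", "pmds", "hmrAll"))
        assign(nm, `seqinfo<-`(get(nm), value = si))
    seqinfo(reps) <- si
    # --- planted single-site DMCs on background CpGs ---
    special <- reduce(c(granges(sat), granges(pmds), granges(hmrAll),
        granges(ys)))
    bg <- cpgs[!overlapsAny(cpgs, special)]
    dmcs <- GRanges(seqinfo = si)
    if (cfg$nDmcSites > 0 && length(bg))
        dmcs <- sort(bg[sample.int(length(bg),
            min(cfg$nDmcSites, length(bg)))])
    proximal <- data.frame(
        gene_id = if (length(ysGenes)) mcols(genes)$gene_id[ysGenes]
            else character(0),
        element = if (length(ys)) mcols(ys)$name else character(0))
    list(genome = genome, cpgs = cpgs, genes = genes, cgis = cgis,
        satellites = granges(sat), repeats = reps,
        truth = list(pmds = pmds, pmdGroup = cfg$pmdGroup,
            hmrs = list(
                shared = hmrAll[mcols(hmrAll)$kind == "shared"],
                sperm = hmrAll[mcols(hmrAll)$kind %in%
                    c("shared", "sperm")],
                somatic = hmrAll[mcols(hmrAll)$kind %in%
                    c("shared", "somatic")]),
            satellites = granges(sat), dmcs = dmcs, youngSines = ys,
            proximalPairs = proximal, seed = cfg$seed))
}

clamp01 <- function(x, eps = 1e-3) pmin(pmax(x, eps), 1 - eps)

## per-group true level at every CpG site (shared across replicates)
groupTrueLevels <- function(cfg, sim, group, gi) {
    cpgs <- sim$cpgs
    n <- length(cpgs)
    set.seed(streamSeed(cfg$seed, 2, gi))
    mu <- cfg$backgroundLevel; k <- cfg$backgroundConc
    lev <- rbeta(n, mu * k, (1 - mu) * k)
    setRegion <- function(lev, region, mu, k = cfg$backgroundConc) {
        idx <- which(overlapsAny(cpgs, region, ignore.strand = TRUE))
        if (length(idx))
            lev[idx] <- rbeta(length(idx), clamp01(mu) * k,
                (1 - clamp01(mu)) * k)
        lev
    }
    tr <- sim$truth
    lev <- setRegion(lev, tr$satellites, cfg$satLevels[[group]])
    if (group == tr$pmdGroup && length(tr$pmds))
        lev <- setRegion(lev, tr$pmds, cfg$pmdLevel)
    if (length(tr$hmrs[[group]]))
        lev <- setRegion(lev, tr$hmrs[[group]], cfg$hmrLevel, k = 50)
    if (!is.null(cfg$ageMethSlope)) {
        reps <- sim$repeats
        old <- reps[mcols(reps)$class %in% c("SINE", "LINE", "LTR", "DNA")]
        hits <- findOverlaps(cpgs, old, ignore.strand = TRUE)
        if (length(hits))
            lev[queryHits(hits)] <- clamp01(cfg$ageMethSlope[1] +
                cfg$ageMethSlope[2] *
                mcols(old)$milliDiv[subjectHits(hits)])
    }
    if (length(tr$youngSines)) {
        yl <- cfg$youngSineLevels[[group]]
        lev <- setRegion(lev, tr$youngSines, yl, k = 50)
    }
    if (length(tr$dmcs)) {
        idx <- which(overlapsAny(cpgs, tr$dmcs))
        lev[idx] <- if (group == "sperm") 0.05 else 0.95
    }
    clamp01(lev)
}

#' Simulate methylomes for every sample in the design
#'
#' Per sample and CpG: coverage ~ Poisson(`coverageMean`); the
#' replicate's level is a Beta draw around the group truth
#' (concentration `replicateConc`, modelling biological overdispersion);
#' methylated calls ~ Binomial(coverage, level). Uncovered sites are
#' dropped. Group truth is drawn once per group, so replicates share
#' the planted signal and differ only in noise; random streams are
#' split per (sample, chromosome-set) so adding a sample never perturbs
#' the others. A lambda-like unmethylated spike-in contig is appended
#' when configured.
#'
#' @param config A [simConfig()].
#' @param sim Result of [simulateGenome()].
#' @return List with `samples` (list of [Methylome-class]) and `truth`
#'   (the genome truth plus per-group true level matrix `levels`).
#' @export
simulateMethylomes <- function(config, sim) {
    cfg <- config
    groups <- unique(cfg$design$group)
    trueLev <- vapply(seq_along(groups), function(gi)
        groupTrueLevels(cfg, sim, groups[gi], gi),
        numeric(length(sim$cpgs)))
    colnames(trueLev) <- groups
    samples <- vector("list", nrow(cfg$design))
    for (siIdx in seq_len(nrow(cfg$design))) {
        set.seed(streamSeed(cfg$seed, 3, siIdx))
        lev <- trueLev[, cfg$design$group[siIdx]]
        k <- cfg$replicateConc
        rlev <- rbeta(length(lev), lev * k, (1 - lev) * k)
        cov <- rpois(length(lev), cfg$coverageMean)
        nm <- rbinom(length(lev), cov, rlev)
        keep <- cov > 0
        gr <- sim$cpgs[keep]
        strand(gr) <- "+"
        mcols(gr)$n_meth <- nm[keep]
        mcols(gr)$n_unmeth <- (cov - nm)[keep]
        mcols(gr)$context <- "CpG"
        if (cfg$spikein) {
            set.seed(streamSeed(cfg$seed, 4, siIdx))
            pos <- sort(sample.int(cfg$spikeinLength - 1L,
                cfg$spikeinSites))
            scov <- rpois(length(pos), cfg$coverageMean)
            snm <- rbinom(length(pos), scov, cfg$conversionError)
            skeep <- scov > 0
            sg <- GRanges("chrL", IRanges(pos[skeep], width = 1L),
                strand = "+", seqinfo = seqinfo(sim$genome))
            mcols(sg)$n_meth <- snm[skeep]
            mcols(sg)$n_unmeth <- (scov - snm)[skeep]
            mcols(sg)$context <- rep(c("CpG", "CHH"),
                length.out = length(sg))
            gr <- c(gr, sg)
        }
        samples[[siIdx]] <- Methylome(gr,
            sampleId = cfg$design$sample_id[siIdx],
            group = cfg$design$group[siIdx],
            tissue = cfg$design$tissue[siIdx])
    }
    names(samples) <- cfg$design$sample_id
    truth <- sim$truth
    truth$levels <- trueLev
    list(samples = samples, truth = truth)
}

#' Evaluate calls against planted truth intervals
#'
#' Base-pair sensitivity (called-and-true bp over true bp), precision
#' (called-and-true bp over called bp) and per-edge boundary distances
#' for each truth interval matched to its best-overlapping call.
#'
#' @param calls `GRanges` of calls.
#' @param truth `GRanges` of planted intervals (non-empty).
#' @param toleranceBp Edge tolerance used for the `boundary_ok`
#'   fraction.
#' @return List with `sensitivity`, `precision` (`NA` when nothing was
#'   called), `boundary` (`data.frame` of per-interval edge errors),
#'   `max_boundary_error` and `boundary_ok`.
#' @export
truthEvaluation <- function(calls, truth, toleranceBp = 0L) {
    truth <- reduce(granges(truth), ignore.strand = TRUE)
    if (length(truth) == 0L) stop("empty truth set")
    calls <- reduce(granges(calls), ignore.strand = TRUE)
    truthBp <- sum(as.numeric(width(truth)))
    if (length(calls) == 0L)
        return(list(sensitivity = 0, precision = NA_real_,
            boundary = data.frame(), max_boundary_error = NA_real_,
            boundary_ok = 0))
    ov <- sum(as.numeric(width(GenomicRanges::intersect(calls, truth,
        ignore.strand = TRUE))))
    callBp <- sum(as.numeric(width(calls)))
    hits <- findOverlaps(truth, calls, ignore.strand = TRUE)
    bdf <- data.frame()
    if (length(hits)) {
        ovw <- width(pintersect(truth[queryHits(hits)],
            calls[subjectHits(hits)]))
        best <- tapply(seq_along(ovw), queryHits(hits),
            function(ix) ix[which.max(ovw[ix])])
        ti <- as.integer(names(best)); ciX <- subjectHits(hits)[unlist(best)]
        bdf <- data.frame(truth_index = ti,
            start_error = abs(start(calls)[ciX] - start(truth)[ti]),
            end_error = abs(end(calls)[ciX] - end(truth)[ti]))
    }
    matchedOk <- if (nrow(bdf)) bdf$start_error <= toleranceBp &
        bdf$end_error <= toleranceBp else logical(0)
    ok <- sum(matchedOk)
    list(sensitivity = ov / truthBp, precision = ov / callBp,
        boundary = bdf,
        max_boundary_error = if (nrow(bdf))
            max(bdf$start_error, bdf$end_error) else NA_real_,
        boundary_ok = ok / length(truth))
}

#' Export a simulated dataset in standard on-disk formats
#'
#' Writes chrom.sizes, a genePred-like gene table, CGI and satellite
#' BEDs, a tab-separated repeat table, one cytosine report per sample
#' and a JSON truth file into `dir`. Everything round-trips through the
#' package's readers.
#'
#' @param sim Result of [simulateGenome()].
#' @param meth Result of [simulateMethylomes()] (or `NULL` to skip the
#'   cytosine reports).
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
exportSimulation <- function(sim, meth, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sl <- seqlengths(sim$genome)
    write.table(data.frame(names(sl), as.integer(sl)),
        file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    g <- sim$genes
    write.table(data.frame(name = mcols(g)$gene_id,
        chrom = as.character(seqnames(g)),
        strand = as.character(strand(g)), txStart = start(g) - 1L,
        txEnd = end(g)), file.path(dir, "genes.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    writeBed(sim$cgis, file.path(dir, "cgi.bed"))
    writeBed(sim$satellites, file.path(dir, "satellites.bed"))
    r <- sim$repeats
    write.table(data.frame(chrom = as.character(seqnames(r)),
        start = start(r) - 1L, end = end(r), name = mcols(r)$name,
        class = mcols(r)$class, family = mcols(r)$family,
        milliDiv = mcols(r)$milliDiv,
        consensus_fraction = mcols(r)$consensus_fraction),
        file.path(dir, "repeats.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    if (!is.null(meth)) {
        rd <- file.path(dir, "reports")
        dir.create(rd, showWarnings = FALSE)
        for (sm in meth$samples)
            writeCytosineReport(sm,
                file.path(rd, paste0(sampleId(sm), ".tsv")))
    }
    grList <- function(x) if (length(x) == 0) list() else
        lapply(seq_along(x), function(i) list(
            chrom = as.character(seqnames(x))[i], start = start(x)[i] - 1L,
            end = end(x)[i]))
    tr <- sim$truth
    jsonlite::write_json(list(seed = tr$seed, pmd_group = tr$pmdGroup,
        pmds = grList(tr$pmds), hmrs_shared = grList(tr$hmrs$shared),
        hmrs_sperm = grList(tr$hmrs$sperm),
        hmrs_somatic = grList(tr$hmrs$somatic),
        satellites = grList(tr$satellites), dmcs = grList(tr$dmcs),
        young_sines = grList(tr$youngSines)),
        file.path(dir, "truth.json"), auto_unbox = TRUE)
    invisible(dir)
}
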