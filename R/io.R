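#' Read a Bismark-style cytosine report
#'
#' Parses a TSV with columns chromosome, 1-based position, strand, count of
#' methylated calls, count of unmethylated calls, context (and an optional
#' trinucleotide column, ignored). Rows on chromosomes absent from `genome`
#' are dropped with a message.
#'
#' @param path Path to the report (plain text).
#' @param genome A [MethGenome-class]; rows on unknown chromosomes are
#'   dropped.
#' @param sampleId,group,tissue Sample annotation attached to the result.
#' @return A [Methylome-class] with sorted sites.
#' @export
readCytosineReport <- function(path, genome, sampleId = basename(path),
                               group = "unknown", tissue = group) {
    if (file.size(path) == 0) stop("no sites parsed from ", path)
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
        colClasses = list(character = c(1, 3, 6)), fill = TRUE,
        showProgress = FALSE)
    if (nrow(dt) == 0L) stop("no sites parsed from ", path)
    if (ncol(dt) < 6L) stop("cytosine report needs >= 6 columns: ", path)
    chrom <- dt[[1]]; pos <- dt[[2]]; strand <- dt[[3]]
    nm <- dt[[4]]; nu <- dt[[5]]; ctx <- dt[[6]]
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad))
        stop("unknown strand '", strand[bad[1]], "' at line ", bad[1])
    if (!is.numeric(pos) || !is.numeric(nm) || !is.numeric(nu) ||
        any(pos != floor(pos)) || any(nm != floor(nm)) || any(nu != floor(nu)))
        stop("non-integer position or counts in ", path, " (line ",
            which(!(pos == floor(pos)) | !(nm == floor(nm)) |
                  !(nu == floor(nu)))[1], ")")
    if (any(nm < 0) || any(nu < 0)) stop("negative counts in ", path)
    ctx <- ifelse(ctx %in% c("CpG", "CG"), "CpG", ctx)
    keep <- chrom %in% seqlevels(genome)
    if (!all(keep))
        message("readCytosineReport: dropped ", sum(!keep),
            " rows on chromosomes absent from the genome")
    if (!any(keep)) stop("no sites parsed (all on unknown chromosomes)")
    gr <- GRanges(chrom[keep], IRanges(pos[keep], width = 1L),
        strand = strand[keep], seqinfo = seqinfo(genome))
    mcols(gr)$n_meth <- as.integer(nm[keep])
    mcols(gr)$n_unmeth <- as.integer(nu[keep])
    mcols(gr)$context <- ctx[keep]
    Methylome(gr, sampleId = sampleId, group = group, tissue = tissue)
}

#' Write a cytosine report
#'
#' Inverse of [readCytosineReport()]: emits the 1-based six-column TSV.
#' @param x A [Methylome-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCytosineReport <- function(x, path) {
    s <- methSites(x)
    dt <- data.table::data.table(
        chrom = as.character(seqnames(s)), pos = start(s),
        strand = as.character(strand(s)), n_meth = mcols(s)$n_meth,
        n_unmeth = mcols(s)$n_unmeth, context = mcols(s)$context)
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Read a bedGraph-with-counts methylation file
#'
#' Alternate input dialect: 0-based half-open intervals with columns chrom,
#' start, end, level (percent), count methylated, count unmethylated.
#' Context is assumed CpG; strand is recorded as `+`.
#' @inheritParams readCytosineReport
#' @return A [Methylome-class].
#' @export
readBedGraphCounts <- function(path, genome, sampleId = basename(path),
                               group = "unknown", tissue = group) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
        showProgress = FALSE)
    if (nrow(dt) == 0L) stop("no sites parsed from ", path)
    if (ncol(dt) < 6L) stop("bedGraph-with-counts needs 6 columns")
    keep <- dt[[1]] %in% seqlevels(genome)
    if (!any(keep)) stop("no sites parsed (all on unknown chromosomes)")
    gr <- GRanges(dt[[1]][keep], IRanges(dt[[2]][keep] + 1L, width = 1L),
        strand = "+", seqinfo = seqinfo(genome))
    mcols(gr)$n_meth <- as.integer(dt[[5]][keep])
    mcols(gr)$n_unmeth <- as.integer(dt[[6]][keep])
    mcols(gr)$context <- "CpG"
    Methylome(gr, sampleId = sampleId, group = group, tissue = tissue)
}

#' Merge strand-symmetric CpG dyads
#'
#' A CpG dinucleotide shows up in a cytosine report as a `+` strand C at
#' position p and a `-` strand C at p+1. Merging sums the two counts into a
#' single record at p (strand `+`), doubling effective coverage. Unpaired
#' sites pass through unchanged; non-CpG contexts are never merged.
#' Idempotent: merged records have no `-` partner left to absorb.
#'
#' @param x A [Methylome-class].
#' @return A [Methylome-class] with CpG dyads collapsed.
#' @export
mergeCpGDyads <- function(x) {
    s <- methSites(x)
    is_cpg <- mcols(s)$context == "CpG"
    cpg <- s[is_cpg]
    rest <- s[!is_cpg]
    if (length(cpg)) {
        chrom <- as.character(seqnames(cpg))
        str <- as.character(strand(cpg))
        key <- paste0(chrom, ":", start(cpg), str)
        if (anyDuplicated(key))
            stop("duplicate site at ", key[duplicated(key)][1])
        # anchor every site at the + position of its dyad
        anchor <- ifelse(str == "-", start(cpg) - 1L, start(cpg))
        akey <- paste0(chrom, ":", anchor)
        nm <- rowsum(as.numeric(mcols(cpg)$n_meth), akey)
        nu <- rowsum(as.numeric(mcols(cpg)$n_unmeth), akey)
        first <- !duplicated(akey)
        ord <- akey[first]
        out <- GRanges(chrom[first], IRanges(anchor[first], width = 1L),
            strand = "+", seqinfo = seqinfo(cpg))
        mcols(out)$n_meth <- as.integer(nm[ord, 1])
        mcols(out)$n_unmeth <- as.integer(nu[ord, 1])
        mcols(out)$context <- "CpG"
        cpg <- out
    }
    Methylome(c(cpg, rest), sampleId = x@sampleId, group = x@group,
        tissue = x@tissue)
}

#' Weighted (pooled) methylation level of a set of sites
#'
#' The default regional summary is the coverage-weighted level: total
#' methylated calls over total calls, across sites passing the coverage
#' filter. The unweighted alternative averages per-site levels. Sites with
#' coverage below `minCoverage` are ignored; if none remain the level is
#' undefined and `NA` is returned (distinct from 0).
#'
#' @param x A [Methylome-class] or a `GRanges` with `n_meth`/`n_unmeth`.
#' @param minCoverage Minimum per-site coverage (default 5, the regional
#'   filter used throughout).
#' @param weighted If `FALSE`, return the unweighted mean of site levels.
#' @return A single fraction in \[0,1\], or `NA` if no site qualifies.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 5, 9), width = 1),
#'     n_meth = c(3, 0, 2), n_unmeth = c(1, 4, 2), context = "CpG")
#' weightedMethLevel(gr, minCoverage = 1)  # 5/12
#' @export
weightedMethLevel <- function(x, minCoverage = 5L, weighted = TRUE) {
    s <- if (is(x, "Methylome")) x@sites else x
    cov <- mcols(s)$n_meth + mcols(s)$n_unmeth
    keep <- cov >= minCoverage & cov > 0
    if (!any(keep)) return(NA_real_)
    if (weighted) {
        sum(as.numeric(mcols(s)$n_meth[keep])) / sum(as.numeric(cov[keep]))
    } else {
        mean(mcols(s)$n_meth[keep] / cov[keep])
    }
}

#' Bisulfite conversion rate from an unmethylated spike-in
#'
#' Libraries are spiked with unmethylated lambda DNA; every methylated call
#' on the spike-in contig is a conversion failure. The rate is
#' 1 - (methylated calls / total calls) over all cytosines (all contexts)
#' on that contig.
#'
#' @param x A [Methylome-class] containing the spike-in contig.
#' @param spikeinChrom Name of the spike-in chromosome.
#' @return Conversion rate in \[0,1\].
#' @export
conversionRate <- function(x, spikeinChrom) {
    s <- x@sites[as.character(seqnames(x@sites)) == spikeinChrom]
    tot <- sum(as.numeric(mcols(s)$n_meth + mcols(s)$n_unmeth))
    if (length(s) == 0L || tot == 0)
        stop("spike-in chromosome '", spikeinChrom,
            "' absent or uncovered in sample ", x@sampleId)
    1 - sum(as.numeric(mcols(s)$n_meth)) / tot
}

#' Write intervals as BED
#'
#' Emits 0-based half-open BED. Numeric/character metadata columns are
#' appended after the standard name and score columns so interval
#' statistics (CpG counts, mean methylation, support) travel with the
#' calls. An empty set produces a file holding only the header comment.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param scoreCol Optional mcol name written into the BED score column.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path, scoreCol = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# BED (0-based, half-open) written by methseg", con)
    if (length(gr) == 0L) return(invisible(path))
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    mc <- as.data.frame(mcols(gr))
    name <- if ("name" %in% colnames(mc)) mc$name else
        paste0("region_", seq_along(gr))
    score <- if (!is.null(scoreCol) && scoreCol %in% colnames(mc))
        mc[[scoreCol]] else 0
    dt <- data.frame(chrom = as.character(seqnames(gr)),
        start = start(gr) - 1L, end = end(gr), name = name, score = score,
        stringsAsFactors = FALSE)
    extra <- setdiff(colnames(mc), c("name", scoreCol))
    for (cn in extra) dt[[cn]] <- mc[[cn]]
    write.table(dt, con, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}

#' Read a BED file as GRanges
#'
#' Accepts BED3+ (comment lines starting with `#` or `track` skipped);
#' columns beyond the sixth are ignored. Coordinates convert from 0-based
#' half-open to the 1-based ranges used internally.
#'
#' @param path BED path.
#' @param genome Optional [MethGenome-class] supplying seqinfo.
#' @return `GRanges` (with `name`/`score` mcols when present).
#' @export
readBedTrack <- function(path, genome = NULL) {
    ln <- readLines(path)
    ln <- ln[nzchar(ln) & !grepl("^(#|track|browser)", ln)]
    si <- if (!is.null(genome)) seqinfo(genome) else NULL
    dt <- if (length(ln))
        data.table::fread(text = ln, header = FALSE, sep = "\t",
            fill = TRUE, showProgress = FALSE)
    else data.table::data.table()
    if (nrow(dt) == 0L) {
        gr <- GRanges()
        if (!is.null(si)) seqinfo(gr) <- si
        return(gr)
    }
    gr <- GRanges(dt[[1]], IRanges(as.integer(dt[[2]]) + 1L,
        as.integer(dt[[3]])))
    if (!is.null(genome)) gr <- applySeqinfo(gr, genome)
    if (ncol(dt) >= 4L) mcols(gr)$name <- as.character(dt[[4]])
    if (ncol(dt) >= 5L) mcols(gr)$score <- dt[[5]]
    if (ncol(dt) >= 6L) strand(gr) <- ifelse(dt[[6]] %in% c("+", "-"),
        dt[[6]], "*")
    gr
}

## attach a genome's seqinfo regardless of current seqlevel order
applySeqinfo <- function(gr, genome) {
    si <- seqinfo(genome)
    seqinfo(gr, new2old = match(seqlevels(si), seqlevels(gr))) <- si
    gr
}

#' Read a two-column chrom.sizes file
#'
#' @param path TSV of chromosome name and length.
#' @param autosomes Passed to [methGenome()].
#' @return A [MethGenome-class].
#' @export
readChromSizes <- function(path, autosomes = NULL) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
        showProgress = FALSE)
    methGenome(setNames(as.integer(dt[[2]]), dt[[1]]), autosomes = autosomes)
}

#' Read a genePred-like gene table
#'
#' Expects a TSV with header containing at least `name`, `chrom`, `strand`,
#' `txStart`, `txEnd` (UCSC genePred column names; txStart is 0-based).
#' The transcription start site (TSS) is txStart for `+` genes and txEnd
#' for `-` genes; it is recorded in the `tss` mcol (1-based).
#'
#' @param path Gene table path.
#' @param genome Optional [MethGenome-class].
#' @return `GRanges` of transcripts with `gene_id` and `tss` mcols.
#' @export
readGenePred <- function(path, genome = NULL) {
    dt <- data.table::fread(path, header = TRUE, sep = "\t",
        showProgress = FALSE)
    need <- c("name", "chrom", "strand", "txStart", "txEnd")
    if (!all(need %in% colnames(dt)))
        stop("gene table needs columns: ", paste(need, collapse = ", "))
    gr <- GRanges(dt$chrom, IRanges(dt$txStart + 1L, dt$txEnd),
        strand = dt$strand)
    if (!is.null(genome)) gr <- applySeqinfo(gr, genome)
    mcols(gr)$gene_id <- as.character(dt$name)
    mcols(gr)$tss <- ifelse(dt$strand == "+", dt$txStart + 1L,
        as.integer(dt$txEnd))
    gr
}

#' Read a RepeatMasker .out-style repeat table
#'
#' Accepts either the classic whitespace-delimited RepeatMasker `.out`
#' (three header lines, fields: score, milliDiv as percent divergence,
#' ... query, begin, end ... repeat name, class/family) or a tab-separated
#' table with header columns `chrom,start,end,name,class,family,milliDiv`
#' (start 0-based). milliDiv is stored as substitutions per 1000 bp.
#'
#' @param path Repeat table path.
#' @param genome Optional [MethGenome-class].
#' @return `GRanges` with mcols `name`, `class`, `family`, `milliDiv`.
#' @export
readRepeatMaskerOut <- function(path, genome = NULL) {
    head1 <- readLines(path, n = 1L)
    if (grepl("\t", head1)) {
        dt <- data.table::fread(path, header = TRUE, sep = "\t",
            showProgress = FALSE)
        gr <- GRanges(dt$chrom, IRanges(dt$start + 1L, dt$end))
        mcols(gr)$name <- as.character(dt$name)
        mcols(gr)$class <- as.character(dt$class)
        mcols(gr)$family <- as.character(dt$family)
        mcols(gr)$milliDiv <- as.numeric(dt$milliDiv)
    } else {
        ln <- readLines(path)
        ln <- ln[-seq_len(min(3L, length(ln)))]   # banner lines
        ln <- trimws(ln[nzchar(trimws(ln))])
        if (!length(ln)) stop("no repeat records in ", path)
        fld <- strsplit(ln, "\\s+")
        get <- function(i) vapply(fld, `[`, "", i)
        cls <- get(11)
        fam <- sub("^[^/]*/?", "", cls)
        cls0 <- sub("/.*$", "", cls)
        gr <- GRanges(get(5), IRanges(as.integer(get(6)), as.integer(get(7))))
        mcols(gr)$name <- get(10)
        mcols(gr)$class <- cls0
        mcols(gr)$family <- ifelse(nzchar(fam), fam, cls0)
        # column 2 is percent divergence; store as milliDiv
        mcols(gr)$milliDiv <- as.numeric(get(2)) * 10
    }
    if (any(mcols(gr)$milliDiv < 0 | mcols(gr)$milliDiv > 1000, na.rm = TRUE))
        stop("milliDiv outside [0, 1000]")
    if (!is.null(genome)) gr <- applySeqinfo(gr, genome)
    gr
}
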