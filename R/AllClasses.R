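#' @import methods
#' @importFrom GenomicRanges GRanges granges findOverlaps countOverlaps
#'   reduce pintersect seqnames start end width strand mcols mcols<-
#'   strand<- GRangesList tileGenome
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors queryHits subjectHits metadata metadata<- DataFrame
#'   Rle runValue
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqinfo<- seqlengths seqlevels
#'   seqnames<- keepSeqlevels
#' @importFrom stats rpois rbinom rbeta runif rnorm cor cor.test t.test
#'   p.adjust dhyper setNames median sd complete.cases
#' @importFrom utils head tail write.table read.table
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' MethGenome: chromosome sizes plus the autosome designation
#'
#' A thin wrapper around a [GenomeInfoDb::Seqinfo] that additionally records
#' which chromosomes count as autosomes. Several statistics (DMC calling,
#' observed/expected enrichment) are restricted to autosomes, following the
#' convention of comparing region densities against the autosomal average.
#'
#' @slot seqinfo A `Seqinfo` with chromosome names and lengths.
#' @slot autosomes Character vector, a subset of the chromosome names.
#' @exportClass MethGenome
setClass("MethGenome",
    representation(seqinfo = "Seqinfo", autosomes = "character"))

setValidity("MethGenome", function(object) {
    sl <- seqlengths(object@seqinfo)
    if (length(sl) == 0L)
        return("genome has no chromosomes")
    if (any(is.na(sl)) || any(sl <= 0))
        return("all chromosome lengths must be positive")
    if (!all(object@autosomes %in% names(sl)))
        return("autosomes must be a subset of the chromosome names")
    TRUE
})

#' Construct a MethGenome
#'
#' @param seqlengths Named integer/numeric vector of chromosome lengths.
#' @param autosomes Character vector of autosome names. Defaults to every
#'   chromosome not named like a sex chromosome (`chrX`, `chrY`, `X`, `Y`)
#'   or a spike-in/lambda contig.
#' @return A [MethGenome-class] object.
#' @examples
#' methGenome(c(chr1 = 1e6, chrX = 5e5))
#' @export
methGenome <- function(seqlengths, autosomes = NULL) {
    if (is.null(names(seqlengths)) || anyNA(names(seqlengths)))
        stop("seqlengths must be a named vector")
    if (is.null(autosomes)) {
        nm <- names(seqlengths)
        autosomes <- nm[!grepl("^(chr)?(X|Y|M|MT)$|lambda|chrL|spike",
            nm, ignore.case = TRUE)]
    }
    new("MethGenome",
        seqinfo = Seqinfo(names(seqlengths),
            seqlengths = as.integer(seqlengths)),
        autosomes = autosomes)
}

#' @describeIn MethGenome-class chromosome names
#' @param x,object A `MethGenome`.
#' @export
setMethod("seqlevels", "MethGenome", function(x) seqlevels(x@seqinfo))

#' @describeIn MethGenome-class named chromosome lengths
#' @export
setMethod("seqlengths", "MethGenome", function(x) seqlengths(x@seqinfo))

#' @describeIn MethGenome-class the underlying Seqinfo
#' @export
setMethod("seqinfo", "MethGenome", function(x) x@seqinfo)

#' Autosome names of a genome
#' @param x A [MethGenome-class].
#' @return Character vector of autosome names.
#' @export
autosomes <- function(x) {
    stopifnot(is(x, "MethGenome"))
    x@autosomes
}

setMethod("show", "MethGenome", function(object) {
    sl <- seqlengths(object)
    cat("MethGenome with", length(sl), "chromosomes (",
        length(object@autosomes), "autosomes ),",
        format(sum(as.numeric(sl)), big.mark = ","), "bp total\n")
})

#' Methylome: one sample's cytosine-level bisulfite calls
#'
#' Holds per-cytosine methylated/unmethylated call counts as a sorted
#' `GRanges` (width-1 ranges at each cytosine; 1-based, as usual for
#' Bioconductor ranges) with metadata columns `n_meth`, `n_unmeth` and
#' `context` (`"CpG"`, `"CHG"` or `"CHH"`). The sample carries an
#' identifier, a group label (e.g. `"sperm"` vs `"somatic"`) and a tissue.
#'
#' @slot sites `GRanges` of cytosines with `n_meth`, `n_unmeth`, `context`.
#' @slot sampleId Sample identifier.
#' @slot group Group label used by two-group comparisons.
#' @slot tissue Free-text tissue label.
#' @exportClass Methylome
setClass("Methylome",
    representation(sites = "GRanges", sampleId = "character",
        group = "character", tissue = "character"))

setValidity("Methylome", function(object) {
    s <- object@sites
    mc <- mcols(s)
    need <- c("n_meth", "n_unmeth", "context")
    if (!all(need %in% colnames(mc)))
        return(paste("sites must carry mcols:", paste(need, collapse = ", ")))
    if (length(s)) {
        if (any(mc$n_meth < 0) || any(mc$n_unmeth < 0))
            return("negative call counts")
        if (!all(mc$context %in% c("CpG", "CHG", "CHH")))
            return("context must be CpG, CHG or CHH")
        if (is.unsorted(order(as.integer(seqnames(s)), start(s))))
            return("sites must be sorted by chromosome and position")
    }
    if (length(object@sampleId) != 1L || length(object@group) != 1L)
        return("sampleId and group must be single strings")
    TRUE
})

#' Construct a Methylome
#'
#' @param sites `GRanges` with mcols `n_meth`, `n_unmeth`, `context`.
#' @param sampleId Sample identifier string.
#' @param group Group label (conventionally `"sperm"` or `"somatic"`).
#' @param tissue Tissue label.
#' @return A [Methylome-class] object, sites sorted.
#' @export
Methylome <- function(sites, sampleId, group = "unknown", tissue = group) {
    sites <- GenomicRanges::sort(sites, ignore.strand = TRUE)
    new("Methylome", sites = sites, sampleId = as.character(sampleId),
        group = as.character(group), tissue = as.character(tissue))
}

#' Cytosine sites of a methylome
#' @param x A [Methylome-class].
#' @param context Optional context filter (e.g. `"CpG"`).
#' @return `GRanges` of sites.
#' @export
methSites <- function(x, context = NULL) {
    stopifnot(is(x, "Methylome"))
    s <- x@sites
    if (!is.null(context)) s <- s[mcols(s)$context %in% context]
    s
}

#' @rdname methSites
#' @export
sampleId <- function(x) x@sampleId

#' @rdname methSites
#' @export
sampleGroup <- function(x) x@group

#' Per-site coverage and methylation level
#'
#' `siteCoverage()` returns `n_meth + n_unmeth` per site; `siteLevel()`
#' returns `n_meth / coverage` (NA where coverage is zero).
#' @param x A [Methylome-class] or a `GRanges` with count mcols.
#' @return Numeric vector, one entry per site.
#' @export
siteCoverage <- function(x) {
    s <- if (is(x, "Methylome")) x@sites else x
    mcols(s)$n_meth + mcols(s)$n_unmeth
}

#' @rdname siteCoverage
#' @export
siteLevel <- function(x) {
    s <- if (is(x, "Methylome")) x@sites else x
    cov <- mcols(s)$n_meth + mcols(s)$n_unmeth
    lev <- mcols(s)$n_meth / cov
    lev[cov == 0] <- NA_real_
    lev
}

setMethod("show", "Methylome", function(object) {
    s <- object@sites
    cov <- siteCoverage(object)
    cat("Methylome", object@sampleId, "(group:", object@group,
        ", tissue:", object@tissue, ")\n")
    cat("  ", length(s), "sites on",
        length(unique(as.character(seqnames(s)))), "chromosomes;",
        "median coverage", if (length(s)) median(cov) else NA, "\n")
    tab <- table(mcols(s)$context)
    if (length(tab))
        cat("  contexts:", paste(names(tab), tab, sep = "=", collapse = " "),
            "\n")
})
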