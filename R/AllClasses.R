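#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRangesList
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' UTRSet: per-gene 3'UTR intervals and spliced sequences
#'
#' Holds, for every gene, its 3'UTR genomic intervals (a
#' \link[GenomicRanges]{GRangesList} named by gene) together with the spliced
#' transcript-sense (5'-to-3' mRNA) sequence. Length and GC fraction are
#' derived, never stored, so the object cannot drift out of sync.
#'
#' @slot ranges \code{GRangesList}, one element per gene, intervals sorted in
#'   genomic order and non-overlapping within a gene.
#' @slot seq \code{DNAStringSet} named by gene; each sequence is the splice of
#'   the gene's intervals, reverse-complemented for minus-strand genes.
#'
#' @seealso \code{\link{loadUTRAnnotation}}, \code{\link{geneTable}}
#' @export
setClass("UTRSet", slots = c(ranges = "GRangesList", seq = "DNAStringSet"))

setValidity("UTRSet", function(object) {
    msg <- character()
    rn <- names(object@ranges)
    sn <- names(object@seq)
    if (is.null(rn) || is.null(sn) || !identical(rn, sn))
        msg <- c(msg, "ranges and seq must carry identical gene names")
    else {
        wsum <- vapply(GenomicRanges::width(object@ranges), sum, numeric(1))
        if (!all(wsum == Biostrings::width(object@seq)))
            msg <- c(msg, "sequence length must equal summed interval width")
        strands <- unique(vapply(object@ranges, function(gr)
            length(unique(as.character(BiocGenerics::strand(gr)))), integer(1)))
        if (any(strands > 1))
            msg <- c(msg, "all intervals of one gene must share a strand")
    }
    if (length(msg)) msg else TRUE
})

#' MRECatalog: candidate seed-match sites on a 3'UTR universe
#'
#' The catalog enumerates every candidate microRNA seed-match site (MRE) on
#' every gene's 3'UTR: one row per (gene, microRNA family, site type, offset).
#' It also carries the per-gene covariate table (length, GC fraction) that the
#' normalization stage consumes.
#'
#' @slot sites \code{DataFrame} with columns \code{gene_id}, \code{family_id},
#'   \code{site_type} (one of 8mer, 7mer-m8, 7mer-A1, 6mer), \code{utr_offset}
#'   (0-based start on the spliced transcript-sense UTR) and \code{site_seq}.
#' @slot genes \code{DataFrame} with columns \code{gene_id}, \code{length},
#'   \code{gc}.
#'
#' @seealso \code{\link{buildMRECatalog}}
#' @export
setClass("MRECatalog", slots = c(sites = "DataFrame", genes = "DataFrame"))

setValidity("MRECatalog", function(object) {
    msg <- character()
    need <- c("gene_id", "family_id", "site_type", "utr_offset", "site_seq")
    if (!all(need %in% colnames(object@sites)))
        msg <- c(msg, paste("sites must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (!all(object@sites$site_type %in% .SITE_TYPES))
            msg <- c(msg, "unknown site_type")
        key <- paste(object@sites$gene_id, object@sites$family_id,
                     object@sites$site_type, object@sites$utr_offset)
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate (gene, family, site_type, offset) entry")
        if (any(object@sites$utr_offset < 0))
            msg <- c(msg, "utr_offset must be >= 0")
    }
    if (!all(c("gene_id", "length", "gc") %in% colnames(object@genes)))
        msg <- c(msg, "genes must have columns gene_id, length, gc")
    if (length(msg)) msg else TRUE
})

#' MREExperiment: MRE count container
#'
#' A thin extension of \link[SummarizedExperiment]{SummarizedExperiment} whose
#' rows are (gene, microRNA family) pairs -- the unit at which MRE read support
#' is reported -- and whose columns are samples. The \code{"counts"} assay
#' holds raw non-negative integer read support; \code{\link{normalizeMRE}}
#' adds a \code{"normalized"} assay on the log2 scale. Column data carries the
#' sample group label and the UTR-restricted library size.
#'
#' @seealso \code{\link{MREExperiment}}, \code{\link{quantifySamples}},
#'   \code{\link{normalizeMRE}}
#' @export
setClass("MREExperiment",
         contains = "SummarizedExperiment")

setValidity("MREExperiment", function(object) {
    msg <- character()
    rd <- SummarizedExperiment::rowData(object)
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("gene_id", "family_id") %in% colnames(rd)))
        msg <- c(msg, "rowData must have gene_id and family_id")
    if (!all(c("group", "lib_size") %in% colnames(cd)))
        msg <- c(msg, "colData must have group and lib_size")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "a 'counts' assay is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(cts < 0) || any(cts != floor(cts)))
            msg <- c(msg, "counts must be non-negative integers")
    }
    if (length(msg)) msg else TRUE
})

#' GCNormModel: binned-median GC correction model
#'
#' Captures the fitted sample-specific GC effect: GC bin edges, bin centers,
#' the per-sample bin medians of the library/length-adjusted log2 values, and
#' the grand (across-sample) bin medians. The correction subtracted from a row
#' of sample s interpolates \code{sampleMedians[s,] - grandMedians} linearly
#' between bin centers and is held constant beyond the outer centers.
#'
#' @slot pseudocount pseudocount used upstream of the log2 (default 0.5).
#' @slot edges numeric bin edges on [0, 1] (after small-bin merging).
#' @slot centers numeric bin mid-points.
#' @slot sampleMedians samples x bins matrix of within-bin medians.
#' @slot grandMedians per-bin median across samples.
#'
#' @seealso \code{\link{fitGCCorrection}}, \code{\link{applyGCCorrection}}
#' @export
setClass("GCNormModel",
         slots = c(pseudocount = "numeric", edges = "numeric",
                   centers = "numeric", sampleMedians = "matrix",
                   grandMedians = "numeric"))

setValidity("GCNormModel", function(object) {
    msg <- character()
    if (is.unsorted(object@edges, strictly = TRUE))
        msg <- c(msg, "edges must be strictly increasing")
    if (length(object@centers) != length(object@edges) - 1L)
        msg <- c(msg, "need one center per bin")
    if (ncol(object@sampleMedians) != length(object@centers))
        msg <- c(msg, "sampleMedians must have one column per bin")
    if (length(object@grandMedians) != length(object@centers))
        msg <- c(msg, "grandMedians must have one value per bin")
    if (length(msg)) msg else TRUE
})

#' SelectionResult: intersected condition-specific MRE selection
#'
#' Bundles the two selection routes and their intersection: the set of MREs
#' called target-specific by the pairwise multiple-comparison (DTK) route, the
#' set called differentially expressed by the NB exact-test route, and the
#' intersected condition-specific set, all keyed as \code{"gene|family"}.
#' The full per-MRE tables of both routes ride along for reporting.
#'
#' @slot dtkSet character, MRE keys selected by the DTK route.
#' @slot deSet character, MRE keys selected by the differential route.
#' @slot specificSet character, the intersection.
#' @slot dtk \code{DataFrame} of per-pair DTK statistics (long format).
#' @slot de \code{DataFrame} with per-MRE \code{log2FC}, \code{pvalue},
#'   \code{fdr}.
#'
#' @seealso \code{\link{intersectSelections}}, \code{\link{decoupleMRE}}
#' @export
setClass("SelectionResult",
         slots = c(dtkSet = "character", deSet = "character",
                   specificSet = "character", dtk = "DataFrame",
                   de = "DataFrame"))

setValidity("SelectionResult", function(object) {
    msg <- character()
    if (!all(object@specificSet %in% object@dtkSet) ||
        !all(object@specificSet %in% object@deSet))
        msg <- c(msg, "specificSet must be a subset of both parent sets")
    if (length(msg)) msg else TRUE
})

#' DecoupledSets: mRNA / microRNA decomposition of an MRE set
#'
#' An MRE is an interaction site between an mRNA and a microRNA; decoupling a
#' selected MRE set recovers the two interacting partner lists. Holds the
#' unique gene list, the unique microRNA family list, the pair table and the
#' per-gene multiplicity (number of distinct selected MREs on that gene), all
#' in deterministic lexicographic order.
#'
#' @slot genes character, unique gene ids (sorted).
#' @slot mirnas character, unique microRNA family ids (sorted).
#' @slot pairs data.frame with columns \code{gene_id}, \code{family_id}.
#' @slot multiplicity named integer, distinct selected MREs per gene.
#'
#' @seealso \code{\link{decoupleMRE}}, \code{\link{multiplicitySummary}}
#' @export
setClass("DecoupledSets",
         slots = c(genes = "character", mirnas = "character",
                   pairs = "data.frame", multiplicity = "integer"))

setValidity("DecoupledSets", function(object) {
    msg <- character()
    if (nrow(object@pairs) < max(length(object@genes), length(object@mirnas)))
        msg <- c(msg, "pair count below unique-member count")
    if (!all(object@pairs$gene_id %in% object@genes) ||
        !all(object@pairs$family_id %in% object@mirnas))
        msg <- c(msg, "every pair member must appear in the unique lists")
    if (sum(object@multiplicity) != nrow(object@pairs))
        msg <- c(msg, "multiplicities must sum to the pair count")
    if (length(msg)) msg else TRUE
})
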