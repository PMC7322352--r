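#' Read 3'UTR-restricted alignments
#'
#' Reads a SAM (converted on the fly) or BAM file of alignments and returns
#' the aligned genomic spans with the stored read sequence. The aligned span
#' excludes soft-clipped bases; the sequence keeps them and is in
#' forward-genomic orientation as stored by the alignment format.
#'
#' @param path path to a headered SAM or BAM file.
#' @return a \link[GenomicRanges]{GRanges} of aligned spans with metadata
#'   columns \code{qname}, \code{seq} (\code{DNAStringSet}) and
#'   \code{is_mate2}.
#' @export
readAlignments <- function(path) {
    if (grepl("\\.sam$", path, ignore.case = TRUE))
        path <- Rsamtools::asBam(path, tempfile(),
                                 overwrite = TRUE, indexDestination = FALSE)
    ga <- GenomicAlignments::readGAlignments(
        path, param = Rsamtools::ScanBamParam(
            what = c("qname", "seq", "flag")))
    gr <- GenomicRanges::granges(ga)
    S4Vectors::mcols(gr)$qname <- S4Vectors::mcols(ga)$qname
    S4Vectors::mcols(gr)$seq <- S4Vectors::mcols(ga)$seq
    S4Vectors::mcols(gr)$is_mate2 <-
        bitwAnd(S4Vectors::mcols(ga)$flag, 128L) > 0L
    gr
}

#' Assign reads to genes by 3'UTR overlap
#'
#' A read is assigned to a gene if its aligned span overlaps any of the
#' gene's 3'UTR intervals by at least \code{minOverlap} nucleotides; a read
#' overlapping the UTRs of several genes is assigned to all of them but is
#' counted once in the library size. The library size returned here (reads
#' assigned to any UTR) is the \code{N_s} used by the normalization stage.
#'
#' @param reads a \code{GRanges} as returned by \code{\link{readAlignments}}.
#' @param utrs a \code{\linkS4class{UTRSet}}.
#' @param minOverlap minimum overlap in nucleotides (default 1).
#' @return list with \code{hits} (data.frame: \code{read} index into
#'   \code{reads}, \code{gene_id}) and \code{libSize} (number of distinct
#'   assigned read ids).
#' @export
assignReadsToUTRs <- function(reads, utrs, minOverlap = 1L) {
    utrGR <- BiocGenerics::unlist(utrRanges(utrs), use.names = FALSE)
    utrGR$gene_id <- rep(names(utrRanges(utrs)),
                         lengths(utrRanges(utrs)))
    if (length(reads)) {
        shared <- intersect(as.character(unique(
                      GenomeInfoDb::seqnames(reads))),
                  as.character(unique(GenomeInfoDb::seqnames(utrGR))))
        if (length(shared) == 0)
            stop("chromosome naming mismatch: alignment contig(s) ",
                 paste(utils::head(unique(as.character(
                     GenomeInfoDb::seqnames(reads))), 5), collapse = ", "),
                 " not found in the UTR annotation")
    }
    ov <- suppressWarnings(GenomicRanges::findOverlaps(
        reads, utrGR, minoverlap = minOverlap, ignore.strand = TRUE))
    hits <- unique(data.frame(
        read = S4Vectors::queryHits(ov),
        gene_id = utrGR$gene_id[S4Vectors::subjectHits(ov)],
        stringsAsFactors = FALSE))
    libSize <- length(unique(S4Vectors::mcols(reads)$qname[hits$read]))
    list(hits = hits, libSize = libSize)
}

#' Count site-sequence occurrences in read sequences
#'
#' Counts exact occurrences of any of the given site sequences in each read.
#' By default scanning is unstranded: the reverse complement of each site is
#' searched as well, and an occurrence found in both orientations at the same
#' read offset (a palindromic site) is counted once. Overlapping occurrences
#' within one orientation each count. \code{N} bases never match.
#'
#' @param readSeq character vector or \code{DNAStringSet} of read sequences.
#' @param siteSeqs character vector of DNA site sequences.
#' @param stranded if \code{TRUE}, scan the sense orientation only.
#' @return integer vector of occurrence counts, one per read.
#' @examples
#' scanRead("TTACATTCCATT", "ACATTCCA")   # 1
#' scanRead("TGGAATGT", "ACATTCCA")       # 1 (reverse complement)
#' scanRead("TGGAATGT", "ACATTCCA", stranded = TRUE)  # 0
#' @export
scanRead <- function(readSeq, siteSeqs, stranded = FALSE) {
    if (is.character(readSeq)) {
        if (any(nchar(readSeq) == 0)) stop("empty read sequence")
        readSeq <- Biostrings::DNAStringSet(toupper(readSeq))
    }
    counts <- integer(length(readSeq))
    for (s in unique(siteSeqs)) {
        fwd <- Biostrings::vmatchPattern(s, readSeq, fixed = TRUE)
        if (stranded) {
            counts <- counts + lengths(fwd)
        } else {
            rev <- Biostrings::vmatchPattern(.revcompChar(s), readSeq,
                                             fixed = TRUE)
            fs <- BiocGenerics::start(fwd)
            rs <- BiocGenerics::start(rev)
            counts <- counts + vapply(seq_along(readSeq), function(i)
                length(union(fs[[i]], rs[[i]])), integer(1))
        }
    }
    counts
}

# genomic ranges of catalog sites for one gene, honoring splicing and strand
.siteGenomicRanges <- function(gr, siteOffsets, siteLens) {
    gr <- GenomicRanges::sort(gr)
    w <- GenomicRanges::width(gr)
    minus <- as.character(BiocGenerics::strand(gr))[1] == "-"
    # transcript start (0-based) of each genomic interval
    tStart <- if (minus) rev(cumsum(rev(w))) - w else cumsum(w) - w
    out <- vector("list", length(siteOffsets))
    for (k in seq_along(siteOffsets)) {
        a <- siteOffsets[k]; b <- a + siteLens[k] - 1L   # 0-based inclusive
        parts <- list()
        for (i in seq_along(w)) {
            lo <- max(a, tStart[i]); hi <- min(b, tStart[i] + w[i] - 1L)
            if (lo > hi) next
            if (minus) {
                gEnd <- GenomicRanges::end(gr)[i] - (lo - tStart[i])
                gStart <- GenomicRanges::end(gr)[i] - (hi - tStart[i])
            } else {
                gStart <- GenomicRanges::start(gr)[i] + (lo - tStart[i])
                gEnd <- GenomicRanges::start(gr)[i] + (hi - tStart[i])
            }
            parts[[length(parts) + 1L]] <- GenomicRanges::GRanges(
                GenomeInfoDb::seqnames(gr)[i],
                IRanges::IRanges(gStart, gEnd),
                strand = BiocGenerics::strand(gr)[1])
        }
        out[[k]] <- do.call(c, parts)
    }
    out
}

#' Quantify MRE read support for one sample
#'
#' Computes the raw MRE count column c[(gene, family), sample]: for every
#' (gene, microRNA family) pair in the catalog, the read-level support among
#' reads assigned to that gene's 3'UTR.
#'
#' Two counting modes are provided. \code{"sequence"} (default) scans each
#' assigned read's sequence for the family's catalogued site sequences and
#' sums occurrences -- faithful to an alignment-to-FASTQ-to-motif-scan
#' design, which discards coordinates. \code{"coordinate"} counts fragments
#' whose aligned span fully contains the site's genomic interval (paired
#' mates deduplicated per site locus). On error-free reads that are exact
#' UTR substrings the two modes agree.
#'
#' @param reads a \code{GRanges} from \code{\link{readAlignments}}, or a
#'   path to a SAM/BAM file.
#' @param catalog an \code{\linkS4class{MRECatalog}}.
#' @param utrs the \code{\linkS4class{UTRSet}} the catalog was built on.
#' @param mode \code{"sequence"} or \code{"coordinate"}.
#' @param stranded sequence mode only: restrict scanning to the sense
#'   orientation (default \code{FALSE}, unstranded libraries).
#' @param tally sequence mode only: \code{"occurrence"} counts every motif
#'   occurrence (default); \code{"read"} counts each read at most once per
#'   family.
#' @param minOverlap minimum read/UTR overlap for assignment.
#' @return list with \code{counts} (named integer vector over
#'   \code{mreKeys(catalog)}) and \code{libSize}.
#' @export
quantifySample <- function(reads, catalog, utrs,
                           mode = c("sequence", "coordinate"),
                           stranded = FALSE,
                           tally = c("occurrence", "read"),
                           minOverlap = 1L) {
    mode <- match.arg(mode)
    tally <- match.arg(tally)
    if (is.character(reads)) reads <- readAlignments(reads)
    keys <- mreKeys(catalog)
    counts <- stats::setNames(integer(length(keys)), keys)
    asg <- assignReadsToUTRs(reads, utrs, minOverlap = minOverlap)
    if (nrow(asg$hits) == 0)
        return(list(counts = counts, libSize = asg$libSize))
    sites <- mreSites(catalog)
    if (mode == "sequence") {
        hitByGene <- split(asg$hits$read, asg$hits$gene_id)
        bySite <- split(seq_len(nrow(sites)),
                        paste(sites$gene_id, sites$family_id, sep = "|"))
        for (key in names(bySite)) {
            g <- sites$gene_id[bySite[[key]][1]]
            ridx <- hitByGene[[g]]
            if (is.null(ridx)) next
            sseqs <- unique(sites$site_seq[bySite[[key]]])
            occ <- scanRead(S4Vectors::mcols(reads)$seq[ridx], sseqs,
                            stranded = stranded)
            counts[key] <- if (tally == "occurrence") sum(occ)
                           else sum(occ > 0)
        }
    } else {
        grl <- utrRanges(utrs)
        spans <- GenomicRanges::granges(reads)
        qn <- S4Vectors::mcols(reads)$qname
        for (g in unique(sites$gene_id)) {
            gi <- which(sites$gene_id == g)
            parts <- .siteGenomicRanges(grl[[g]], sites$utr_offset[gi],
                                        nchar(sites$site_seq[gi]))
            for (j in seq_along(gi)) {
                ov <- suppressWarnings(GenomicRanges::findOverlaps(
                    parts[[j]], spans, type = "within",
                    ignore.strand = TRUE))
                # read must contain every part of a (possibly spliced) site
                tab <- table(S4Vectors::subjectHits(ov))
                full <- as.integer(names(tab)[tab == length(parts[[j]])])
                key <- paste(g, sites$family_id[gi[j]], sep = "|")
                counts[key] <- counts[key] + length(unique(qn[full]))
            }
        }
    }
    list(counts = counts, libSize = asg$libSize)
}

#' Construct an MREExperiment
#'
#' @param counts integer matrix, rows named \code{"gene|family"}, columns
#'   named by sample.
#' @param groups character/factor of group labels, one per column.
#' @param libSizes numeric vector of UTR-restricted library sizes, one per
#'   column.
#' @return an \code{\linkS4class{MREExperiment}}.
#' @export
MREExperiment <- function(counts, groups, libSizes) {
    counts <- as.matrix(counts)
    parts <- .parseKeys(rownames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene_id = parts$gene_id,
                                       family_id = parts$family_id),
        colData = S4Vectors::DataFrame(group = as.character(groups),
                                       lib_size = as.numeric(libSizes),
                                       row.names = colnames(counts)))
    methods::new("MREExperiment", se)
}

.parseKeys <- function(keys) {
    parts <- strsplit(keys, "|", fixed = TRUE)
    bad <- lengths(parts) != 2L |
        vapply(parts, function(p) any(!nzchar(p)), logical(1))
    if (any(bad))
        stop("malformed MRE key(s): ",
             paste(utils::head(keys[bad], 5), collapse = ", "))
    list(gene_id = vapply(parts, `[[`, "", 1),
         family_id = vapply(parts, `[[`, "", 2))
}

#' Quantify a cohort of samples
#'
#' Runs \code{\link{quantifySample}} over a set of alignment files and
#' assembles the raw MRE count matrix. Samples whose library size is zero
#' are flagged with a warning (they would be dropped by normalization).
#'
#' @param paths named character vector of SAM/BAM paths; names are sample
#'   ids.
#' @param catalog an \code{\linkS4class{MRECatalog}}.
#' @param utrs the matching \code{\linkS4class{UTRSet}}.
#' @param groups group label per sample (same order as \code{paths}).
#' @param ... passed to \code{\link{quantifySample}}.
#' @return an \code{\linkS4class{MREExperiment}}.
#' @export
quantifySamples <- function(paths, catalog, utrs, groups, ...) {
    stopifnot(!is.null(names(paths)), length(groups) == length(paths))
    cols <- lapply(paths, quantifySample, catalog = catalog, utrs = utrs,
                   ...)
    counts <- do.call(cbind, lapply(cols, `[[`, "counts"))
    colnames(counts) <- names(paths)
    libs <- vapply(cols, `[[`, numeric(1), "libSize")
    if (any(libs == 0))
        warning("sample(s) with zero assigned reads: ",
                paste(names(paths)[libs == 0], collapse = ", "))
    MREExperiment(counts, groups, libs)
}

#' @rdname mreExperimentAccessors
#' @name mreExperimentAccessors
#' @title MREExperiment accessors
#' @param x an \code{\linkS4class{MREExperiment}}.
#' @export
setMethod("mreCounts", "MREExperiment", function(x)
    SummarizedExperiment::assay(x, "counts"))

#' @rdname mreExperimentAccessors
#' @export
setMethod("normValues", "MREExperiment", function(x) {
    if (!"normalized" %in% SummarizedExperiment::assayNames(x))
        stop("no 'normalized' assay; run normalizeMRE() first")
    SummarizedExperiment::assay(x, "normalized")
})

#' @rdname mreExperimentAccessors
#' @export
setMethod("libSizes", "MREExperiment", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$lib_size,
                    colnames(x)))

#' @rdname mreExperimentAccessors
#' @export
setMethod("sampleGroups", "MREExperiment", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$group, colnames(x)))

#' @rdname mreSites
#' @export
setMethod("mreKeys", "MREExperiment", function(x, ...) rownames(x))
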