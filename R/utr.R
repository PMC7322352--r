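.checkDNA <- function(x) {
    bad <- grepl("[^ACGTN]", toupper(x))
    if (any(bad))
        stop("non-ACGTN character in sequence(s): ",
             paste(utils::head(which(bad), 5), collapse = ", "))
    invisible(toupper(x))
}

#' @rdname gcContent
#' @export
setMethod("gcContent", "character", function(x, ...) {
    if (any(nchar(x) == 0)) stop("empty sequence")
    x <- .checkDNA(x)
    gcContent(Biostrings::DNAStringSet(x))
})

#' @rdname gcContent
#' @export
setMethod("gcContent", "DNAStringSet", function(x, ...) {
    if (any(Biostrings::width(x) == 0)) stop("empty sequence")
    f <- Biostrings::letterFrequency(x, c("G", "C", "N"))
    denom <- Biostrings::width(x) - f[, "N"]
    if (any(denom == 0)) stop("sequence consists only of N")
    unname((f[, "G"] + f[, "C"]) / denom)
})

#' @rdname gcContent
#' @export
setMethod("gcContent", "UTRSet", function(x, ...) {
    stats::setNames(gcContent(x@seq), names(x@seq))
})

#' Construct a UTRSet
#'
#' @param ranges a named \link[GenomicRanges]{GRangesList}, one element per
#'   gene; intervals of a gene must be non-overlapping and on one strand.
#' @param seq a \link[Biostrings]{DNAStringSet} named identically, holding
#'   each gene's spliced transcript-sense sequence.
#' @return a \code{\linkS4class{UTRSet}}.
#' @export
UTRSet <- function(ranges, seq) {
    ranges <- GenomicRanges::GRangesList(lapply(ranges, GenomicRanges::sort))
    methods::new("UTRSet", ranges = ranges, seq = seq)
}

#' UTRSet accessors
#'
#' @param x a \code{\linkS4class{UTRSet}}.
#' @return \code{utrRanges}: the per-gene \code{GRangesList};
#'   \code{utrSequences}: the spliced sequences; \code{utrLengths}: named
#'   integer UTR lengths; \code{geneIds}: character gene ids.
#' @name utrAccessors
NULL

#' @rdname utrAccessors
#' @export
setMethod("utrRanges", "UTRSet", function(x) x@ranges)

#' @rdname utrAccessors
#' @export
setMethod("utrSequences", "UTRSet", function(x) x@seq)

#' @rdname utrAccessors
#' @export
setMethod("utrLengths", "UTRSet", function(x)
    stats::setNames(Biostrings::width(x@seq), names(x@seq)))

#' @rdname utrAccessors
#' @export
setMethod("geneIds", "UTRSet", function(x) names(x@seq))

setMethod("length", "UTRSet", function(x) length(x@seq))

setMethod("show", "UTRSet", function(object) {
    L <- utrLengths(object)
    cat("UTRSet with", length(object), "genes\n")
    cat("  UTR length: ", min(L), "-", max(L),
        " nt (median ", stats::median(L), ")\n", sep = "")
    cat("  GC fraction: ",
        sprintf("%.3f-%.3f", min(gcContent(object)), max(gcContent(object))),
        "\n", sep = "")
})

#' Per-gene covariate table
#'
#' The per-gene 3'UTR length and GC fraction consumed by the normalization
#' stage.
#'
#' @param x a \code{\linkS4class{UTRSet}} or \code{\linkS4class{MRECatalog}}.
#' @param ... unused.
#' @return a \link[S4Vectors]{DataFrame} with columns \code{gene_id},
#'   \code{length}, \code{gc}.
#' @name geneTable
#' @export
setMethod("geneTable", "UTRSet", function(x, ...) {
    S4Vectors::DataFrame(gene_id = geneIds(x),
                         length = unname(utrLengths(x)),
                         gc = unname(gcContent(x)))
})

.readBED6 <- function(path) {
    ln <- readLines(path)
    ln <- ln[nzchar(ln)]
    fields <- strsplit(ln, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 6))
        stop("malformed BED line (fewer than 6 fields) at line ",
             which(nf < 6)[1])
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
    strand <- vapply(fields, `[[`, "", 6)
    bad <- which(is.na(start) | is.na(end) | end <= start |
                 !strand %in% c("+", "-"))
    if (length(bad))
        stop("malformed BED line at line ", bad[1])
    GenomicRanges::GRanges(
        seqnames = vapply(fields, `[[`, "", 1),
        ranges = IRanges::IRanges(start = start + 1L, end = end),
        strand = strand,
        name = vapply(fields, `[[`, "", 4))
}

#' Load a 3'UTR annotation
#'
#' Reads a BED6 3'UTR annotation plus a FASTA and returns one
#' \code{\linkS4class{UTRSet}} record per gene. The FASTA is interpreted per
#' gene when every BED \code{name} matches a FASTA id; otherwise it is treated
#' as a genome (ids are chromosome names) and sequences are extracted,
#' spliced across a gene's intervals in genomic order and reverse-complemented
#' for minus-strand genes, yielding transcript-sense UTR sequences.
#'
#' Coordinates are BED convention (0-based half-open) on disk and 1-based
#' inside \code{GRanges}.
#'
#' @param bedPath path to a BED6 file (chrom, start, end, gene id, score,
#'   strand); several lines may share a gene id (multi-interval UTRs).
#' @param fastaPath path to a FASTA file, genome-level or per-gene.
#' @return a \code{\linkS4class{UTRSet}}.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' fa <- tempfile(fileext = ".fa")
#' writeLines("chr1\t2\t14\tgeneA\t0\t+", bed)
#' writeLines(c(">chr1", "TTACGTACGTACGTACGT"), fa)
#' utrs <- loadUTRAnnotation(bed, fa)
#' utrLengths(utrs)
#' @export
loadUTRAnnotation <- function(bedPath, fastaPath) {
    gr <- .readBED6(bedPath)
    fa <- Biostrings::readDNAStringSet(fastaPath)
    names(fa) <- sub("\\s.*$", "", names(fa))
    genes <- unique(gr$name)
    perGene <- all(genes %in% names(fa))
    if (!perGene) {
        missingChrom <- setdiff(as.character(GenomeInfoDb::seqnames(gr)),
                                names(fa))
        if (length(missingChrom)) {
            missingGene <- setdiff(genes, names(fa))
            stop("BED genes absent from FASTA: ",
                 paste(utils::head(missingGene, 10), collapse = ", "),
                 " (and FASTA has no contig(s) ",
                 paste(utils::head(missingChrom, 5), collapse = ", "), ")")
        }
    }
    grl <- GenomicRanges::GRangesList(lapply(
        split(gr, factor(gr$name, levels = genes)), GenomicRanges::sort))
    if (perGene) {
        seqs <- fa[genes]
        wsum <- vapply(GenomicRanges::width(grl), sum, numeric(1))
        if (!all(wsum == Biostrings::width(seqs)))
            stop("per-gene FASTA sequence length disagrees with BED ",
                 "interval widths for: ",
                 paste(utils::head(
                     genes[wsum != Biostrings::width(seqs)], 10),
                     collapse = ", "))
    } else {
        seqs <- Biostrings::DNAStringSet(vapply(genes, function(g) {
            ivs <- grl[[g]]
            parts <- vapply(seq_along(ivs), function(i) {
                chrom <- as.character(GenomeInfoDb::seqnames(ivs)[i])
                as.character(Biostrings::subseq(
                    fa[[chrom]], start = GenomicRanges::start(ivs)[i],
                    end = GenomicRanges::end(ivs)[i]))
            }, character(1))
            s <- paste(parts, collapse = "")
            if (as.character(BiocGenerics::strand(ivs))[1] == "-")
                s <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(s)))
            s
        }, character(1)))
        names(seqs) <- genes
    }
    UTRSet(grl, seqs)
}
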