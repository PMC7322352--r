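.revcompChar <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

.siteFromS <- function(S) {
    core <- substr(S, 2, 7)
    c("8mer" = paste0(S, "A"),
      "7mer-m8" = S,
      "7mer-A1" = paste0(core, "A"),
      "6mer" = core)
}

#' Canonical seed-match site sequences of a microRNA
#'
#' A microRNA binds its targets through its seed region (positions 2-8); the
#' Watson-Crick match of that region on the mRNA defines the four canonical
#' site types. Let S be the reverse complement (as DNA) of miRNA positions
#' 2-8. Then the site sequences are: 7mer-m8 = S; 8mer = S followed by "A";
#' 7mer-A1 = S without its first base, followed by "A"; 6mer = S without its
#' first base. The terminal "A" of the 8mer/7mer-A1 types is the adenine
#' opposite miRNA position 1, recognized directly rather than paired.
#'
#' @param mirnaSeq mature microRNA sequence, 5' to 3', RNA or DNA alphabet,
#'   at least 8 nt.
#' @return named character vector with elements \code{8mer}, \code{7mer-m8},
#'   \code{7mer-A1}, \code{6mer} (DNA alphabet).
#' @examples
#' seedToSiteSequences("UGGAAUGUAAAGAAGUAUGUAU")  # miR-1
#' @seealso \code{\link{siteSequencesFromSeed}} when only the 7-nt seed
#'   region is known.
#' @export
seedToSiteSequences <- function(mirnaSeq) {
    x <- chartr("Uu", "Tt", toupper(mirnaSeq))
    if (nchar(x) < 8)
        stop("microRNA sequence must be at least 8 nt, got ", nchar(x))
    .checkDNA(x)
    .siteFromS(.revcompChar(substr(x, 2, 8)))
}

#' Site sequences from a 7-nt seed region
#'
#' Same site-type definitions as \code{\link{seedToSiteSequences}}, starting
#' from the seed region itself (microRNA positions 2-8).
#'
#' @param seedRegion 7-nt seed region sequence, 5' to 3', RNA or DNA.
#' @return named character vector of the four site sequences.
#' @export
siteSequencesFromSeed <- function(seedRegion) {
    x <- chartr("Uu", "Tt", toupper(seedRegion))
    if (nchar(x) != 7)
        stop("seed region must be exactly 7 nt, got ", nchar(x))
    .checkDNA(x)
    .siteFromS(.revcompChar(x))
}

.SITE_COLS <- c("8mer" = "site_8mer", "7mer-m8" = "site_7mer_m8",
                "7mer-A1" = "site_7mer_A1", "6mer" = "site_6mer")

#' Read a seed-motif table
#'
#' Reads the tab-separated microRNA family table (columns \code{family_id},
#' optionally \code{mirna_seq} and/or \code{seed_region}, optionally
#' precomputed site sequences \code{site_8mer}, \code{site_7mer_m8},
#' \code{site_7mer_A1}, \code{site_6mer}) and fills in any missing site
#' sequences from the seed region (or from the mature sequence when only that
#' is given). Families for which no site sequence can be derived are dropped
#' with a warning.
#'
#' @param path path to the TSV file.
#' @return a \link[S4Vectors]{DataFrame} with one row per family and the four
#'   site-sequence columns populated.
#' @export
readSeedMotifs <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (!"family_id" %in% colnames(tab))
        stop("motif table needs a family_id column")
    for (cl in c("mirna_seq", "seed_region", .SITE_COLS))
        if (!cl %in% colnames(tab)) tab[[cl]] <- NA_character_
    tab[tab == ""] <- NA
    for (i in seq_len(nrow(tab))) {
        if (all(!is.na(unlist(tab[i, .SITE_COLS])))) next
        derived <- if (!is.na(tab$seed_region[i]))
            siteSequencesFromSeed(tab$seed_region[i])
        else if (!is.na(tab$mirna_seq[i]))
            seedToSiteSequences(tab$mirna_seq[i])
        else NULL
        if (is.null(derived)) next
        for (tp in names(.SITE_COLS))
            if (is.na(tab[i, .SITE_COLS[tp]]))
                tab[i, .SITE_COLS[tp]] <- derived[tp]
    }
    empty <- apply(is.na(tab[, .SITE_COLS, drop = FALSE]), 1, all)
    if (any(empty)) {
        warning("dropping ", sum(empty),
                " motif(s) with no derivable site sequence: ",
                paste(utils::head(tab$family_id[empty], 5), collapse = ", "))
        tab <- tab[!empty, , drop = FALSE]
    }
    S4Vectors::DataFrame(tab)
}

.motifSiteSeqs <- function(motifs, siteTypes) {
    # named list: family -> named character of site seqs (requested types)
    out <- lapply(seq_len(nrow(motifs)), function(i) {
        s <- stats::setNames(
            as.character(unlist(motifs[i, .SITE_COLS[siteTypes]])),
            siteTypes)
        s[!is.na(s)]
    })
    stats::setNames(out, motifs$family_id)
}

#' Build the MRE catalog
#'
#' Enumerates every exact occurrence of every requested site sequence on
#' every gene's transcript-sense 3'UTR sequence. Overlapping occurrences are
#' all recorded, except that when a longer site of the same family fully
#' contains a shorter one at a locus, only the longest site is kept (an 8mer
#' locus is not additionally counted as a 7mer and a 6mer). \code{N} bases
#' never match. Site positions are 0-based offsets on the spliced UTR.
#'
#' @param utrs a \code{\linkS4class{UTRSet}}.
#' @param motifs a seed-motif table as returned by
#'   \code{\link{readSeedMotifs}} (any data.frame-like with \code{family_id}
#'   and the site-sequence columns works).
#' @param siteTypes subset of \code{c("8mer", "7mer-m8", "7mer-A1", "6mer")};
#'   default all four.
#' @return an \code{\linkS4class{MRECatalog}}.
#' @examples
#' utrs <- UTRSet(
#'   GenomicRanges::GRangesList(geneA = GenomicRanges::GRanges(
#'     "chr1", IRanges::IRanges(1, 12), "+")),
#'   Biostrings::DNAStringSet(c(geneA = "AAACATTCCAAA")))
#' motifs <- S4Vectors::DataFrame(family_id = "miR-1",
#'   t(siteSequencesFromSeed("GGAAUGU")))
#' colnames(motifs)[-1] <- c("site_8mer", "site_7mer_m8",
#'                           "site_7mer_A1", "site_6mer")
#' buildMRECatalog(utrs, motifs)
#' @export
buildMRECatalog <- function(utrs, motifs,
                            siteTypes = c("8mer", "7mer-m8",
                                          "7mer-A1", "6mer")) {
    siteTypes <- match.arg(siteTypes, .SITE_TYPES, several.ok = TRUE)
    fam <- .motifSiteSeqs(motifs, siteTypes)
    empty <- lengths(fam) == 0
    if (any(empty)) {
        warning("motif(s) without site sequences skipped: ",
                paste(names(fam)[empty], collapse = ", "))
        fam <- fam[!empty]
    }
    seqs <- utrSequences(utrs)
    rows <- list()
    for (f in names(fam)) {
        for (tp in names(fam[[f]])) {
            pat <- fam[[f]][[tp]]
            hits <- Biostrings::vmatchPattern(pat, seqs, fixed = TRUE)
            n <- lengths(hits)
            if (sum(n) == 0) next
            starts <- unlist(lapply(hits, BiocGenerics::start))
            rows[[length(rows) + 1L]] <- data.frame(
                gene_id = rep(names(seqs), n),
                family_id = f, site_type = tp,
                utr_offset = starts - 1L, site_seq = pat,
                stringsAsFactors = FALSE)
        }
    }
    sites <- if (length(rows)) do.call(rbind, rows) else
        data.frame(gene_id = character(), family_id = character(),
                   site_type = character(), utr_offset = integer(),
                   site_seq = character())
    sites <- .suppressContained(sites)
    o <- order(sites$gene_id, sites$family_id, sites$utr_offset,
               match(sites$site_type, .SITE_TYPES))
    sites <- sites[o, , drop = FALSE]
    rownames(sites) <- NULL
    methods::new("MRECatalog", sites = S4Vectors::DataFrame(sites),
                 genes = geneTable(utrs))
}

# Longest-site-wins: within one (gene, family), drop any occurrence whose
# interval is fully contained in a strictly longer occurrence; at identical
# intervals keep the highest-priority type (8mer first).
.suppressContained <- function(sites) {
    if (nrow(sites) == 0) return(sites)
    grp <- paste(sites$gene_id, sites$family_id, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(sites)), grp), function(idx) {
        if (length(idx) == 1) return(idx)
        len <- nchar(sites$site_seq[idx])
        ir <- IRanges::IRanges(start = sites$utr_offset[idx] + 1L,
                               width = len)
        hits <- IRanges::findOverlaps(ir, ir, type = "within")
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        contained <- unique(qh[len[qh] < len[sh]])
        idx2 <- idx[setdiff(seq_along(idx), contained)]
        # identical-interval ties: keep highest-priority site type
        key <- paste(sites$utr_offset[idx2], nchar(sites$site_seq[idx2]))
        pri <- match(sites$site_type[idx2], .SITE_TYPES)
        ord <- order(key, pri)
        idx2[ord][!duplicated(key[ord])]
    }))
    sites[sort(keep), , drop = FALSE]
}

#' MRE site table and keys
#'
#' @param x an \code{\linkS4class{MRECatalog}},
#'   \code{\linkS4class{MREExperiment}} or
#'   \code{\linkS4class{SelectionResult}}.
#' @param ... unused.
#' @return \code{mreSites}: the site-level \code{DataFrame} (one row per
#'   site). \code{mreKeys}: character \code{"gene|family"} keys, the
#'   gene-family unit at which read support is reported.
#' @name mreSites
#' @export
setMethod("mreSites", "MRECatalog", function(x) x@sites)

#' @rdname geneTable
#' @export
setMethod("geneTable", "MRECatalog", function(x, ...) x@genes)

#' @rdname mreSites
#' @name mreKeys
#' @export
setMethod("mreKeys", "MRECatalog", function(x, ...)
    unique(paste(x@sites$gene_id, x@sites$family_id, sep = "|")))

setMethod("length", "MRECatalog", function(x) nrow(x@sites))

setMethod("show", "MRECatalog", function(object) {
    cat("MRECatalog:", nrow(object@sites), "sites on",
        length(unique(object@sites$gene_id)), "genes /",
        length(unique(object@sites$family_id)), "microRNA families\n")
    if (nrow(object@sites)) {
        tb <- table(object@sites$site_type)
        cat("  site types:",
            paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
    }
    cat(" ", length(mreKeys(object)), "gene|family MRE keys\n")
})
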