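suppressPackageStartupMessages({
    library(S4Vectors)
    library(GenomicRanges)
    library(Biostrings)
    library(SummarizedExperiment)
})

# miR-1 site sequences, written out by hand from the seed definitions
mir1Motifs <- function() {
    S4Vectors::DataFrame(family_id = "miR-1",
                         site_8mer = "ACATTCCA", site_7mer_m8 = "ACATTCC",
                         site_7mer_A1 = "CATTCCA", site_6mer = "CATTCC")
}

# plus-strand single-interval UTRSet from named sequences, laid end to end
makeUTRSet <- function(seqs, gap = 25L) {
    L <- nchar(seqs)
    starts <- cumsum(c(gap, head(L + gap, -1)))  # 0-based
    grl <- GenomicRanges::GRangesList(setNames(lapply(
        seq_along(seqs), function(i)
            GenomicRanges::GRanges("chrT",
                IRanges::IRanges(starts[i] + 1L, starts[i] + L[i]),
                strand = "+")), names(seqs)))
    UTRSet(grl, Biostrings::DNAStringSet(seqs))
}

# independent oracle: 0-based offsets of exact (possibly overlapping)
# occurrences, by direct substring comparison
naiveFind <- function(seq, pat) {
    n <- nchar(seq); m <- nchar(pat)
    if (m > n) return(integer())
    which(vapply(seq_len(n - m + 1L),
                 function(i) substr(seq, i, i + m - 1L) == pat,
                 logical(1))) - 1L
}

randomDNA <- function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# small, fast simulation scenario used across test files
smallSimConfig <- function(...) {
    args <- list(nGenes = 8L, nFamilies = 6L, sitesPerGene = 2L,
                 utrLength = c(250L, 400L), nPerGroup = 3L, mu = 15,
                 readLength = 30L, backgroundReads = 1L, seed = 11L)
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(simConfig, args)
}

# MREExperiment straight from a counts matrix
makeMRE <- function(counts, groups, libSizes = colSums(counts)) {
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("g", seq_len(nrow(counts)), "|m1")
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    MREExperiment(counts, groups, libSizes)
}
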