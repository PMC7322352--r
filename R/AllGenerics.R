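#' GC fraction of DNA sequences
#'
#' Fraction of G+C among non-N bases. \code{N} bases are excluded from the
#' denominator; a sequence that is entirely \code{N} (or empty) is an error.
#' 3'UTR GC content is one of the two per-gene covariates (with length) that
#' the normalization stage removes from MRE counts.
#'
#' @param x a character vector of DNA strings (alphabet ACGTN, case
#'   insensitive), a \link[Biostrings]{DNAStringSet}, or a
#'   \code{\linkS4class{UTRSet}}.
#' @param ... unused.
#' @return numeric vector of fractions in [0, 1].
#' @examples
#' gcContent(c("GCGC", "ATAT", "ATGC"))
#' @export
setGeneric("gcContent", function(x, ...) standardGeneric("gcContent"))

#' @rdname geneTable
#' @export
setGeneric("geneTable", function(x, ...) standardGeneric("geneTable"))

#' @rdname mreKeys
#' @export
setGeneric("mreKeys", function(x, ...) standardGeneric("mreKeys"))

#' @rdname utrAccessors
#' @export
setGeneric("utrRanges", function(x) standardGeneric("utrRanges"))

#' @rdname utrAccessors
#' @export
setGeneric("utrSequences", function(x) standardGeneric("utrSequences"))

#' @rdname utrAccessors
#' @export
setGeneric("utrLengths", function(x) standardGeneric("utrLengths"))

#' @rdname utrAccessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname mreSites
#' @export
setGeneric("mreSites", function(x) standardGeneric("mreSites"))

#' @rdname mreExperimentAccessors
#' @export
setGeneric("mreCounts", function(x) standardGeneric("mreCounts"))

#' @rdname mreExperimentAccessors
#' @export
setGeneric("normValues", function(x) standardGeneric("normValues"))

#' @rdname mreExperimentAccessors
#' @export
setGeneric("libSizes", function(x) standardGeneric("libSizes"))

#' @rdname mreExperimentAccessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname SelectionResult-accessors
#' @export
setGeneric("dtkSelected", function(x) standardGeneric("dtkSelected"))

#' @rdname SelectionResult-accessors
#' @export
setGeneric("deSelected", function(x) standardGeneric("deSelected"))

#' @rdname SelectionResult-accessors
#' @export
setGeneric("specificSet", function(x) standardGeneric("specificSet"))

#' @rdname DecoupledSets-accessors
#' @export
setGeneric("decoupledGenes", function(x) standardGeneric("decoupledGenes"))

#' @rdname DecoupledSets-accessors
#' @export
setGeneric("decoupledMirnas", function(x) standardGeneric("decoupledMirnas"))

#' @rdname DecoupledSets-accessors
#' @export
setGeneric("decoupledPairs", function(x) standardGeneric("decoupledPairs"))

#' @rdname DecoupledSets-accessors
#' @export
setGeneric("geneMultiplicity", function(x) standardGeneric("geneMultiplicity"))
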