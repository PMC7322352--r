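#' Decouple an MRE set into mRNA and microRNA partners
#'
#' Every MRE is an interaction site between one mRNA and one microRNA
#' family; decoupling a selected set recovers its unique gene list, unique
#' microRNA list, the pair table and the per-gene multiplicity (how many
#' distinct selected MREs sit on each gene). All outputs are in
#' deterministic lexicographic order and the operation is idempotent.
#'
#' @param x character vector of \code{"gene|family"} keys, or a
#'   \code{\linkS4class{SelectionResult}} (its condition-specific set is
#'   used).
#' @return a \code{\linkS4class{DecoupledSets}}.
#' @examples
#' d <- decoupleMRE(c("A|m1", "A|m2", "B|m1"))
#' decoupledGenes(d)
#' geneMultiplicity(d)
#' @export
decoupleMRE <- function(x) {
    if (methods::is(x, "SelectionResult")) x <- specificSet(x)
    keys <- sort(unique(as.character(x)))
    if (!length(keys))
        return(methods::new("DecoupledSets", genes = character(),
                            mirnas = character(),
                            pairs = data.frame(gene_id = character(),
                                               family_id = character(),
                                               stringsAsFactors = FALSE),
                            multiplicity = stats::setNames(integer(),
                                                           character())))
    parts <- .parseKeys(keys)
    pairs <- data.frame(gene_id = parts$gene_id,
                        family_id = parts$family_id,
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$gene_id, pairs$family_id), , drop = FALSE]
    rownames(pairs) <- NULL
    mult <- table(pairs$gene_id)
    methods::new("DecoupledSets",
                 genes = sort(unique(pairs$gene_id)),
                 mirnas = sort(unique(pairs$family_id)),
                 pairs = pairs,
                 multiplicity = stats::setNames(as.integer(mult),
                                                names(mult)))
}

#' Genes with multiple selected MREs
#'
#' Number of genes carrying at least \code{minSites} distinct selected MREs
#' -- mRNAs used repeatedly as interaction hubs by different microRNAs.
#'
#' @param x a \code{\linkS4class{DecoupledSets}}.
#' @param minSites threshold (default 2).
#' @return integer count.
#' @export
multiplicitySummary <- function(x, minSites = 2L) {
    stopifnot(methods::is(x, "DecoupledSets"))
    sum(x@multiplicity >= minSites)
}

#' DecoupledSets accessors
#'
#' @param x a \code{\linkS4class{DecoupledSets}}.
#' @return \code{decoupledGenes} / \code{decoupledMirnas}: sorted unique id
#'   vectors; \code{decoupledPairs}: the pair data.frame;
#'   \code{geneMultiplicity}: named integer vector.
#' @name DecoupledSets-accessors
NULL

#' @rdname DecoupledSets-accessors
#' @export
setMethod("decoupledGenes", "DecoupledSets", function(x) x@genes)

#' @rdname DecoupledSets-accessors
#' @export
setMethod("decoupledMirnas", "DecoupledSets", function(x) x@mirnas)

#' @rdname DecoupledSets-accessors
#' @export
setMethod("decoupledPairs", "DecoupledSets", function(x) x@pairs)

#' @rdname DecoupledSets-accessors
#' @export
setMethod("geneMultiplicity", "DecoupledSets", function(x) x@multiplicity)

setMethod("show", "DecoupledSets", function(object) {
    cat("DecoupledSets:", nrow(object@pairs), "MRE pairs ->",
        length(object@genes), "mRNAs,",
        length(object@mirnas), "microRNAs;",
        multiplicitySummary(object), "gene(s) with >= 2 MREs\n")
})
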