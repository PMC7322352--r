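#' Intersect the two selection routes
#'
#' Condition-specific MREs are those flagged by both complementary
#' approaches: target-specific under the pairwise multiple-comparison (DTK)
#' route on normalized values, and differentially expressed under the NB
#' exact-test route on raw counts. The intersection is deliberately
#' conservative -- an MRE must stand out against every other group and show
#' a large, well-supported tumor/normal fold change.
#'
#' @param dtkSet character vector of MRE keys from
#'   \code{\link{selectTargetSpecific}} (or any key set).
#' @param deSet character vector of MRE keys passing the differential
#'   thresholds.
#' @param dtk,de optional full per-MRE tables to carry along for reporting.
#' @return a \code{\linkS4class{SelectionResult}}.
#' @examples
#' intersectSelections(c("a|m1", "b|m1", "c|m2"), c("b|m1", "c|m2", "d|m3"))
#' @export
intersectSelections <- function(dtkSet, deSet,
                                dtk = S4Vectors::DataFrame(),
                                de = S4Vectors::DataFrame()) {
    methods::new("SelectionResult",
                 dtkSet = sort(unique(dtkSet)),
                 deSet = sort(unique(deSet)),
                 specificSet = sort(intersect(dtkSet, deSet)),
                 dtk = dtk, de = de)
}

#' Apply the differential thresholds to a deTest table
#'
#' @param de result of \code{\link{deTest}}.
#' @param maxFDR FDR threshold (default 0.05).
#' @param minLog2FC minimum absolute log2 fold change (default 2).
#' @return character vector of passing MRE keys.
#' @export
deSelect <- function(de, maxFDR = 0.05, minLog2FC = 2) {
    sort(de$key[de$fdr < maxFDR & abs(de$log2FC) >= minLog2FC])
}

#' SelectionResult accessors
#'
#' @param x a \code{\linkS4class{SelectionResult}}.
#' @return \code{dtkSelected} / \code{deSelected} / \code{specificSet}:
#'   the respective key sets.
#' @name SelectionResult-accessors
NULL

#' @rdname SelectionResult-accessors
#' @export
setMethod("dtkSelected", "SelectionResult", function(x) x@dtkSet)

#' @rdname SelectionResult-accessors
#' @export
setMethod("deSelected", "SelectionResult", function(x) x@deSet)

#' @rdname SelectionResult-accessors
#' @export
setMethod("specificSet", "SelectionResult", function(x) x@specificSet)

#' @rdname mreSites
#' @export
setMethod("mreKeys", "SelectionResult", function(x, ...) x@specificSet)

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult\n")
    cat("  DTK-selected MREs:         ", length(object@dtkSet), "\n")
    cat("  differentially expressed:  ", length(object@deSet), "\n")
    cat("  condition-specific (both): ", length(object@specificSet), "\n")
})
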