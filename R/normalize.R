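#' Library-size and length adjustment of raw MRE counts
#'
#' First normalization stage: an RPKM-like log2 value,
#' \code{y = log2(c + pseudocount) - log2(N_s / 1e6) - log2(L_g / 1e3)},
#' where \code{N_s} is the sample's UTR-restricted library size and
#' \code{L_g} the 3'UTR length of the row's gene. The pseudocount keeps
#' zero counts finite.
#'
#' @param counts numeric matrix of raw MRE counts, rows keyed
#'   \code{"gene|family"}.
#' @param libSizes per-sample library sizes (same order as columns).
#' @param geneLengths named numeric vector of 3'UTR lengths by gene id.
#' @param pseudocount added to counts before the log (default 0.5).
#' @return numeric matrix of log2 values, same shape as \code{counts}.
#' @export
baseNormalize <- function(counts, libSizes, geneLengths, pseudocount = 0.5) {
    counts <- as.matrix(counts)
    if (any(libSizes <= 0))
        stop("sample(s) with zero library size must be excluded: ",
             paste(colnames(counts)[libSizes <= 0], collapse = ", "))
    genes <- .parseKeys(rownames(counts))$gene_id
    L <- geneLengths[genes]
    if (any(is.na(L)))
        stop("no UTR length for gene(s): ",
             paste(utils::head(unique(genes[is.na(L)]), 5), collapse = ", "))
    if (any(L <= 0)) stop("non-positive UTR length")
    y <- log2(counts + pseudocount)
    y <- sweep(y, 2, log2(libSizes / 1e6), "-")
    sweep(y, 1, log2(L / 1e3), "-")
}

# merge adjacent GC bins until every occupied bin holds >= minSites rows
.mergeBins <- function(gc, edges, minSites) {
    repeat {
        bin <- findInterval(gc, edges, rightmost.closed = TRUE,
                            all.inside = TRUE)
        cnt <- tabulate(bin, nbins = length(edges) - 1L)
        if (length(cnt) == 1L || all(cnt >= minSites)) return(edges)
        i <- which.min(cnt)
        # drop the edge shared with the smaller adjacent bin
        drop <- if (i == 1L) 2L
                else if (i == length(cnt)) length(cnt)
                else if (cnt[i - 1L] <= cnt[i + 1L]) i else i + 1L
        edges <- edges[-drop]
    }
}

#' Fit the per-sample GC correction
#'
#' Models the sample-specific GC effect that remains after library-size and
#' length adjustment: rows are binned by their gene's 3'UTR GC fraction
#' (equal-width bins on [0, 1], small bins merged with a neighbor until each
#' holds at least \code{minSites} rows), and for each sample the within-bin
#' median of the adjusted log2 values is recorded along with the grand
#' (across-sample) bin median. The correction later subtracted is the
#' difference of the two, interpolated between bin centers.
#'
#' A sample whose values are all identical carries no usable GC signal; its
#' offsets are forced to zero with a warning.
#'
#' @param yPre matrix from \code{\link{baseNormalize}}.
#' @param gc numeric vector of per-row GC fractions (the row's gene's
#'   \code{gc_g}).
#' @param bins number of equal-width GC bins before merging (default 20).
#' @param minSites minimum rows per fitted bin (default 50).
#' @param pseudocount recorded in the model for provenance.
#' @return a \code{\linkS4class{GCNormModel}}.
#' @export
fitGCCorrection <- function(yPre, gc, bins = 20L, minSites = 50L,
                            pseudocount = 0.5) {
    yPre <- as.matrix(yPre)
    if (ncol(yPre) < 2) stop("need at least 2 samples to fit a GC model")
    if (length(gc) != nrow(yPre)) stop("one gc value per row required")
    if (any(gc < 0 | gc > 1)) stop("gc outside [0,1]")
    edges <- .mergeBins(gc, seq(0, 1, length.out = bins + 1L), minSites)
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    bin <- findInterval(gc, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    m <- matrix(NA_real_, ncol(yPre), length(centers),
                dimnames = list(colnames(yPre), NULL))
    for (b in seq_along(centers)) {
        idx <- which(bin == b)
        m[, b] <- if (length(idx))
            apply(yPre[idx, , drop = FALSE], 2, stats::median) else 0
    }
    grand <- apply(m, 2, stats::median)
    flat <- apply(yPre, 2, function(v) length(unique(v)) == 1L)
    if (any(flat)) {
        warning("sample(s) with all-identical values get zero GC offsets: ",
                paste(colnames(yPre)[flat], collapse = ", "))
        m[flat, ] <- rep(grand, each = sum(flat))
    }
    methods::new("GCNormModel", pseudocount = pseudocount, edges = edges,
                 centers = centers, sampleMedians = m, grandMedians = grand)
}

#' Apply a fitted GC correction
#'
#' Subtracts the sample-specific GC offset: for sample s and a row with GC
#' fraction g, the offset is the linear interpolation of
#' \code{sampleMedians[s, ] - grandMedians} between bin centers, held
#' constant beyond the outer centers. At a bin center the offset is exactly
#' the sample's departure from the grand bin median, so corrected bin
#' medians line up across samples there.
#'
#' @param yPre matrix from \code{\link{baseNormalize}}.
#' @param model a \code{\linkS4class{GCNormModel}}.
#' @param gc per-row GC fractions (same universe the model was fitted on).
#' @return the corrected log2 matrix.
#' @export
applyGCCorrection <- function(yPre, model, gc) {
    yPre <- as.matrix(yPre)
    if (any(gc < 0 | gc > 1)) stop("gc outside [0,1]")
    off <- sweep(model@sampleMedians, 2, model@grandMedians, "-")
    y <- yPre
    for (s in seq_len(ncol(yPre))) {
        delta <- if (length(model@centers) == 1L)
            rep(off[s, 1L], length(gc))
        else
            stats::approx(model@centers, off[s, ], xout = gc,
                          rule = 2)$y
        y[, s] <- yPre[, s] - delta
    }
    y
}

#' Normalize an MREExperiment
#'
#' Full normalization: library-size/length adjustment
#' (\code{\link{baseNormalize}}) followed by the binned-median GC correction
#' (\code{\link{fitGCCorrection}} + \code{\link{applyGCCorrection}}), using
#' the per-gene covariates of the catalog's gene table. Adds a
#' \code{"normalized"} assay and stores the fitted model in
#' \code{metadata(x)$gcnorm}.
#'
#' @param x an \code{\linkS4class{MREExperiment}}.
#' @param genes per-gene covariates: an \code{\linkS4class{MRECatalog}},
#'   \code{\linkS4class{UTRSet}} or a \code{DataFrame}/data.frame with
#'   columns \code{gene_id}, \code{length}, \code{gc}.
#' @param pseudocount,bins,minSites see the stage functions.
#' @return \code{x} with the added assay and model.
#' @export
normalizeMRE <- function(x, genes, pseudocount = 0.5, bins = 20L,
                         minSites = 50L) {
    gt <- if (methods::is(genes, "MRECatalog") ||
              methods::is(genes, "UTRSet")) geneTable(genes) else genes
    L <- stats::setNames(as.numeric(gt$length), gt$gene_id)
    gcg <- stats::setNames(as.numeric(gt$gc), gt$gene_id)
    rg <- SummarizedExperiment::rowData(x)$gene_id
    yPre <- baseNormalize(mreCounts(x), libSizes(x), L, pseudocount)
    model <- fitGCCorrection(yPre, gcg[rg], bins = bins,
                             minSites = minSites,
                             pseudocount = pseudocount)
    SummarizedExperiment::assay(x, "normalized") <-
        applyGCCorrection(yPre, model, gcg[rg])
    S4Vectors::metadata(x)$gcnorm <- model
    methods::validObject(x)
    x
}

setMethod("show", "GCNormModel", function(object) {
    cat("GCNormModel:", length(object@centers), "GC bin(s),",
        nrow(object@sampleMedians), "samples; pseudocount",
        object@pseudocount, "\n")
})
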