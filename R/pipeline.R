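#' Run the full selection pipeline on an MREExperiment
#'
#' Normalization, the two selection routes and their intersection, and
#' decoupling, in one call: (1) library-size/length/GC normalization; (2)
#' DTK pairwise multiple comparisons across all groups on the normalized
#' values, keeping MREs significant and sign-consistent against the target
#' group in every pairwise comparison; (3) the NB exact differential test
#' on raw counts between the target tumor group and its normal-adjacent
#' group, thresholded at FDR < \code{maxFDR} and |log2FC| >=
#' \code{minLog2FC}; (4) intersection; (5) decoupling into mRNA and
#' microRNA partner sets.
#'
#' @param mre an \code{\linkS4class{MREExperiment}} with raw counts.
#' @param genes per-gene covariates (catalog, UTRSet or table) for
#'   normalization.
#' @param targetGroup group whose specific MREs are sought (DTK route).
#' @param normalGroup comparison group for the differential route
#'   (typically the target's normal-adjacent group).
#' @param alpha DTK family-wise error target (default 0.05).
#' @param maxFDR,minLog2FC differential thresholds (defaults 0.05 and 2).
#' @param pseudocount,bins,minSites normalization settings.
#' @param requireSignConsistency DTK sign-consistency rule (default TRUE).
#' @return list with \code{mre} (normalized), \code{dtk}, \code{dtkSet},
#'   \code{de}, \code{deSet}, \code{selection}
#'   (\code{\linkS4class{SelectionResult}}) and \code{decoupled}
#'   (\code{\linkS4class{DecoupledSets}}).
#' @export
runPipeline <- function(mre, genes, targetGroup, normalGroup,
                        alpha = 0.05, maxFDR = 0.05, minLog2FC = 2,
                        pseudocount = 0.5, bins = 20L, minSites = 50L,
                        requireSignConsistency = TRUE) {
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
    if (maxFDR <= 0 || maxFDR > 1) stop("maxFDR must be in (0,1]")
    mre <- normalizeMRE(mre, genes, pseudocount = pseudocount,
                        bins = bins, minSites = minSites)
    dtk <- dtkTest(normValues(mre), sampleGroups(mre), alpha = alpha)
    dtkSet <- selectTargetSpecific(dtk, targetGroup,
                                   requireSignConsistency)
    de <- deTest(mre, targetGroup, normalGroup)
    deSet <- deSelect(de, maxFDR = maxFDR, minLog2FC = minLog2FC)
    sel <- intersectSelections(dtkSet, deSet, dtk = dtk, de = de)
    list(mre = mre, dtk = dtk, dtkSet = dtkSet, de = de, deSet = deSet,
         selection = sel, decoupled = decoupleMRE(sel))
}

.writeTSV <- function(x, path) {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write pipeline outputs as TSV files
#'
#' Writes the standard stage outputs into a directory: catalog and gene
#' tables, counts and library sizes, normalized values and the GC model
#' (JSON), per-pair DTK statistics, per-MRE differential statistics, the
#' selection table and the four decoupling tables. All files have header
#' rows and deterministic column order.
#'
#' @param res result list of \code{\link{runPipeline}}.
#' @param dir output directory (created if needed).
#' @param catalog optional \code{\linkS4class{MRECatalog}} to include.
#' @return invisible named vector of written paths.
#' @export
writeResults <- function(res, dir, catalog = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c()
    if (!is.null(catalog)) {
        paths["catalog"] <- .writeTSV(mreSites(catalog),
                                      file.path(dir, "catalog.tsv"))
        paths["genes"] <- .writeTSV(geneTable(catalog),
                                    file.path(dir, "gene_table.tsv"))
    }
    cts <- data.frame(key = rownames(res$mre), mreCounts(res$mre),
                      check.names = FALSE)
    paths["counts"] <- .writeTSV(cts, file.path(dir, "counts.tsv"))
    paths["libsizes"] <- .writeTSV(
        data.frame(sample_id = colnames(res$mre),
                   group = unname(sampleGroups(res$mre)),
                   lib_size = unname(libSizes(res$mre))),
        file.path(dir, "library_sizes.tsv"))
    nrm <- data.frame(key = rownames(res$mre), normValues(res$mre),
                      check.names = FALSE)
    paths["normalized"] <- .writeTSV(nrm, file.path(dir, "normalized.tsv"))
    model <- S4Vectors::metadata(res$mre)$gcnorm
    jsonlite::write_json(
        list(pseudocount = model@pseudocount, edges = model@edges,
             centers = model@centers,
             sample_medians = model@sampleMedians,
             grand_medians = model@grandMedians),
        file.path(dir, "gcnorm_model.json"), digits = NA)
    paths["gcmodel"] <- file.path(dir, "gcnorm_model.json")
    paths["dtk"] <- .writeTSV(res$dtk, file.path(dir, "dtk.tsv"))
    paths["de"] <- .writeTSV(res$de, file.path(dir, "de.tsv"))
    allKeys <- rownames(res$mre)
    paths["selection"] <- .writeTSV(
        data.frame(key = allKeys,
                   in_dtk = allKeys %in% res$dtkSet,
                   in_de = allKeys %in% res$deSet,
                   selected = allKeys %in% specificSet(res$selection)),
        file.path(dir, "selection.tsv"))
    d <- res$decoupled
    paths["genes_out"] <- .writeTSV(
        data.frame(gene_id = decoupledGenes(d)),
        file.path(dir, "genes.tsv"))
    paths["mirnas"] <- .writeTSV(
        data.frame(family_id = decoupledMirnas(d)),
        file.path(dir, "mirnas.tsv"))
    paths["pairs"] <- .writeTSV(decoupledPairs(d),
                                file.path(dir, "pairs.tsv"))
    paths["multiplicity"] <- .writeTSV(
        data.frame(gene_id = names(geneMultiplicity(d)),
                   n_mres = unname(geneMultiplicity(d))),
        file.path(dir, "multiplicity.tsv"))
    invisible(paths)
}

#' Read a counts TSV back into an MREExperiment
#'
#' Counterpart of the files written by \code{\link{writeResults}}: a counts
#' TSV (column \code{key} plus one column per sample) and a sample sheet
#' (\code{sample_id}, \code{group}, optional \code{lib_size}; library sizes
#' default to column sums).
#'
#' @param countsPath path to the counts TSV.
#' @param samplesPath path to the sample sheet TSV.
#' @return an \code{\linkS4class{MREExperiment}}.
#' @export
readCounts <- function(countsPath, samplesPath) {
    cts <- utils::read.delim(countsPath, check.names = FALSE)
    ss <- utils::read.delim(samplesPath, check.names = FALSE)
    if (!all(c("sample_id", "group") %in% colnames(ss)))
        stop("sample sheet needs sample_id and group columns")
    m <- as.matrix(cts[, ss$sample_id, drop = FALSE])
    rownames(m) <- cts$key
    libs <- if ("lib_size" %in% colnames(ss)) ss$lib_size else colSums(m)
    MREExperiment(m, ss$group, libs)
}
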