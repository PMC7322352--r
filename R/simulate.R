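#' Simulation configuration
#'
#' Parameters of the ground-truthed synthetic study. The defaults emulate a
#' three-subtype tumor / normal-adjacent design: six groups of 13 samples, a
#' universe of genes carrying a handful of planted seed-match sites each,
#' negative-binomially distributed read support, and a 10 percent fraction
#' of (gene, family) rows planted with a target-group-specific effect of
#' |log2FC| = 3.
#'
#' @param nGenes number of genes (default 200).
#' @param nFamilies number of microRNA families (default 50).
#' @param sitesPerGene planted sites (distinct families) per gene
#'   (default 5).
#' @param utrLength integer range of UTR lengths (default c(500, 2000)).
#' @param gcRange range of per-gene GC targets (default c(0.3, 0.7)).
#' @param groups group labels (default six: TN/ER/HER2 x tumor/normal).
#' @param nPerGroup samples per group, scalar or per-group vector
#'   (default 13).
#' @param targetGroup group receiving the planted effect (default
#'   "TN_tumor").
#' @param plantedFraction fraction of (gene, family) rows planted with the
#'   effect (default 0.1).
#' @param effectSize absolute log2 fold change of planted rows (default 3);
#'   direction is random per row.
#' @param mu baseline NB mean per row (default 100).
#' @param phi NB dispersion (default 0.2); 0 gives Poisson counts.
#' @param readLength simulated read length (default 50); also the minimum
#'   spacing between planted sites so one read never spans two sites.
#' @param sizeFactorRange range of per-sample depth multipliers, sampled
#'   log-uniformly (default c(0.75, 1.35)).
#' @param backgroundReads site-free reads per gene per sample in read-level
#'   simulation (default 2).
#' @param seed integer RNG seed; every simulation stage derives its stream
#'   from it.
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nGenes = 200L, nFamilies = 50L, sitesPerGene = 5L,
                      utrLength = c(500L, 2000L), gcRange = c(0.3, 0.7),
                      groups = c("TN_tumor", "TN_normal", "ER_tumor",
                                 "ER_normal", "HER2_tumor", "HER2_normal"),
                      nPerGroup = 13L, targetGroup = "TN_tumor",
                      plantedFraction = 0.1, effectSize = 3,
                      mu = 100, phi = 0.2, readLength = 50L,
                      sizeFactorRange = c(0.75, 1.35),
                      backgroundReads = 2L, seed = 1L) {
    cfg <- list(nGenes = as.integer(nGenes),
                nFamilies = as.integer(nFamilies),
                sitesPerGene = as.integer(sitesPerGene),
                utrLength = as.integer(utrLength),
                gcRange = as.numeric(gcRange),
                groups = as.character(groups),
                nPerGroup = as.integer(rep(nPerGroup,
                                           length.out = length(groups))),
                targetGroup = targetGroup,
                plantedFraction = plantedFraction,
                effectSize = effectSize, mu = mu, phi = phi,
                readLength = as.integer(readLength),
                sizeFactorRange = as.numeric(sizeFactorRange),
                backgroundReads = as.integer(backgroundReads),
                seed = as.integer(seed))
    stopifnot(cfg$nGenes > 0, cfg$nFamilies > 0,
              cfg$sitesPerGene <= cfg$nFamilies,
              length(cfg$utrLength) == 2, cfg$utrLength[1] > 0,
              diff(cfg$utrLength) >= 0,
              all(cfg$gcRange >= 0 & cfg$gcRange <= 1),
              cfg$targetGroup %in% cfg$groups,
              cfg$plantedFraction >= 0, cfg$plantedFraction <= 1,
              cfg$mu > 0, cfg$phi >= 0, cfg$readLength >= 6,
              all(cfg$nPerGroup >= 2), cfg$seed < 2^31 - 10)
    minLen <- cfg$sitesPerGene * (8L + cfg$readLength) + cfg$readLength
    if (cfg$utrLength[1] < minLen)
        stop("UTR length range too short for ", cfg$sitesPerGene,
             " spaced sites at read length ", cfg$readLength,
             "; need at least ", minLen, " nt")
    class(cfg) <- "SimConfig"
    cfg
}

.randSeq <- function(n, gc) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
          collapse = "")
}

# exact-composition sequence: round(gc*n) G/C bases, shuffled
.exactGCSeq <- function(n, gc) {
    ngc <- round(gc * n)
    gcb <- sample(c("G", "C"), ngc, replace = TRUE)
    atb <- sample(c("A", "T"), n - ngc, replace = TRUE)
    paste(sample(c(gcb, atb)), collapse = "")
}

# draw seed regions whose derived site sequences never contain another
# family's site (either orientation), so planted sites are family-exclusive
.drawSeeds <- function(nFamilies) {
    seeds <- vapply(seq_len(nFamilies), function(i)
        paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE),
              collapse = ""), character(1))
    for (iter in 1:200) {
        sitesBy <- lapply(seeds, .siteFromS2)
        bad <- rep(FALSE, nFamilies)
        allSix <- lapply(sitesBy, function(s)
            unique(c(s, .revcompChar(s))))
        for (a in seq_len(nFamilies)) {
            for (b in seq_len(nFamilies)) {
                if (a == b) next
                hit <- any(vapply(allSix[[b]], function(p)
                    any(grepl(p, sitesBy[[a]], fixed = TRUE)),
                    logical(1)))
                if (hit) { bad[a] <- TRUE; bad[b] <- TRUE }
            }
        }
        if (anyDuplicated(seeds)) bad[duplicated(seeds)] <- TRUE
        if (!any(bad)) return(seeds)
        seeds[bad] <- vapply(seq_len(sum(bad)), function(i)
            paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE),
                  collapse = ""), character(1))
    }
    stop("could not draw conflict-free seed regions")
}

.siteFromS2 <- function(seed) .siteFromS(.revcompChar(seed))

# all-pattern scanner used by the cleaning loop: pdicts per width
.buildPatternIndex <- function(siteTab) {
    pats <- data.frame(seq = c(siteTab$site_seq,
                               .revcompChar(siteTab$site_seq)),
                       family_id = rep(siteTab$family_id, 2),
                       orient = rep(c("+", "-"),
                                    each = nrow(siteTab)),
                       stringsAsFactors = FALSE)
    pats <- unique(pats)
    lapply(split(pats, nchar(pats$seq)), function(tab)
        list(tab = tab, pd = Biostrings::PDict(tab$seq)))
}

.scanAllPatterns <- function(seqChar, patIndex) {
    subj <- Biostrings::DNAString(seqChar)
    hits <- list()
    for (w in names(patIndex)) {
        tab <- patIndex[[w]]$tab
        m <- Biostrings::matchPDict(patIndex[[w]]$pd, subj)
        n <- lengths(m)
        if (sum(n) == 0) next
        hits[[w]] <- data.frame(
            start = unlist(lapply(m, BiocGenerics::start)) - 1L,
            width = as.integer(w),
            family_id = rep(tab$family_id, n),
            orient = rep(tab$orient, n),
            stringsAsFactors = FALSE)
    }
    if (length(hits)) do.call(rbind, hits) else
        data.frame(start = integer(), width = integer(),
                   family_id = character(), orient = character())
}

#' Generate a ground-truthed synthetic annotation
#'
#' Produces random 3'UTR sequences with requested length and GC
#' distributions, plants one seed-match site per chosen (gene, family) pair
#' by literal insertion, and writes genome FASTA, BED6 and seed-motif TSV.
#' Background sequence is iteratively resampled until the only site-sequence
#' occurrences anywhere on a UTR (either orientation) lie inside planted
#' sites of their own family, so the planted site list is exactly what
#' \code{\link{buildMRECatalog}} recovers and read-level counts carry no
#' stochastic false support. Planted sites are spaced at least one read
#' length apart. With a degenerate GC range (e.g. \code{c(0.5, 0.5)}) and no
#' planted sites the background has exact base composition.
#'
#' @param config a \code{\link{simConfig}}.
#' @param dir output directory (created if needed).
#' @return list with \code{paths} (fasta, bed, motifs), \code{utrs}
#'   (\code{\linkS4class{UTRSet}}), \code{truthSites} (data.frame of planted
#'   sites: gene_id, family_id, site_type, utr_offset, site_seq),
#'   \code{motifs} and the echoed \code{config}.
#' @export
simulateAnnotation <- function(config, dir = tempfile("simann")) {
    stopifnot(inherits(config, "SimConfig"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config$seed)
    seeds <- .drawSeeds(config$nFamilies)
    famIds <- sprintf("fam%03d", seq_len(config$nFamilies))
    siteSets <- lapply(seeds, .siteFromS2)
    names(siteSets) <- famIds

    geneIds <- sprintf("gene%04d", seq_len(config$nGenes))
    lenRange <- seq(config$utrLength[1], config$utrLength[2])
    L <- lenRange[sample.int(length(lenRange), config$nGenes,
                             replace = TRUE)]
    gcTarget <- stats::runif(config$nGenes, config$gcRange[1],
                             config$gcRange[2])
    minGap <- config$readLength

    truth <- list(); seqs <- character(config$nGenes)
    siteTabAll <- data.frame(family_id = rep(famIds, each = 4),
                             site_seq = unlist(siteSets),
                             stringsAsFactors = FALSE)
    patIndex <- .buildPatternIndex(siteTabAll)

    for (gi in seq_len(config$nGenes)) {
        nS <- config$sitesPerGene
        fams <- if (nS > 0) sort(sample(config$nFamilies, nS)) else integer()
        types <- sample(.SITE_TYPES, nS, replace = TRUE)
        siteSeqs <- vapply(seq_len(nS), function(k)
            siteSets[[fams[k]]][[types[k]]], character(1))
        slen <- nchar(siteSeqs)
        if (nS > 0) {
            spare <- L[gi] - sum(slen) - (nS + 1) * minGap
            gaps <- minGap + as.vector(stats::rmultinom(
                1, spare, rep(1, nS + 1)))
            starts <- cumsum(c(0, slen)) [seq_len(nS)] +
                cumsum(gaps[seq_len(nS)])
        } else starts <- integer()
        plantedIR <- IRanges::IRanges(start = starts + 1L, width = slen)
        # assemble: exact-GC background when nothing is planted
        if (nS == 0) {
            seqChar <- if (config$gcRange[1] == config$gcRange[2])
                .exactGCSeq(L[gi], gcTarget[gi])
            else .randSeq(L[gi], gcTarget[gi])
        } else {
            base <- strsplit(.randSeq(L[gi], gcTarget[gi]), "")[[1]]
            for (k in seq_len(nS))
                base[(starts[k] + 1):(starts[k] + slen[k])] <-
                    strsplit(siteSeqs[k], "")[[1]]
            seqChar <- paste(base, collapse = "")
        }
        plantedFam <- if (nS > 0) famIds[fams] else character()
        seqChar <- .cleanSequence(seqChar, patIndex, plantedIR,
                                  plantedFam, gcTarget[gi],
                                  exact = config$gcRange[1] ==
                                          config$gcRange[2])
        seqs[gi] <- seqChar
        if (nS > 0)
            truth[[gi]] <- data.frame(
                gene_id = geneIds[gi], family_id = famIds[fams],
                site_type = types, utr_offset = starts,
                site_seq = siteSeqs, stringsAsFactors = FALSE)
    }
    truthSites <- if (length(truth)) do.call(rbind, truth) else
        data.frame(gene_id = character(), family_id = character(),
                   site_type = character(), utr_offset = integer(),
                   site_seq = character())
    rownames(truthSites) <- NULL

    # lay genes on one synthetic chromosome, alternating strands
    spacer <- 100L
    strand <- rep(c("+", "-"), length.out = config$nGenes)
    gStart <- cumsum(c(spacer, utils::head(L + spacer, -1)))  # 0-based
    chromLen <- sum(L) + spacer * (config$nGenes + 1L)
    chrom <- paste(rep("T", chromLen), collapse = "")
    chromVec <- strsplit(chrom, "")[[1]]
    for (gi in seq_len(config$nGenes)) {
        s <- if (strand[gi] == "+") seqs[gi] else .revcompChar(seqs[gi])
        chromVec[(gStart[gi] + 1):(gStart[gi] + L[gi])] <-
            strsplit(s, "")[[1]]
    }
    fastaPath <- file.path(dir, "genome.fa")
    bedPath <- file.path(dir, "utrs.bed")
    motifPath <- file.path(dir, "motifs.tsv")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(
        stats::setNames(paste(chromVec, collapse = ""), "chrSim")),
        fastaPath)
    writeLines(paste("chrSim", gStart, gStart + L, geneIds, 0L, strand,
                     sep = "\t"), bedPath)
    motifs <- data.frame(family_id = famIds,
                         seed_region = chartr("T", "U", seeds),
                         stringsAsFactors = FALSE)
    utils::write.table(motifs, motifPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    grl <- GenomicRanges::GRangesList(stats::setNames(lapply(
        seq_len(config$nGenes), function(gi)
            GenomicRanges::GRanges("chrSim",
                IRanges::IRanges(gStart[gi] + 1L, gStart[gi] + L[gi]),
                strand = strand[gi])), geneIds))
    utrs <- UTRSet(grl, Biostrings::DNAStringSet(
        stats::setNames(seqs, geneIds)))
    list(paths = list(fasta = fastaPath, bed = bedPath,
                      motifs = motifPath),
         utrs = utrs, truthSites = truthSites,
         motifs = S4Vectors::DataFrame(motifs), config = config)
}

# resample background bases until every site-sequence occurrence lies
# inside a planted site of its own family; in exact mode offending bases
# are swapped with random background positions, preserving composition
.cleanSequence <- function(seqChar, patIndex, plantedIR, plantedFam, gc,
                           exact = FALSE) {
    base <- strsplit(seqChar, "")[[1]]
    plantedPos <- unlist(lapply(seq_along(plantedIR), function(k)
        seq(BiocGenerics::start(plantedIR)[k],
            BiocGenerics::end(plantedIR)[k])))
    for (iter in 1:200) {
        hits <- .scanAllPatterns(paste(base, collapse = ""), patIndex)
        if (nrow(hits) == 0) return(paste(base, collapse = ""))
        ir <- IRanges::IRanges(start = hits$start + 1L, width = hits$width)
        ok <- rep(FALSE, nrow(hits))
        if (length(plantedIR)) {
            within <- IRanges::findOverlaps(ir, plantedIR, type = "within")
            famOK <- hits$family_id[S4Vectors::queryHits(within)] ==
                plantedFam[S4Vectors::subjectHits(within)]
            ok[unique(S4Vectors::queryHits(within)[famOK])] <- TRUE
        }
        if (all(ok)) return(paste(base, collapse = ""))
        badPos <- unique(unlist(lapply(which(!ok), function(i)
            seq(hits$start[i] + 1L, hits$start[i] + hits$width[i]))))
        badPos <- setdiff(badPos, plantedPos)
        if (exact) {
            free <- setdiff(seq_along(base), c(plantedPos, badPos))
            donors <- sample(free, min(length(free), length(badPos)))
            take <- seq_along(donors)
            tmp <- base[badPos[take]]
            base[badPos[take]] <- base[donors]
            base[donors] <- tmp
        } else {
            p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
            base[badPos] <- sample(c("A", "C", "G", "T"), length(badPos),
                                   replace = TRUE, prob = p)
        }
    }
    stop("background cleaning did not converge")
}

#' Simulate an MRE count matrix from the planted truth
#'
#' Draws raw counts c[(gene, family), sample] from a negative binomial with
#' mean mu * multiplier * sizeFactor and dispersion phi (Poisson when phi =
#' 0). A random subset of rows (\code{plantedFraction}) receives a
#' target-group-specific multiplier of 2^(+-effectSize); all other
#' group multipliers are 1. Library sizes are the column sums.
#'
#' @param config a \code{\link{simConfig}}.
#' @param annotation result of \code{\link{simulateAnnotation}} (supplies
#'   the (gene, family) row universe); optional -- when omitted, rows are
#'   synthesized as all planted (gene, family) ids would be, using
#'   \code{nGenes * sitesPerGene} generic keys.
#' @return list with \code{mre} (an \code{\linkS4class{MREExperiment}}),
#'   \code{truth} (data.frame: key, planted, direction, multiplier) and
#'   \code{sizeFactors}.
#' @export
simulateCounts <- function(config, annotation = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 1L)
    keys <- if (!is.null(annotation))
        unique(paste(annotation$truthSites$gene_id,
                     annotation$truthSites$family_id, sep = "|"))
    else as.vector(outer(sprintf("gene%04d", seq_len(config$nGenes)),
                         sprintf("fam%03d", seq_len(config$sitesPerGene)),
                         paste, sep = "|"))
    nRow <- length(keys)
    nPer <- config$nPerGroup
    groups <- rep(config$groups, nPer)
    sampleIds <- paste0(rep(config$groups, nPer), "_s",
                        unlist(lapply(nPer, seq_len)))
    nPlant <- floor(config$plantedFraction * nRow)
    planted <- sort(sample(nRow, nPlant))
    dirn <- rep(0L, nRow)
    dirn[planted] <- sample(c(-1L, 1L), nPlant, replace = TRUE)
    mult <- matrix(1, nRow, length(config$groups),
                   dimnames = list(keys, config$groups))
    mult[, config$targetGroup] <- 2^(config$effectSize * dirn)
    sf <- exp(stats::runif(length(groups),
                           log(config$sizeFactorRange[1]),
                           log(config$sizeFactorRange[2])))
    mu <- sweep(mult[, groups, drop = FALSE], 2, sf, "*") * config$mu
    counts <- matrix(if (config$phi > 0)
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$phi)
        else stats::rpois(length(mu), mu),
        nRow, length(groups), dimnames = list(keys, sampleIds))
    mre <- MREExperiment(counts, groups, colSums(counts))
    list(mre = mre,
         truth = data.frame(key = keys, planted = dirn != 0L,
                            direction = dirn,
                            multiplier = mult[, config$targetGroup],
                            stringsAsFactors = FALSE),
         sizeFactors = stats::setNames(sf, sampleIds))
}

#' Simulate per-sample reads realizing a count matrix
#'
#' Emits, for every (gene, family, sample) count, that many error-free
#' reads whose span fully covers the planted site (SAM coordinates correct,
#' minus-strand genes stored reverse-complemented with flag 16), plus
#' site-free background reads. Because background sequence is cleaned of
#' all site motifs, coordinate-mode quantification of the output recovers
#' the count matrix exactly, and sequence mode agrees on these error-free
#' reads.
#'
#' @param config a \code{\link{simConfig}}.
#' @param annotation result of \code{\link{simulateAnnotation}}.
#' @param counts integer matrix (rows = "gene|family" keys present in the
#'   annotation truth, columns = samples), e.g. from
#'   \code{\link{simulateCounts}}.
#' @param dir output directory.
#' @return list with \code{sam} and \code{fastq} (named paths per sample)
#'   and \code{counts} (the realized truth matrix).
#' @export
simulateReads <- function(config, annotation, counts,
                          dir = tempfile("simreads")) {
    stopifnot(inherits(config, "SimConfig"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config$seed + 2L)
    ts <- annotation$truthSites
    if (config$readLength < max(nchar(ts$site_seq)))
        stop("read length shorter than the longest site")
    key <- paste(ts$gene_id, ts$family_id, sep = "|")
    if (!all(rownames(counts) %in% key))
        stop("counts rows not present in annotation truth")
    utrs <- annotation$utrs
    seqs <- as.character(utrSequences(utrs))
    Lg <- utrLengths(utrs)
    grl <- utrRanges(utrs)
    g0 <- vapply(names(grl), function(g)
        GenomicRanges::start(grl[[g]])[1] - 1L, numeric(1))  # 0-based
    gEnd <- vapply(names(grl), function(g)
        GenomicRanges::end(grl[[g]])[1], numeric(1))
    strand <- vapply(names(grl), function(g)
        as.character(BiocGenerics::strand(grl[[g]]))[1], character(1))
    rl <- config$readLength
    samPaths <- fastqPaths <- character(0)
    chromLen <- GenomeInfoDb::seqlengths(grl)
    header <- c("@HD\tVN:1.6\tSO:unknown",
                paste0("@SQ\tSN:chrSim\tLN:",
                       max(gEnd) + 100L))
    for (s in colnames(counts)) {
        recs <- character(0); fq <- character(0); rid <- 0L
        for (i in seq_len(nrow(ts))) {
            cnt <- counts[key[i], s]
            if (is.na(cnt) || cnt == 0) next
            g <- ts$gene_id[i]
            a <- ts$utr_offset[i]; b <- a + nchar(ts$site_seq[i])  # [a,b)
            lo <- max(0L, b - rl); hi <- min(a, Lg[g] - rl)
            starts <- if (hi > lo) sample(lo:hi, cnt, replace = TRUE)
                      else rep(lo, cnt)
            for (st in starts) {
                rid <- rid + 1L
                rseq <- substr(seqs[g], st + 1, st + rl)
                rec <- .samRecord(sprintf("%s_r%06d", s, rid), g, st, rseq,
                                  rl, g0, gEnd, strand)
                recs <- c(recs, rec$sam); fq <- c(fq, rec$fq)
            }
        }
        # background: windows that do not fully contain any planted site
        if (config$backgroundReads > 0) {
            for (g in names(seqs)) {
                sitesG <- ts[ts$gene_id == g, , drop = FALSE]
                for (k in seq_len(config$backgroundReads)) {
                    for (try in 1:50) {
                        st <- sample(0:(Lg[g] - rl), 1)
                        contains <- any(st <= sitesG$utr_offset &
                            st + rl >= sitesG$utr_offset +
                                nchar(sitesG$site_seq))
                        if (!contains) break
                    }
                    if (contains) next
                    rid <- rid + 1L
                    rseq <- substr(seqs[g], st + 1, st + rl)
                    rec <- .samRecord(sprintf("%s_b%06d", s, rid), g, st,
                                      rseq, rl, g0, gEnd, strand)
                    recs <- c(recs, rec$sam); fq <- c(fq, rec$fq)
                }
            }
        }
        samPath <- file.path(dir, paste0(s, ".sam"))
        writeLines(c(header, recs), samPath)
        fqPath <- file.path(dir, paste0(s, ".fastq"))
        writeLines(fq, fqPath)
        samPaths[s] <- samPath; fastqPaths[s] <- fqPath
    }
    list(sam = samPaths, fastq = fastqPaths, counts = counts)
}

.samRecord <- function(id, gene, st, rseq, rl, g0, gEnd, strand) {
    if (strand[gene] == "+") {
        pos <- g0[gene] + st + 1L
        flag <- 0L; sseq <- rseq
    } else {
        pos <- gEnd[gene] - st - rl + 1L
        flag <- 16L; sseq <- .revcompChar(rseq)
    }
    list(sam = paste(id, flag, "chrSim", pos, 60L, paste0(rl, "M"),
                     "*", 0L, 0L, sseq,
                     paste(rep("I", rl), collapse = ""), sep = "\t"),
         fq = c(paste0("@", id), rseq, "+",
                paste(rep("I", rl), collapse = "")))
}
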