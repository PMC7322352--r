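.readGR <- function(chrom, start1, end1, qname, seq = "ACGT") {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1), "+")
    S4Vectors::mcols(gr)$qname <- qname
    S4Vectors::mcols(gr)$seq <- Biostrings::DNAStringSet(
        rep(seq, length(gr)))
    S4Vectors::mcols(gr)$is_mate2 <- FALSE
    gr
}

test_that("reads are assigned to every overlapped UTR, counted once", {
    utrs <- makeUTRSet(c(geneA = randomDNA(60), geneB = randomDNA(60)))
    # geneA occupies [26,85], geneB [111,170] (1-based)
    inA <- .readGR("chrT", 30, 79, "r1")
    off <- .readGR("chrT", 1, 20, "r2")
    both <- .readGR("chrT", 80, 115, "r3")     # spans the gap into geneB
    asg <- assignReadsToUTRs(c(inA, off, both), utrs)
    expect_setequal(asg$hits$gene_id[asg$hits$read == 1], "geneA")
    expect_false(2 %in% asg$hits$read)
    expect_setequal(asg$hits$gene_id[asg$hits$read == 3],
                    c("geneA", "geneB"))
    expect_equal(asg$libSize, 2L)              # r3 counted once

    # minimum-overlap rule
    touch <- .readGR("chrT", 1, 26, "r4")      # 1 nt inside geneA
    expect_equal(nrow(assignReadsToUTRs(touch, utrs)$hits), 1L)
    expect_equal(nrow(assignReadsToUTRs(touch, utrs,
                                        minOverlap = 2L)$hits), 0L)

    expect_error(assignReadsToUTRs(.readGR("chrOther", 5, 10, "r5"), utrs),
                 "chromosome naming mismatch.*chrOther")
})

test_that("read scanning counts occurrences in both orientations", {
    expect_equal(scanRead("TTACATTCCATT", "ACATTCCA"), 1L)
    expect_equal(scanRead("GGGGGGGG", c("ACATTCCA", "CATTCC")), 0L)
    # site present only as reverse complement
    expect_equal(scanRead("TGGAATGT", "ACATTCCA"), 1L)
    expect_equal(scanRead("TGGAATGT", "ACATTCCA", stranded = TRUE), 0L)
    # overlapping occurrences within one orientation all count
    expect_equal(scanRead("AAAAAAA", "AAAAAA"), 2L)
    # palindromic site: both orientations at one offset count once
    expect_equal(scanRead("TTACGCGTTT", "ACGCGT"), 1L)
    # N never matches
    expect_equal(scanRead("TTACATTNCATT", "ACATTCCA"), 0L)
    # vectorized over reads
    expect_equal(scanRead(c("TTACATTCCATT", "GGG"), "ACATTCCA"), c(1L, 0L))
})

test_that("quantification is additive, order-invariant and monotone", {
    cfg <- smallSimConfig()
    ann <- simulateAnnotation(cfg)
    sim <- simulateCounts(cfg, ann)
    rds <- simulateReads(cfg, ann, mreCounts(sim$mre)[, 1:2, drop = FALSE])
    cat <- buildMRECatalog(ann$utrs, readSeedMotifs(ann$paths$motifs))

    s1 <- readLines(rds$sam[[1]])
    hdr <- grep("^@", s1, value = TRUE)
    body <- setdiff(s1, hdr)
    q1 <- quantifySample(rds$sam[[1]], cat, ann$utrs)

    # permutation invariance
    perm <- tempfile(fileext = ".sam")
    set.seed(1); writeLines(c(hdr, sample(body)), perm)
    qp <- quantifySample(perm, cat, ann$utrs)
    expect_identical(qp$counts, q1$counts)
    expect_identical(qp$libSize, q1$libSize)

    # additivity over read-set concatenation
    s2 <- readLines(rds$sam[[2]])
    body2 <- setdiff(s2, grep("^@", s2, value = TRUE))
    comb <- tempfile(fileext = ".sam")
    writeLines(c(hdr, body, body2), comb)
    q2 <- quantifySample(rds$sam[[2]], cat, ann$utrs)
    qc <- quantifySample(comb, cat, ann$utrs)
    expect_equal(qc$counts, q1$counts + q2$counts)

    # monotonicity: adding one read never decreases any count
    plus <- tempfile(fileext = ".sam")
    writeLines(c(hdr, body, body2[1]), plus)
    qplus <- quantifySample(plus, cat, ann$utrs)
    expect_true(all(qplus$counts >= q1$counts))
})

test_that("simulated reads are recovered exactly in both counting modes", {
    cfg <- smallSimConfig(seed = 21L)
    ann <- simulateAnnotation(cfg)
    sim <- simulateCounts(cfg, ann)
    truthCounts <- mreCounts(sim$mre)[, 1:3, drop = FALSE]
    rds <- simulateReads(cfg, ann, truthCounts)
    cat <- buildMRECatalog(ann$utrs, readSeedMotifs(ann$paths$motifs))
    for (s in colnames(truthCounts)) {
        qc <- quantifySample(rds$sam[[s]], cat, ann$utrs,
                             mode = "coordinate")
        qs <- quantifySample(rds$sam[[s]], cat, ann$utrs,
                             mode = "sequence")
        expect_equal(unname(qc$counts[rownames(truthCounts)]),
                     unname(truthCounts[, s]))
        expect_identical(qs$counts, qc$counts)
    }
})

test_that("zero-read samples give a flagged all-zero column", {
    cfg <- smallSimConfig(seed = 31L)
    ann <- simulateAnnotation(cfg)
    cat <- buildMRECatalog(ann$utrs, readSeedMotifs(ann$paths$motifs))
    empty <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 paste0("@SQ\tSN:chrSim\tLN:100000")), empty)
    sim <- simulateCounts(cfg, ann)
    rds <- simulateReads(cfg, ann, mreCounts(sim$mre)[, 1, drop = FALSE])
    expect_warning(
        mre <- quantifySamples(c(a = rds$sam[[1]], b = empty), cat,
                               ann$utrs, groups = c("t", "n")),
        "zero assigned reads")
    expect_true(all(mreCounts(mre)[, "b"] == 0))
    expect_equal(unname(libSizes(mre)["b"]), 0)
})
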