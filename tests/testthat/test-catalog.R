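test_that("gcContent computes the G+C fraction over non-N bases", {
    expect_equal(gcContent(c("GCGC", "ATAT", "ATGC")), c(1, 0, 0.5))
    expect_equal(gcContent("ANGN"), 0.5)        # N excluded from denominator
    expect_equal(gcContent("atgc"), 0.5)        # case insensitive
    expect_error(gcContent(""), "empty")
    expect_error(gcContent("NNNN"), "only.*N")
    expect_error(gcContent("ACGU"), "non-ACGTN")

    # concatenation is the length-weighted mean of the parts
    set.seed(5)
    for (i in 1:20) {
        a <- randomDNA(sample(10:80, 1)); b <- randomDNA(sample(10:80, 1))
        expect_equal(gcContent(paste0(a, b)),
                     (nchar(a) * gcContent(a) + nchar(b) * gcContent(b)) /
                         (nchar(a) + nchar(b)))
    }
})

test_that("seed-derived site sequences follow the canonical definitions", {
    # miR-1: reverse complement of positions 2-8 worked out by hand
    expect_equal(seedToSiteSequences("UGGAAUGUAAAGAAGUAUGUAU"),
                 c("8mer" = "ACATTCCA", "7mer-m8" = "ACATTCC",
                   "7mer-A1" = "CATTCCA", "6mer" = "CATTCC"))
    expect_equal(seedToSiteSequences("AAAAAAAA"),
                 c("8mer" = "TTTTTTTA", "7mer-m8" = "TTTTTTT",
                   "7mer-A1" = "TTTTTTA", "6mer" = "TTTTTT"))
    expect_error(seedToSiteSequences("ACGUACG"), "at least 8")

    set.seed(6)
    for (i in 1:25) {
        mir <- chartr("T", "U", randomDNA(22))
        s <- seedToSiteSequences(mir)
        # definitional relations between the four types
        expect_equal(s[["6mer"]], substr(s[["7mer-m8"]], 2, 7))
        expect_equal(s[["8mer"]], paste0(s[["7mer-m8"]], "A"))
        expect_equal(s[["7mer-A1"]], paste0(s[["6mer"]], "A"))
        # reverse complement of the 7mer-m8 recovers miRNA positions 2-8
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s[["7mer-m8"]])))
        expect_equal(rc, chartr("U", "T", substr(mir, 2, 8)))
        # agreement with the seed-region entry point
        expect_equal(siteSequencesFromSeed(substr(mir, 2, 8)), s)
    }
})

test_that("catalog records exact occurrences with longest-site-wins", {
    utrs <- makeUTRSet(c(geneA = "AAACATTCCAAA"))
    sites <- as.data.frame(mreSites(buildMRECatalog(utrs, mir1Motifs())))
    expect_equal(nrow(sites), 1L)   # 7mer/6mer inside the 8mer suppressed
    expect_equal(sites$site_type, "8mer")
    expect_equal(sites$utr_offset, 2L)
    expect_equal(sites$site_seq, "ACATTCCA")

    expect_equal(length(buildMRECatalog(
        makeUTRSet(c(g = "GGGGGG")), mir1Motifs())), 0L)

    two <- as.data.frame(mreSites(buildMRECatalog(
        makeUTRSet(c(g = "CATTCCGGGCATTCC")), mir1Motifs(),
        siteTypes = "6mer")))
    expect_equal(two$utr_offset, c(0L, 9L))

    # a 7mer-A1 not preceded by the m8-matching base stays a 7mer-A1
    lone <- as.data.frame(mreSites(buildMRECatalog(
        makeUTRSet(c(g = "GGGCATTCCAGGG")), mir1Motifs())))
    expect_equal(lone$site_type, "7mer-A1")
    expect_equal(lone$utr_offset, 3L)

    # recorded site_seq re-extracts identically from the UTR sequence
    utr <- "TTTACATTCCATTTCATTCCTTTACATTCCTTT"
    cat3 <- buildMRECatalog(makeUTRSet(c(g = utr)), mir1Motifs())
    s3 <- as.data.frame(mreSites(cat3))
    for (i in seq_len(nrow(s3)))
        expect_equal(substr(utr, s3$utr_offset[i] + 1,
                            s3$utr_offset[i] + nchar(s3$site_seq[i])),
                     unname(s3$site_seq[i]))

    # N never matches
    expect_equal(length(buildMRECatalog(
        makeUTRSet(c(g = "AAACATTNCAAA")), mir1Motifs())), 0L)

    # motifs without site sequences are skipped with a warning
    noSites <- S4Vectors::DataFrame(family_id = "empty",
        site_8mer = NA_character_, site_7mer_m8 = NA_character_,
        site_7mer_A1 = NA_character_, site_6mer = NA_character_)
    expect_warning(buildMRECatalog(makeUTRSet(c(g = "ACGTACGT")), noSites),
                   "skipped")
})

test_that("catalog matching equals a naive substring oracle", {
    set.seed(7)
    typeOf <- c("6mer" = "site_6mer", "7mer-m8" = "site_7mer_m8",
                "8mer" = "site_8mer")
    for (i in 1:200) {
        sq <- randomDNA(sample(30:500, 1))
        w <- sample(c(6L, 7L, 8L), 1)
        pat <- randomDNA(w)
        tp <- names(typeOf)[match(w, c(6, 7, 8))]
        motif <- S4Vectors::DataFrame(family_id = "m",
            site_8mer = NA_character_, site_7mer_m8 = NA_character_,
            site_7mer_A1 = NA_character_, site_6mer = NA_character_)
        motif[[typeOf[tp]]] <- pat
        found <- suppressWarnings(as.data.frame(mreSites(
            buildMRECatalog(makeUTRSet(c(g = sq)), motif,
                            siteTypes = tp))))
        expect_identical(found$utr_offset, naiveFind(sq, pat),
                         info = paste("case", i))
        # stranded read scan counts the same occurrences
        expect_identical(scanRead(sq, pat, stranded = TRUE),
                         length(naiveFind(sq, pat)))
    }
})

test_that("UTR annotation loading splices intervals and honors strand", {
    dir <- withr::local_tempdir()
    genome <- paste0(paste(rep("T", 100), collapse = ""),
                     "ACGTACGTACGT",                  # geneA [100,112)
                     paste(rep("A", 38), collapse = ""),
                     "GGGCCCGGGG",                    # geneB part 1 [150,160)
                     paste(rep("T", 20), collapse = ""),
                     "AACCGGTTAA")                    # geneB part 2 [180,190)
    fa <- file.path(dir, "g.fa"); bed <- file.path(dir, "u.bed")
    writeLines(c(">chr1", genome), fa)
    writeLines(c("chr1\t100\t112\tgeneA\t0\t+",
                 "chr1\t150\t160\tgeneB\t0\t-",
                 "chr1\t180\t190\tgeneB\t0\t-"), bed)
    utrs <- loadUTRAnnotation(bed, fa)
    expect_equal(unname(utrLengths(utrs)), c(12L, 20L))
    expect_equal(as.character(utrSequences(utrs)[["geneA"]]),
                 "ACGTACGTACGT")
    # minus strand: splice genomic order then reverse-complement
    expect_equal(as.character(utrSequences(utrs)[["geneB"]]),
                 as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(
                         paste0("GGGCCCGGGG", "AACCGGTTAA")))))

    # per-gene FASTA mode
    fa2 <- file.path(dir, "pergene.fa")
    writeLines(c(">geneA", "ACGTACGTACGT",
                 ">geneB", "TTAACCGGTTCCCCGGGCCC"), fa2)
    utrs2 <- loadUTRAnnotation(bed, fa2)
    expect_equal(as.character(utrSequences(utrs2)[["geneB"]]),
                 "TTAACCGGTTCCCCGGGCCC")

    # errors: missing id, malformed line
    writeLines(c("chr1\t100\t112\tgeneC\t0\t+"), bed)
    fa3 <- file.path(dir, "short.fa")
    writeLines(c(">chrX", "ACGT"), fa3)
    expect_error(loadUTRAnnotation(bed, fa3), "geneC")
    writeLines(c("chr1\t100\t112\tgeneA\t0\t+",
                 "chr1\tnotanumber\t112\tgeneB\t0\t+"), bed)
    expect_error(loadUTRAnnotation(bed, fa), "line 2")
})
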