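test_that("library-size/length adjustment follows the RPKM-like formula", {
    m <- matrix(c(0, 8), 2, 1,
                dimnames = list(c("gA|m1", "gB|m1"), "s1"))
    y <- baseNormalize(m, libSizes = 1e6,
                       geneLengths = c(gA = 1e3, gB = 1e3))
    expect_equal(unname(y[, 1]), c(log2(0.5), log2(8.5)))

    # doubling counts and library size leaves large-count rows nearly put
    c0 <- 400
    m2 <- matrix(c(c0, 2 * c0), 1, 2,
                 dimnames = list("gA|m1", c("s1", "s2")))
    y2 <- baseNormalize(m2, libSizes = c(1e6, 2e6),
                        geneLengths = c(gA = 1e3))
    expect_lt(abs(y2[1, 2] - y2[1, 1]), 2 / c0)

    expect_error(baseNormalize(m, libSizes = c(0),
                               geneLengths = c(gA = 1e3, gB = 1e3)),
                 "zero library size")
    expect_error(baseNormalize(m, libSizes = 1e6,
                               geneLengths = c(gA = 1e3)), "gB")
})

.normFixture <- function(nrow = 400, ncol = 4, seed = 9, centersOnly = TRUE,
                         bins = 4) {
    set.seed(seed)
    edges <- seq(0, 1, length.out = bins + 1)
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    gc <- if (centersOnly) sample(centers, nrow, replace = TRUE)
          else runif(nrow)
    y <- matrix(rnorm(nrow * ncol, sd = 2), nrow,
                dimnames = list(paste0("g", seq_len(nrow), "|m1"),
                                paste0("s", seq_len(ncol))))
    list(y = y, gc = gc, bins = bins)
}

test_that("GC correction removes constructed sample-specific GC offsets", {
    fx <- .normFixture(ncol = 2)
    # two identical samples: zero correction everywhere
    y <- cbind(s1 = fx$y[, 1], s2 = fx$y[, 1])
    mod <- fitGCCorrection(y, fx$gc, bins = fx$bins, minSites = 20)
    expect_equal(applyGCCorrection(y, mod, fx$gc), y)

    # +1 shift planted on the top-GC bin of sample 2 is equalized away
    hi <- fx$gc > 0.75
    y2 <- y; y2[hi, 2] <- y2[hi, 2] + 1
    mod2 <- fitGCCorrection(y2, fx$gc, bins = fx$bins, minSites = 20)
    cor2 <- applyGCCorrection(y2, mod2, fx$gc)
    expect_equal(cor2[hi, 1], cor2[hi, 2])
    expect_equal(cor2[!hi, 1], cor2[!hi, 2])

    # single bin degenerates to global median centering
    mod1 <- fitGCCorrection(y2, fx$gc, bins = 1, minSites = 1)
    cor1 <- applyGCCorrection(y2, mod1, fx$gc)
    grand <- median(apply(y2, 2, median))
    for (s in 1:2)
        expect_equal(unname(cor1[, s]),
                     unname(y2[, s] - (median(y2[, s]) - grand)))

    # all-identical sample: zero offsets with a warning
    yflat <- cbind(s1 = fx$y[, 1], s2 = rep(1, nrow(fx$y)))
    expect_warning(modf <- fitGCCorrection(yflat, fx$gc, bins = fx$bins,
                                           minSites = 20),
                   "all-identical")
    corf <- applyGCCorrection(yflat, modf, fx$gc)
    expect_equal(corf[, 2], yflat[, 2])

    expect_error(applyGCCorrection(y, mod, rep(1.5, nrow(y))),
                 "gc outside")
})

test_that("correction leaves bin medians flat and preserves in-bin ranks", {
    for (seed in c(1, 2, 3)) {
        fx <- .normFixture(seed = seed, ncol = 5)
        mod <- fitGCCorrection(fx$y, fx$gc, bins = fx$bins, minSites = 20)
        y <- applyGCCorrection(fx$y, mod, fx$gc)
        bin <- findInterval(fx$gc, mod@edges, rightmost.closed = TRUE,
                            all.inside = TRUE)
        for (b in unique(bin)) {
            idx <- bin == b
            med <- apply(y[idx, , drop = FALSE], 2, median)
            # per-sample bin medians coincide with the grand medians
            expect_true(all(abs(med - mod@grandMedians[b]) < 1e-9))
            # within (sample x bin) the correction is a pure shift
            for (s in seq_len(ncol(y)))
                expect_identical(order(y[idx, s]), order(fx$y[idx, s]))
        }
    }
})

test_that("normalization is deterministic and scale-insensitive", {
    cfg <- smallSimConfig(seed = 41L)
    ann <- simulateAnnotation(cfg)
    sim <- simulateCounts(cfg, ann)
    gt <- as.data.frame(geneTable(ann$utrs))
    n1 <- normalizeMRE(sim$mre, gt, minSites = 5)
    n2 <- normalizeMRE(sim$mre, gt, minSites = 5)
    expect_identical(normValues(n1), normValues(n2))

    # scaling one sample's counts and library size by k barely moves y
    cts <- mreCounts(sim$mre)
    big <- cts + 300   # keep counts far above the pseudocount
    mre1 <- MREExperiment(big, sampleGroups(sim$mre), colSums(big))
    cts2 <- big; cts2[, 1] <- big[, 1] * 3
    mre2 <- MREExperiment(cts2, sampleGroups(sim$mre),
                          c(colSums(big)[1] * 3, colSums(big)[-1]))
    y1 <- baseNormalize(mreCounts(mre1), libSizes(mre1),
                        setNames(gt$length, gt$gene_id))
    y2 <- baseNormalize(mreCounts(mre2), libSizes(mre2),
                        setNames(gt$length, gt$gene_id))
    expect_lt(max(abs(y2[, 1] - y1[, 1])), 2 / min(big[, 1]))
})
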