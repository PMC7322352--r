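test_that("TMM factors behave as trimmed-mean scaling factors", {
    set.seed(15)
    cts <- matrix(rnbinom(400 * 4, mu = 150, size = 4), 400,
                  dimnames = list(NULL, paste0("s", 1:4)))
    # identical columns: all factors 1
    same <- cbind(a = cts[, 1], b = cts[, 1], c = cts[, 1])
    expect_equal(unname(tmmFactors(same)), rep(1, 3))

    # a column that is exactly twice the reference: factors 1/sqrt(2),
    # sqrt(2) after the geometric-mean rescale
    dbl <- cbind(a = cts[, 1], b = 2L * cts[, 1])
    expect_equal(unname(tmmFactors(dbl, libSizes = c(1e5, 1e5))),
                 c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

    # row-permutation invariance
    expect_equal(tmmFactors(cts), tmmFactors(cts[sample(400), ]))

    # geometric mean is 1
    f <- tmmFactors(cts)
    expect_equal(exp(mean(log(f))), 1)

    # no co-positive rows: factor 1 with a warning
    disj <- cbind(a = c(5L, 0L), b = c(0L, 7L))
    expect_warning(fd <- tmmFactors(disj, libSizes = c(10, 10),
                                    refColumn = 1),
                   "co-positive")
    expect_equal(unname(fd), c(1, 1))
})

test_that("TMM matches the reference implementation", {
    set.seed(16)
    for (i in 1:5) {
        cts <- matrix(rnbinom(600 * 6, mu = exp(runif(600 * 6, 2, 6)),
                              size = 3), 600)
        expect_equal(unname(tmmFactors(cts)),
                     unname(edgeR::calcNormFactors(cts, method = "TMM")),
                     tolerance = 1e-10)
    }
})

test_that("common dispersion is recovered by method of moments", {
    set.seed(17)
    cond <- rep(c("t", "n"), each = 13)
    # Poisson data: phi shrinks to (near) zero
    pois <- matrix(rpois(200 * 26, 50), 200)
    expect_lte(estimateCommonDispersion(pois, cond), 0.05)
    # NB data at phi = 0.2
    nb <- matrix(rnbinom(2000 * 26, mu = 100, size = 5), 2000)
    phi <- estimateCommonDispersion(nb, cond)
    expect_gte(phi, 0.1); expect_lte(phi, 0.3)
    # constant counts: zero dispersion
    const <- matrix(7, 10, 26)
    expect_equal(estimateCommonDispersion(const, cond), 0)
    expect_error(estimateCommonDispersion(pois, rep("t", 26)),
                 "two conditions")
})

test_that("the conditional NB exact test has its closed-form limits", {
    # symmetric data: p = 1, log2FC = 0
    r <- nbExactTest(c(10, 12, 8), c(8, 12, 10), phi = 0.2)
    expect_equal(r$pvalue, 1); expect_equal(r$log2FC, 0)
    # empty row
    r0 <- nbExactTest(c(0, 0), c(0, 0), phi = 0.1)
    expect_equal(r0$pvalue, 1); expect_equal(r0$log2FC, 0)
    expect_error(nbExactTest(1, 1, phi = -1), "phi")

    # Poisson limit equals the exact binomial test
    set.seed(18)
    for (i in 1:40) {
        tum <- rpois(sample(3:8, 1), 15)
        nor <- rpois(sample(3:8, 1), 15)
        z <- sum(tum) + sum(nor)
        expect_equal(
            nbExactTest(tum, nor, phi = 0)$pvalue,
            binom.test(sum(tum), z,
                       length(tum) / (length(tum) + length(nor)))$p.value,
            tolerance = 1e-12)
    }

    # overwhelming asymmetry: astronomically small p
    expect_lt(nbExactTest(rep(20, 5), rep(0, 5), phi = 0)$pvalue, 1e-25)

    # p-values increase with dispersion (same counts, more noise allowed)
    p1 <- nbExactTest(c(30, 25, 35), c(10, 12, 9), phi = 0)$pvalue
    p2 <- nbExactTest(c(30, 25, 35), c(10, 12, 9), phi = 0.5)$pvalue
    expect_gt(p2, p1)
})

test_that("BH adjustment is the step-up procedure", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(0.07, 5)), rep(0.07, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "0,1")

    # independent step-up oracle + monotonicity under p perturbation
    stepUp <- function(p) {
        m <- length(p); o <- order(p)
        q <- rev(cummin(rev(m * p[o] / seq_len(m))))
        pmin(1, q)[order(o)]
    }
    set.seed(19)
    for (i in 1:25) {
        p <- runif(sample(3:40, 1))
        expect_equal(bhAdjust(p), stepUp(p))
        j <- sample(length(p), 1)
        p2 <- p; p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
        expect_true(all(bhAdjust(p2) >= bhAdjust(p) - 1e-12))
    }
})

test_that("the differential route flags large planted fold changes", {
    set.seed(20)
    nr <- 120; n <- 13
    mu <- matrix(80, nr, 2 * n)
    planted <- 1:12
    mu[planted, 1:n] <- 80 * 8     # log2FC = 3 in the tumor group
    cts <- matrix(rnbinom(length(mu), mu = mu, size = 5), nr,
                  dimnames = list(paste0("g", 1:nr, "|m"),
                                  paste0("s", 1:(2 * n))))
    # equal library sizes keep the composition effect of the planted
    # rows out of the scaling, so fold changes sit near the truth
    mre <- makeMRE(cts, rep(c("T", "N"), each = n),
                   libSizes = rep(2000, 2 * n))
    de <- deTest(mre, "T", "N")
    sel <- deSelect(de)
    expect_true(all(paste0("g", planted, "|m") %in% sel))
    expect_lt(length(setdiff(sel, paste0("g", planted, "|m"))), 3)
    expect_true(all(abs(de$log2FC[planted] - 3) < 1.2))
    expect_lt(median(abs(de$log2FC[planted] - 3)), 0.5)
    expect_gt(S4Vectors::metadata(de)$dispersion, 0.05)
    expect_error(deTest(mre, "T", "missing"), ">= 2 samples")
})
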