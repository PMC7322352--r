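#' TMM scaling factors (trimmed mean of M-values)
#'
#' Between-sample scaling factors for count matrices, computed against a
#' reference column as the precision-weighted mean of doubly trimmed
#' log-ratios. For sample s against reference r, on rows positive in both,
#' M = log2((c_s/N_s)/(c_r/N_r)) and A = log2 of the geometric mean of the
#' two relative abundances; the most extreme 30 percent of M (each tail) and
#' 5 percent of A are discarded, the remaining M are averaged with inverse
#' asymptotic-variance weights, and factors are rescaled so their geometric
#' mean is 1. The reference is the column whose 75th count percentile
#' (relative to library size) is closest to the mean across samples.
#'
#' @param counts numeric matrix of raw counts (rows = MREs).
#' @param libSizes per-column library sizes; defaults to column sums.
#' @param refColumn optional reference column index/name; default as above.
#' @param logratioTrim,sumTrim trim fractions for M and A (defaults 0.30 and
#'   0.05).
#' @return named numeric vector of factors, geometric mean 1.
#' @export
tmmFactors <- function(counts, libSizes = colSums(counts),
                       refColumn = NULL, logratioTrim = 0.30,
                       sumTrim = 0.05) {
    counts <- as.matrix(counts)
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    libSizes <- as.numeric(libSizes)
    if (any(libSizes <= 0)) stop("non-positive library size")
    if (is.null(refColumn)) {
        f75 <- apply(sweep(counts, 2, libSizes, "/"), 2,
                     stats::quantile, probs = 0.75)
        refColumn <- which.min(abs(f75 - mean(f75)))
    }
    r <- counts[, refColumn]; Nr <- libSizes[refColumn]
    f <- vapply(seq_len(ncol(counts)), function(s) {
        o <- counts[, s]; Ns <- libSizes[s]
        keep <- o > 0 & r > 0
        if (!any(keep)) {
            warning("no co-positive rows for sample ", colnames(counts)[s],
                    "; factor set to 1")
            return(1)
        }
        obs <- o[keep] / Ns; ref <- r[keep] / Nr
        M <- log2(obs / ref)
        A <- (log2(obs) + log2(ref)) / 2
        v <- (Ns - o[keep]) / (Ns * o[keep]) +
             (Nr - r[keep]) / (Nr * r[keep])
        if (max(abs(M)) < 1e-6) return(1)
        n <- length(M)
        loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
        loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
        keep2 <- rank(M) >= loM & rank(M) <= hiM &
                 rank(A) >= loA & rank(A) <= hiA
        if (!any(keep2)) return(1)
        2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
    }, numeric(1))
    f <- f / exp(mean(log(f)))
    stats::setNames(f, colnames(counts))
}

#' Method-of-moments common NB dispersion
#'
#' Estimates a single negative-binomial dispersion shared across MREs. On
#' factor-scaled counts (each column rescaled to the geometric-mean
#' effective library size), each row contributes
#' \eqn{\hat\phi = (\hat v - \hat\mu) / \hat\mu^2} pooled across the two
#' conditions with degrees-of-freedom weights; the common value is the
#' median across rows of the non-negative estimates. Under Poisson data the
#' estimate shrinks to 0.
#'
#' @param counts raw count matrix (columns = samples of both conditions).
#' @param condition two-level factor, one level per sample.
#' @param libSizes per-sample library sizes.
#' @param factors per-sample TMM factors (default all 1).
#' @return scalar dispersion phi >= 0.
#' @export
estimateCommonDispersion <- function(counts, condition,
                                     libSizes = colSums(counts),
                                     factors = rep(1, ncol(counts))) {
    counts <- as.matrix(counts)
    condition <- factor(condition)
    if (nlevels(condition) != 2) stop("exactly two conditions required")
    if (any(table(condition) < 2)) stop("need >= 2 samples per condition")
    eff <- libSizes * factors
    sc <- sweep(counts, 2, exp(mean(log(eff))) / eff, "*")
    phiRow <- rep(NA_real_, nrow(counts))
    num <- den <- rep(0, nrow(counts))
    for (lv in levels(condition)) {
        cc <- sc[, condition == lv, drop = FALSE]
        nl <- ncol(cc)
        m <- rowMeans(cc)
        v <- apply(cc, 1, stats::var)
        ok <- m > 0
        num[ok] <- num[ok] + (nl - 1) * (v[ok] - m[ok]) / m[ok]^2
        den[ok] <- den[ok] + (nl - 1)
    }
    phiRow <- ifelse(den > 0, num / den, NA_real_)
    est <- pmax(0, phiRow[!is.na(phiRow)])
    if (!length(est)) {
        warning("all rows zero; dispersion set to 0")
        return(0)
    }
    stats::median(est)
}

# conditional two-sided exact p for aggregated pseudo-counts
.nbExactP <- function(tt, nn, nT, nN, phi, relErr = 1 + 1e-07) {
    z <- tt + nn
    if (z == 0) return(1)
    pT <- nT / (nT + nN)
    t <- 0:z
    logp <- if (phi <= 0)
        stats::dbinom(t, z, pT, log = TRUE)
    else
        stats::dnbinom(t, size = nT / phi, mu = z * pT, log = TRUE) +
        stats::dnbinom(z - t, size = nN / phi, mu = z * (1 - pT),
                       log = TRUE)
    pr <- exp(logp - max(logp))
    pr <- pr / sum(pr)
    min(1, sum(pr[pr <= pr[tt + 1] * relErr]))
}

#' Conditional NB exact test for one MRE
#'
#' Two-group exact test on raw counts, in the mold of the classic exact test
#' for negative-binomial counts: per-sample counts are rescaled to a common
#' effective library size (library size times TMM factor), summed per
#' condition and rounded to pseudo-counts T and N. Conditional on z = T + N,
#' T follows (for dispersion phi > 0) the law proportional to
#' \code{dnbinom(t, size = nT/phi, mu = z*nT/(nT+nN)) *
#' dnbinom(z-t, size = nN/phi, mu = z*nN/(nT+nN))}, enumerated over
#' t = 0..z; at phi = 0 this is the Poisson limit, i.e. the binomial law.
#' The two-sided p-value sums the probabilities of all outcomes no more
#' likely than the observed one (the observed point mass counted once).
#' The fold change is \code{log2((T/nT + 0.5) / (N/nN + 0.5))}.
#'
#' @param tumor,normal numeric count vectors for the two conditions.
#' @param effLibTumor,effLibNormal effective library sizes per sample
#'   (library size x factor); defaults treat counts as already comparable.
#' @param phi common NB dispersion (>= 0).
#' @return list with \code{pvalue}, \code{log2FC}, \code{pseudoT},
#'   \code{pseudoN}.
#' @export
nbExactTest <- function(tumor, normal,
                        effLibTumor = rep(1, length(tumor)),
                        effLibNormal = rep(1, length(normal)),
                        phi = 0) {
    if (phi < 0) stop("phi must be >= 0")
    eff <- c(effLibTumor, effLibNormal)
    common <- exp(mean(log(eff)))
    tt <- round(sum(tumor * common / effLibTumor))
    nn <- round(sum(normal * common / effLibNormal))
    nT <- length(tumor); nN <- length(normal)
    if (tt + nn == 0)
        return(list(pvalue = 1, log2FC = 0, pseudoT = 0, pseudoN = 0))
    p <- .nbExactP(tt, nn, nT, nN, phi)
    lfc <- log2((tt / nT + 0.5) / (nn / nN + 0.5))
    list(pvalue = p, log2FC = lfc, pseudoT = tt, pseudoN = nn)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to \code{\link[stats]{p.adjust}}) with
#' input validation; values are returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values (q-values), capped at 1.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0,1]")
    stats::p.adjust(p, method = "BH")
}

#' Differential MRE test between two groups
#'
#' The count-based selection route: TMM factors on the two groups' raw
#' counts, a common method-of-moments dispersion, the conditional NB exact
#' test per MRE, and BH adjustment.
#'
#' @param x an \code{\linkS4class{MREExperiment}}.
#' @param tumorGroup,normalGroup the two group labels to compare.
#' @return \link[S4Vectors]{DataFrame} with \code{key}, \code{log2FC},
#'   \code{pvalue}, \code{fdr}; dispersion and factors in
#'   \code{metadata()}.
#' @export
deTest <- function(x, tumorGroup, normalGroup) {
    grp <- sampleGroups(x)
    use <- grp %in% c(tumorGroup, normalGroup)
    if (sum(grp == tumorGroup) < 2 || sum(grp == normalGroup) < 2)
        stop("need >= 2 samples in each of the two groups")
    cts <- mreCounts(x)[, use, drop = FALSE]
    libs <- libSizes(x)[use]
    cond <- factor(grp[use], levels = c(tumorGroup, normalGroup))
    f <- tmmFactors(cts, libs)
    phi <- estimateCommonDispersion(cts, cond, libs, f)
    eff <- libs * f
    isT <- cond == tumorGroup
    res <- lapply(seq_len(nrow(cts)), function(i)
        nbExactTest(cts[i, isT], cts[i, !isT],
                    eff[isT], eff[!isT], phi))
    out <- S4Vectors::DataFrame(
        key = rownames(cts),
        log2FC = vapply(res, `[[`, numeric(1), "log2FC"),
        pvalue = vapply(res, `[[`, numeric(1), "pvalue"))
    out$fdr <- bhAdjust(out$pvalue)
    S4Vectors::metadata(out) <- list(dispersion = phi, factors = f,
                                     tumorGroup = tumorGroup,
                                     normalGroup = normalGroup)
    out
}
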