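#' Dunnett's C pairwise multiple comparisons (DTK test)
#'
#' Unequal-variance, unequal-n pairwise multiple comparison across all k
#' groups, applied per MRE row. For groups i and j with means \eqn{\bar x_i,
#' \bar x_j}, variances \eqn{s_i^2, s_j^2} and sizes \eqn{n_i, n_j}:
#' \deqn{SE_{ij} = \sqrt{s_i^2/n_i + s_j^2/n_j}}
#' and the critical value is the variance-weighted combination of
#' studentized-range quantiles
#' \deqn{q^*_{ij} = \frac{q_{\alpha,k,\nu_i} s_i^2/n_i +
#'   q_{\alpha,k,\nu_j} s_j^2/n_j}{s_i^2/n_i + s_j^2/n_j}, \quad
#'   \nu_i = n_i - 1,}
#' giving the confidence half-width \eqn{w_{ij} = q^*_{ij} SE_{ij} /
#' \sqrt{2}}. A pair is significant when 0 falls outside
#' \eqn{d_{ij} \pm w_{ij}}, \eqn{d_{ij} = \bar x_i - \bar x_j}. With k = 2
#' and equal variances this reduces to the two-sided t test via
#' \eqn{q_{\alpha,2,\nu} = \sqrt{2}\, t_{\alpha/2,\nu}}.
#'
#' Degenerate rows (both variances zero in a pair) get a zero half-width:
#' the pair is non-significant when the difference is also zero and is
#' flagged \code{degenerate} (but significant) otherwise.
#'
#' @param x numeric matrix (rows = MREs, columns = samples) of normalized
#'   log2 values, or a single numeric vector.
#' @param groups group label per column; at least 2 groups with n >= 2 each.
#' @param alpha family-wise error target (default 0.05).
#' @return a \link[S4Vectors]{DataFrame} in long format: \code{key} (row
#'   name), \code{group_i}, \code{group_j}, \code{diff}, \code{halfwidth},
#'   \code{significant}, \code{degenerate}; the group levels and alpha are
#'   kept in \code{metadata()}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 2, dimnames = list(c("g1|m1", "g2|m1"), NULL))
#' dtkTest(x, rep(c("a", "b", "c"), each = 10))
#' @export
dtkTest <- function(x, groups, alpha = 0.05) {
    if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list("row1", NULL))
    x <- as.matrix(x)
    groups <- factor(groups)
    if (ncol(x) != length(groups)) stop("one group label per column needed")
    k <- nlevels(groups)
    if (k < 2) stop("need at least 2 groups")
    n <- as.vector(table(groups))
    if (any(n < 2)) stop("every group needs n >= 2: ",
                         paste(levels(groups)[n < 2], collapse = ", "))
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
    if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
    sums <- t(rowsum(t(x), groups))          # rows x groups
    sq <- t(rowsum(t(x)^2, groups))
    means <- sweep(sums, 2, n, "/")
    vars <- sweep(sq - sweep(means^2, 2, n, "*"), 2, n - 1, "/")
    vars[vars < 0] <- 0                      # numerical guard
    qv <- stats::qtukey(1 - alpha, k, n - 1)
    pairs <- utils::combn(k, 2)
    out <- vector("list", ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
        i <- pairs[1, p]; j <- pairs[2, p]
        vi <- vars[, i] / n[i]; vj <- vars[, j] / n[j]
        se2 <- vi + vj
        d <- means[, i] - means[, j]
        w <- ifelse(se2 > 0,
                    (qv[i] * vi + qv[j] * vj) / se2 * sqrt(se2) / sqrt(2),
                    0)
        degen <- se2 == 0 & d != 0
        out[[p]] <- S4Vectors::DataFrame(
            key = rownames(x),
            group_i = levels(groups)[i], group_j = levels(groups)[j],
            diff = unname(d), halfwidth = unname(w),
            significant = unname(abs(d) > w), degenerate = unname(degen))
    }
    res <- do.call(rbind, out)
    S4Vectors::metadata(res) <- list(alpha = alpha, groups = levels(groups),
                                     n = stats::setNames(n, levels(groups)))
    res
}

#' Select target-group-specific MREs from a DTK result
#'
#' An MRE is target-specific when every one of the k-1 pairwise comparisons
#' involving the target group is significant and all k-1 target-minus-other
#' differences share one sign -- the target group sits apart from, and on
#' the same side of, every other group.
#'
#' @param dtk result of \code{\link{dtkTest}}.
#' @param targetGroup the group whose specific MREs are sought.
#' @param requireSignConsistency require one common sign across the k-1
#'   differences (default TRUE; set FALSE to accept mixed directions).
#' @return character vector of selected MRE keys (sorted).
#' @export
selectTargetSpecific <- function(dtk, targetGroup,
                                 requireSignConsistency = TRUE) {
    lv <- S4Vectors::metadata(dtk)$groups
    if (!targetGroup %in% lv)
        stop("unknown target group: ", targetGroup)
    inv <- dtk$group_i == targetGroup | dtk$group_j == targetGroup
    sub <- dtk[inv, , drop = FALSE]
    # orient every difference as target minus other
    d <- ifelse(sub$group_j == targetGroup, -sub$diff, sub$diff)
    keys <- unique(dtk$key)
    km1 <- length(lv) - 1L
    byKey <- split(seq_len(nrow(sub)), sub$key)
    if (any(lengths(byKey) != km1))
        stop("missing pairwise comparison(s) for some MRE keys")
    sel <- vapply(byKey, function(idx) {
        all(sub$significant[idx]) &&
            (!requireSignConsistency ||
             all(d[idx] > 0) || all(d[idx] < 0))
    }, logical(1))
    sort(names(sel)[sel])
}
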