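# Shared Wilcoxon rank-sum machinery.  One vectorized path for whole
# expression matrices (normal approximation with midranks, tie correction and
# continuity correction) and one exact path (enumeration of all C(n, n1)
# group assignments of the pooled midranks) used for small samples and as the
# default when n1 + n2 <= 20.

# Mann-Whitney U for a single vector: pairs won by the `positive` group,
# ties counted 1/2 (midrank convention).
.mann_whitney_u <- function(x, positive) {
    r <- rank(x, ties.method = "average")
    n1 <- sum(positive)
    sum(r[positive]) - n1 * (n1 + 1) / 2
}

# Exact rank-sum p by enumeration of group assignments (handles ties via
# midranks).  Inclusive convention: p = P(statistic at least as extreme as
# observed), matching stats::wilcox.test.
.rank_sum_exact <- function(x, positive,
                            alternative = c("greater", "two.sided", "less")) {
    alternative <- match.arg(alternative)
    n <- length(x)
    n1 <- sum(positive)
    n2 <- n - n1
    r <- rank(x, ties.method = "average")
    u_obs <- sum(r[positive]) - n1 * (n1 + 1) / 2
    idx <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    eps <- 1e-9
    switch(alternative,
        greater = mean(u_all >= u_obs - eps),
        less = mean(u_all <= u_obs + eps),
        two.sided = min(1, mean(abs(u_all - mu) >= abs(u_obs - mu) - eps)))
}

# Normal approximation with tie correction and continuity correction for a
# single vector.
.rank_sum_normal <- function(x, positive,
                             alternative = c("greater", "two.sided", "less"),
                             continuity = TRUE) {
    alternative <- match.arg(alternative)
    n <- length(x)
    n1 <- sum(positive)
    n2 <- n - n1
    u <- .mann_whitney_u(x, positive)
    tt <- tabulate(match(x, unique(x)))
    tie <- sum(tt^3 - tt)
    s2 <- n1 * n2 / 12 * ((n + 1) - tie / (n * (n - 1)))
    if (s2 <= 0) return(list(u = u, p = 1))
    mu <- n1 * n2 / 2
    cc <- if (continuity) 0.5 else 0
    p <- switch(alternative,
        greater = stats::pnorm((u - mu - cc) / sqrt(s2), lower.tail = FALSE),
        less = stats::pnorm((u - mu + cc) / sqrt(s2)),
        two.sided = min(1, 2 * stats::pnorm(
            (abs(u - mu) - cc) / sqrt(s2), lower.tail = FALSE)))
    list(u = u, p = p)
}

# One rank-sum test, choosing the exact path when the pooled size permits.
.rank_sum_test <- function(x, positive, alternative = "greater",
                           exact = NULL) {
    n <- length(x)
    if (is.null(exact)) exact <- n <= 20
    u <- .mann_whitney_u(x, positive)
    if (exact)
        list(u = u, p = .rank_sum_exact(x, positive, alternative),
             exact = TRUE)
    else
        c(.rank_sum_normal(x, positive, alternative), list(exact = FALSE))
}

# Vectorized rank-sum over the rows of a matrix: returns U, p per row.
.rank_sum_matrix <- function(mat, positive, alternative = "greater",
                             continuity = TRUE) {
    n <- ncol(mat)
    n1 <- sum(positive)
    n2 <- n - n1
    rk <- .row_ranks(mat)
    u <- rowSums(rk[, positive, drop = FALSE]) - n1 * (n1 + 1) / 2
    tie <- .row_tie_term(mat)
    s2 <- n1 * n2 / 12 * ((n + 1) - tie / (n * (n - 1)))
    mu <- n1 * n2 / 2
    cc <- if (continuity) 0.5 else 0
    sd <- sqrt(pmax(s2, 0))
    p <- rep(1, nrow(mat))
    ok <- s2 > 0
    if (any(ok)) {
        z <- switch(alternative,
            greater = (u[ok] - mu - cc) / sd[ok],
            less = -((u[ok] - mu + cc) / sd[ok]),
            two.sided = (abs(u[ok] - mu) - cc) / sd[ok])
        pr <- stats::pnorm(z, lower.tail = FALSE)
        if (alternative == "two.sided") pr <- pmin(1, 2 * pr)
        p[ok] <- pr
    }
    list(u = u, p = p)
}
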