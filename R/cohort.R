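#' @include AllClasses.R ranksum.R
NULL

#' Differential-expression configuration
#'
#' @param lfcThreshold log2 fold-change threshold (1.5 by default).
#' @param fdrThreshold BH-adjusted p-value threshold (0.01 by default).
#' @param signed require \code{lfc > lfcThreshold} instead of
#'   \code{|lfc| > lfcThreshold}.
#' @export
deConfig <- function(lfcThreshold = 1.5, fdrThreshold = 0.01,
                     signed = FALSE) {
    .stop_if(lfcThreshold <= 0 || fdrThreshold <= 0,
             "thresholds must be positive")
    structure(list(lfcThreshold = lfcThreshold, fdrThreshold = fdrThreshold,
                   signed = signed), class = "de_config")
}

#' Global and pairwise rank tests on group scores
#'
#' Kruskal-Wallis test (with tie correction) across all groups, plus a
#' matrix of pairwise two-sided rank-sum p-values (exact enumeration for
#' pooled sizes up to 20).  Pairwise p-values are unadjusted unless
#' \code{adjust} names a \code{p.adjust} method.
#'
#' @param scores numeric vector or \linkS4class{ScoreVector}.
#' @param groups group labels (>= 2 non-empty groups).
#' @param adjust multiplicity adjustment for the pairwise matrix
#'   ("none" by default).
#' @return list(kw_statistic, kw_df, kw_p, pairwise_p).
#' @export
rankTests <- function(scores, groups, adjust = "none") {
    s <- if (is(scores, "ScoreVector")) scores(scores) else scores
    g <- factor(groups)
    .stop_if(nlevels(g) < 2, "need at least 2 groups")
    .stop_if(any(table(g) == 0), "every group must be non-empty")
    if (stats::sd(s) == 0) {
        # fully tied scores carry no rank information; the tie-corrected
        # statistic is 0/0, reported here as the degenerate 0
        kw <- list(statistic = 0, parameter = nlevels(g) - 1L, p.value = 1)
    } else {
        kw <- stats::kruskal.test(s, g)
    }
    lv <- levels(g)
    pw <- matrix(NA_real_, nlevels(g), nlevels(g), dimnames = list(lv, lv))
    for (i in seq_len(nlevels(g) - 1L)) for (j in (i + 1L):nlevels(g)) {
        sel <- g %in% lv[c(i, j)]
        pw[i, j] <- pw[j, i] <-
            .rank_sum_test(s[sel], g[sel] == lv[i], "two.sided")$p
    }
    if (adjust != "none") {
        up <- upper.tri(pw)
        pw[up] <- stats::p.adjust(pw[up], method = adjust)
        pw[lower.tri(pw)] <- t(pw)[lower.tri(pw)]
    }
    list(kw_statistic = unname(kw$statistic), kw_df = unname(kw$parameter),
         kw_p = kw$p.value, pairwise_p = pw)
}

#' Response ROC analysis of signature scores
#'
#' AUC of the scores for discriminating responders (positives) from
#' non-responders by the pair-counting rule (ties one half), a two-sided
#' rank-sum p-value, and the waterfall ordering (samples by descending
#' score).
#'
#' @param scores numeric vector (named by sample) or
#'   \linkS4class{ScoreVector}.
#' @param responder 0/1 (or logical) responder flags, aligned to the
#'   scores.
#' @return list(auc, p_value, n_responder, n_nonresponder, waterfall).
#' @export
responseAUC <- function(scores, responder) {
    s <- if (is(scores, "ScoreVector")) scores(scores) else scores
    pos <- as.logical(responder)
    .stop_if(length(pos) != length(s),
             "'responder' must align with the scores")
    .stop_if(!any(pos) || all(pos), "both classes must be present")
    n1 <- sum(pos)
    n2 <- sum(!pos)
    auc <- .mann_whitney_u(s, pos) / (n1 * n2)
    p <- .rank_sum_test(s, pos, "two.sided")$p
    ord <- order(s, decreasing = TRUE)
    wf <- data.frame(sample_id = if (!is.null(names(s))) names(s)[ord]
                     else as.character(ord),
                     score = s[ord], responder = as.integer(pos)[ord],
                     row.names = NULL)
    list(auc = auc, p_value = p, n_responder = n1, n_nonresponder = n2,
         waterfall = wf)
}

#' Two-group differential expression (Welch t-test)
#'
#' Per-gene Welch (unequal-variance) t-test between two groups of log2
#' expression profiles; the log2 fold change is the difference of group
#' means (first factor level minus second).  Genes are significant iff the
#' fold change passes \code{lfcThreshold} (absolute by default) AND the BH
#' FDR is below \code{fdrThreshold}.
#'
#' @param expr matrix or \linkS4class{ReactivityExperiment} on log2 scale.
#' @param groups two-level labels, one per column (each group >= 2).
#' @param config a \code{\link{deConfig}}.
#' @return data.frame: gene, lfc, t, df, p_value, fdr, significant,
#'   direction.
#' @export
groupDE <- function(expr, groups, config = deConfig()) {
    mat <- .expr_input(expr)$values
    g <- factor(groups)
    .stop_if(nlevels(g) != 2, "exactly two groups are required")
    n1 <- sum(g == levels(g)[1])
    n2 <- sum(g == levels(g)[2])
    .stop_if(n1 < 2 || n2 < 2, "each group needs at least 2 samples")
    m1 <- rowMeans(mat[, g == levels(g)[1], drop = FALSE])
    m2 <- rowMeans(mat[, g == levels(g)[2], drop = FALSE])
    v1 <- apply(mat[, g == levels(g)[1], drop = FALSE], 1L, stats::var)
    v2 <- apply(mat[, g == levels(g)[2], drop = FALSE], 1L, stats::var)
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tt), df)
    # identical constant groups: no evidence, not NaN
    degen <- !is.finite(tt)
    tt[degen] <- 0
    p[degen] <- 1
    df[degen] <- n1 + n2 - 2
    fdr <- stats::p.adjust(p, method = "BH")
    lfc <- m1 - m2
    pass_lfc <- if (config$signed) lfc > config$lfcThreshold
                else abs(lfc) > config$lfcThreshold
    data.frame(gene = rownames(mat), lfc = lfc, t = tt, df = df,
               p_value = p, fdr = fdr,
               significant = pass_lfc & fdr < config$fdrThreshold,
               direction = ifelse(lfc >= 0, levels(g)[1], levels(g)[2]),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Midrank Spearman rho with a t-approximation p-value
#' (\code{t = rho * sqrt((n - 2) / (1 - rho^2))} on n - 2 df); for small
#' samples (n <= 8) an exact permutation p-value can be requested.
#'
#' @param x,y equal-length numeric vectors, n >= 3, non-constant.
#' @param exact use exact permutation enumeration (n <= 8 only).
#' @return list(rho, p_value, n, method).
#' @export
spearmanAssoc <- function(x, y, exact = FALSE) {
    .stop_if(length(x) != length(y), "'x' and 'y' must have equal length")
    n <- length(x)
    .stop_if(n < 3, "need at least 3 observations")
    .stop_if(stats::sd(x) == 0 || stats::sd(y) == 0,
             "constant input; rank correlation undefined")
    rx <- rank(x, ties.method = "average")
    ry <- rank(y, ties.method = "average")
    rho <- stats::cor(rx, ry)
    if (exact) {
        .stop_if(n > 8, "exact enumeration supported for n <= 8 only")
        perms <- .permutations(n)
        rho_all <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
        p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
        return(list(rho = rho, p_value = p, n = n, method = "exact"))
    }
    if (abs(rho) >= 1) {
        p <- 0
    } else {
        tt <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * stats::pt(-abs(tt), n - 2)
    }
    list(rho = rho, p_value = p, n = n, method = "t-approximation")
}
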