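#' @include AllClasses.R
NULL

#' Scoring configuration
#'
#' Parameters of the five single-sample gene-set statistics.  Defaults mirror
#' the reference defaults of the corresponding scorers: Gaussian kernel with
#' bandwidth s_i/4 and Poisson offset 0.5 for the kernel-CDF statistic,
#' walk exponent \code{tau = 1} and \code{esMode = "max_diff"} for its KS
#' enrichment walk, rank weight \code{rwksAlpha = 0.25} with cohort
#' normalization for the rank-weighted KS walk, and a top 5\% ranking
#' threshold for the per-cell recovery-curve score.
#'
#' @param method one of \code{"kcdf_ks"}, \code{"rank_weighted_ks"},
#'   \code{"combined_z"}, \code{"first_singular_vector"}, \code{"mean"},
#'   \code{"ranking_recovery"}.
#' @param kernel kernel for the kernel-CDF statistic.
#' @param poissonOffset rate offset r of the Poisson kernel.
#' @param tau walk weight exponent (>= 0).
#' @param esMode \code{"max_diff"} (largest positive deviation minus largest
#'   absolute negative deviation) or \code{"max_abs"} (single maximum
#'   magnitude deviation).
#' @param rwksAlpha rank weight exponent of the rank-weighted KS walk.
#' @param rwksNormalize divide rank-weighted KS scores by their cohort range.
#' @param recoveryTopFraction fraction of genes defining the ranking
#'   threshold of the recovery score, in (0, 1).
#' @param plageOrient orient the first singular vector so that it correlates
#'   non-negatively with the mean signature z-score.
#' @param tieMethod \code{"random"} (seeded) or \code{"first"} tie-breaking
#'   for per-cell rankings.
#' @param seed seed for randomized tie-breaking.
#' @return a validated config list.
#' @export
scoringConfig <- function(method = c("kcdf_ks", "rank_weighted_ks",
                                     "combined_z", "first_singular_vector",
                                     "mean", "ranking_recovery"),
                          kernel = c("gaussian", "poisson"),
                          poissonOffset = 0.5, tau = 1,
                          esMode = c("max_diff", "max_abs"),
                          rwksAlpha = 0.25, rwksNormalize = TRUE,
                          recoveryTopFraction = 0.05, plageOrient = TRUE,
                          tieMethod = c("random", "first"), seed = 1L) {
    method <- match.arg(method)
    kernel <- match.arg(kernel)
    esMode <- match.arg(esMode)
    tieMethod <- match.arg(tieMethod)
    .stop_if(tau < 0, "'tau' must be >= 0")
    .stop_if(recoveryTopFraction <= 0 || recoveryTopFraction >= 1,
             "'recoveryTopFraction' must be in (0, 1)")
    structure(list(method = method, kernel = kernel,
                   poissonOffset = poissonOffset, tau = tau, esMode = esMode,
                   rwksAlpha = rwksAlpha, rwksNormalize = rwksNormalize,
                   recoveryTopFraction = recoveryTopFraction,
                   plageOrient = plageOrient, tieMethod = tieMethod,
                   seed = as.integer(seed)),
              class = "scoring_config")
}

#' Kernel-CDF expression statistic
#'
#' For each gene i and sample j, the statistic is the kernel estimate of the
#' expression CDF evaluated at x_ij:
#' \code{z_ij = (1/n) sum_k K(x_ij; x_ik)}, with a Gaussian kernel
#' \code{pnorm((x_ij - x_ik) / h_i)} of bandwidth \code{h_i = s_i / 4}
#' (per-gene sample SD over 4) for continuous profiles, or a Poisson kernel
#' \code{ppois(x_ij, x_ik + r)} for raw counts.  Genes with zero variance
#' are assigned the constant row 0.5 instead of an undefined 0/0 bandwidth,
#' so the gene universe stays aligned across methods.
#'
#' @param expr matrix or \linkS4class{ReactivityExperiment}; the Poisson
#'   kernel requires declared raw counts with non-negative integer-like
#'   values.
#' @param kernel "gaussian" or "poisson".
#' @param poissonOffset rate offset r (default 0.5).
#' @param scale optional scale declaration for bare matrices.
#' @return matrix of the same shape and dimnames as the input.
#' @export
kernelCdfStat <- function(expr, kernel = c("gaussian", "poisson"),
                          poissonOffset = 0.5, scale = NULL) {
    kernel <- match.arg(kernel)
    need <- if (kernel == "poisson") "counts" else NULL
    mat <- .expr_input(expr, scale = scale, need = need)$values
    n <- ncol(mat)
    .stop_if(n < 3, "need at least 3 samples for a kernel CDF estimate")
    out <- matrix(NA_real_, nrow(mat), n, dimnames = dimnames(mat))
    if (kernel == "gaussian") {
        for (i in seq_len(nrow(mat))) {
            x <- mat[i, ]
            h <- stats::sd(x) / 4
            if (!is.finite(h) || h == 0) {
                out[i, ] <- 0.5
            } else {
                out[i, ] <- colMeans(stats::pnorm(
                    (matrix(x, n, n, byrow = TRUE) - x) / h))
            }
        }
    } else {
        .stop_if(any(mat < 0) || any(abs(mat - round(mat)) > 1e-8),
                 "Poisson kernel requires non-negative integer-like counts")
        for (i in seq_len(nrow(mat))) {
            x <- mat[i, ]
            if (stats::sd(x) == 0) {
                out[i, ] <- 0.5
            } else {
                out[i, ] <- colMeans(stats::ppois(
                    matrix(x, n, n, byrow = TRUE), lambda = x + poissonOffset))
            }
        }
    }
    out
}

# Weighted KS enrichment walk over one sample's gene-level statistic.
# Genes are ranked by `stat` descending (ties broken by gene index); the
# symmetrized rank |p/2 - rank| raised to `tau` weights in-set steps,
# out-of-set steps are uniform 1/(p - k).
.kcdf_ks_walk <- function(stat, in_set, tau, es_mode) {
    p <- length(stat)
    ord <- order(stat, decreasing = TRUE)
    r <- integer(p)
    r[ord] <- seq_len(p)
    rtilde <- abs(p / 2 - r)
    inset <- in_set[ord]
    w <- rtilde[ord]^tau * inset
    denom_in <- sum(w)
    p_in <- if (denom_in > 0) cumsum(w) / denom_in else cumsum(w)
    p_out <- cumsum(!inset) / (p - sum(in_set))
    dev <- p_in - p_out
    if (es_mode == "max_abs") {
        dev[which.max(abs(dev))]
    } else {
        max(c(0, dev[dev > 0])) - max(c(0, -dev[dev < 0]))
    }
}

# Rank-weighted KS walk (integrated running difference) for one sample.
.rank_weighted_walk <- function(x, in_set, alpha) {
    p <- length(x)
    rk <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    inset <- in_set[ord]
    w <- (rk[ord]^alpha) * inset
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!inset) / (p - sum(in_set))
    sum(p_in - p_out)
}

.match_signature <- function(mat, signature) {
    sig <- if (is(signature, "GeneSignature")) sigGenes(signature)
           else as.character(signature)
    present <- intersect(sig, rownames(mat))
    if (!length(present))
        stop("no signature gene present in the expression matrix; missing: ",
             paste(sig, collapse = ", "), call. = FALSE)
    missing <- setdiff(sig, present)
    if (length(missing))
        message(length(missing), " signature gene(s) absent: ",
                paste(missing, collapse = ", "))
    present
}

#' Score samples with a single-sample gene-set statistic
#'
#' Computes one signature score per sample with the method named in the
#' configuration:
#' \describe{
#'   \item{kcdf_ks}{kernel-CDF statistic (\code{\link{kernelCdfStat}})
#'     followed by a weighted KS enrichment walk per sample.}
#'   \item{rank_weighted_ks}{per-sample expression ranks drive a weighted KS
#'     walk whose running differences are summed; scores are normalized by
#'     their cohort range when \code{rwksNormalize}.}
#'   \item{combined_z}{per-gene z-scores across samples summed over the
#'     signature and divided by sqrt(k).}
#'   \item{first_singular_vector}{entries of the first right singular vector
#'     of the z-scored signature submatrix, sign-oriented so that its
#'     correlation with the mean signature z-score is non-negative (set
#'     \code{plageOrient = FALSE} for the raw, sign-arbitrary vector).}
#'   \item{mean}{mean signature-gene expression per sample.}
#' }
#'
#' @param expr matrix or \linkS4class{ReactivityExperiment}.
#' @param signature \linkS4class{GeneSignature} or character vector; at
#'   least one signature gene must be present (absent genes are reported).
#' @param config a \code{\link{scoringConfig}}.
#' @param statMatrix optional precomputed \code{\link{kernelCdfStat}} matrix
#'   (kcdf_ks only; the kernel statistic does not depend on the signature,
#'   so repeated scoring of gene subsets can share it).
#' @param scale optional scale declaration for bare matrices.
#' @return a \linkS4class{ScoreVector}.
#' @examples
#' m <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
#' sv <- scoreSamples(m, paste0("G", 1:4),
#'                    scoringConfig(method = "combined_z"))
#' scores(sv)
#' @export
scoreSamples <- function(expr, signature, config = scoringConfig(),
                         statMatrix = NULL, scale = NULL) {
    mat <- .expr_input(expr, scale = scale)$values
    sig <- .match_signature(mat, signature)
    k <- length(sig)
    in_set <- rownames(mat) %in% sig
    score <- switch(config$method,
        kcdf_ks = {
            .stop_if(all(in_set),
                     "the signature covers the whole gene universe; the ",
                     "out-of-set walk increment is undefined")
            z <- statMatrix %||%
                kernelCdfStat(expr, kernel = config$kernel,
                              poissonOffset = config$poissonOffset,
                              scale = scale)
            apply(z, 2L, .kcdf_ks_walk, in_set = in_set, tau = config$tau,
                  es_mode = config$esMode)
        },
        rank_weighted_ks = {
            .stop_if(all(in_set),
                     "the signature covers the whole gene universe; the ",
                     "out-of-set walk increment is undefined")
            es <- apply(mat, 2L, .rank_weighted_walk, in_set = in_set,
                        alpha = config$rwksAlpha)
            if (config$rwksNormalize) {
                rng <- max(es) - min(es)
                .stop_if(rng == 0,
                         "all samples share the same score; range ",
                         "normalization is undefined")
                es <- es / rng
            }
            es
        },
        combined_z = {
            z <- .row_zscores(mat[sig, , drop = FALSE])
            colSums(z) / sqrt(k)
        },
        first_singular_vector = {
            z <- .row_zscores(mat[sig, , drop = FALSE])
            sv <- svd(z, nu = 0, nv = 1)
            v <- sv$v[, 1]
            if (config$plageOrient) {
                ref <- colMeans(z)
                s <- sum(v * ref)
                if (is.finite(s) && s < 0) v <- -v
            }
            v
        },
        mean = colMeans(mat[sig, , drop = FALSE]),
        ranking_recovery = stop(
            "use scoreCellsRecovery() for the ranking-recovery statistic",
            call. = FALSE))
    ScoreVector(ids = colnames(mat), score = score, method = config$method,
                config = config[setdiff(names(config), "method")])
}

# z-score each row; zero-variance rows become all-zero (documented).
.row_zscores <- function(mat) {
    mu <- rowMeans(mat)
    s <- apply(mat, 1L, stats::sd)
    z <- (mat - mu) / ifelse(s > 0, s, 1)
    z[s == 0, ] <- 0
    z
}

#' Per-cell ranking-recovery (AUCell-style) score
#'
#' For each cell, genes are ranked by expression descending (ties broken at
#' random under the configured seed, or by first occurrence).  With ranking
#' threshold \code{T = ceiling(recoveryTopFraction * p)}, the score is the
#' area under the step recovery curve -- the number of signature genes found
#' among the top i ranks, accumulated for i = 1..T -- normalized by the
#' maximal possible area, so scores lie in [0, 1].
#'
#' @inheritParams scoreSamples
#' @return a \linkS4class{ScoreVector} of per-cell scores.
#' @export
scoreCellsRecovery <- function(expr, signature, config = scoringConfig(
                                   method = "ranking_recovery"),
                               scale = NULL) {
    mat <- .expr_input(expr, scale = scale)$values
    sig <- .match_signature(mat, signature)
    p <- nrow(mat)
    k <- length(sig)
    thr <- ceiling(config$recoveryTopFraction * p)
    if (k > thr)
        warning("signature size (", k, ") exceeds the ranking threshold (",
                thr, "); scores cannot reach 1")
    in_set <- rownames(mat) %in% sig
    max_area <- sum(pmin(seq_len(thr), k))
    ties <- if (config$tieMethod == "random") "random" else "first"
    score <- .with_seed(config$seed, {
        apply(mat, 2L, function(x) {
            r <- rank(-x, ties.method = ties)
            sr <- r[in_set]
            sr <- sr[sr <= thr]
            if (!length(sr)) return(0)
            sum(thr - sr + 1) / max_area
        })
    })
    ScoreVector(ids = colnames(mat), score = score,
                method = "ranking_recovery",
                config = config[setdiff(names(config), "method")])
}
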