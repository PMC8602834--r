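#' @include AllClasses.R ranksum.R
NULL

.resolve_labels <- function(expr, labels) {
    if (is.null(labels) && is(expr, "ReactivityExperiment"))
        labels <- colData(expr)$state
    .stop_if(is.null(labels), "'labels' are required")
    mat <- .expr_input(expr)$values
    .stop_if(length(labels) != ncol(mat),
             "'labels' must have one entry per observation")
    list(values = mat, labels = as.character(labels))
}

#' Rank-sum marker test of one state against the rest
#'
#' Per-gene Wilcoxon rank-sum test of the target state versus all other
#' cells, one-sided ("greater in target") by default because markers are
#' defined as over-expressed genes.  Midranks handle ties; p-values use the
#' normal approximation with tie and continuity correction, or exact
#' enumeration over group assignments when the pooled sample size is at most
#' 20 (or when \code{exact = TRUE}).  Benjamini-Hochberg adjustment is
#' applied across all tested genes; genes are flagged candidate when
#' FDR < \code{alphaFdr}.
#'
#' @param expr matrix or \linkS4class{ReactivityExperiment}.
#' @param labels per-observation state labels (taken from colData when NULL).
#' @param target the state treated as positive.
#' @param alphaFdr candidate threshold on the adjusted p-value.
#' @param alternative "greater" (default), "two.sided" or "less".
#' @param exact force (TRUE) or forbid (FALSE) exact enumeration;
#'   NULL = automatic (n <= 20).
#' @return data.frame with columns gene, statistic (Mann-Whitney U), p_value,
#'   fdr, mean_target, mean_rest, up, candidate.
#' @export
wilcoxonMarkers <- function(expr, labels = NULL, target, alphaFdr = 0.05,
                            alternative = c("greater", "two.sided", "less"),
                            exact = NULL) {
    alternative <- match.arg(alternative)
    inp <- .resolve_labels(expr, labels)
    mat <- inp$values
    pos <- inp$labels == target
    .stop_if(!any(pos), "target state '", target, "' not present in labels")
    .stop_if(sum(pos) < 2 || sum(!pos) < 2,
             "need at least 2 observations inside and outside the target")
    n <- ncol(mat)
    if (is.null(exact)) exact <- n <= 20
    if (exact) {
        res <- apply(mat, 1L, function(x) {
            unlist(.rank_sum_test(x, pos, alternative, exact = TRUE)[
                c("u", "p")])
        })
        u <- res["u", ]
        p <- res["p", ]
    } else {
        res <- .rank_sum_matrix(mat, pos, alternative)
        u <- res$u
        p <- res$p
    }
    fdr <- stats::p.adjust(p, method = "BH")
    m1 <- rowMeans(mat[, pos, drop = FALSE])
    m0 <- rowMeans(mat[, !pos, drop = FALSE])
    up <- m1 > m0
    cand <- fdr < alphaFdr & if (alternative == "two.sided") up else TRUE
    data.frame(gene = rownames(mat), statistic = u, p_value = p, fdr = fdr,
               mean_target = m1, mean_rest = m0, up = up, candidate = cand,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' One-vs-rest ROC AUC per gene
#'
#' AUC = U / (n1 * n2): the fraction of (target, rest) pairs in which the
#' target cell has the higher value, ties counted one half (midrank
#' convention).  This equals the area under the empirical one-vs-rest ROC
#' curve and is invariant to strictly monotone per-gene transforms.
#'
#' @inheritParams wilcoxonMarkers
#' @return named numeric vector of AUCs, one per gene.
#' @examples
#' m <- matrix(c(3, 1, 2, 0), 1, dimnames = list("g", paste0("c", 1:4)))
#' geneAUC(m, labels = c("T", "T", "R", "R"), target = "T")  # 0.75
#' @export
geneAUC <- function(expr, labels = NULL, target) {
    inp <- .resolve_labels(expr, labels)
    mat <- inp$values
    pos <- inp$labels == target
    .stop_if(!any(pos) || all(pos),
             "both the target and the rest set must be non-empty")
    n1 <- sum(pos)
    n2 <- sum(!pos)
    rk <- .row_ranks(mat)
    u <- rowSums(rk[, pos, drop = FALSE]) - n1 * (n1 + 1) / 2
    structure(u / (n1 * n2), names = rownames(mat))
}

#' Extract the top-k signature from marker statistics
#'
#' Among genes that pass the FDR threshold and are up in the target, selects
#' the \code{k} with the highest one-vs-rest AUC; ties at the k-th AUC are
#' broken lexicographically by gene id.  If fewer than \code{k} candidates
#' exist, all are returned and a warning flag is recorded in the provenance.
#'
#' @param markers data.frame from \code{\link{wilcoxonMarkers}}.
#' @param aucs named AUC vector from \code{\link{geneAUC}} over the same
#'   gene universe.
#' @param k target signature size (20 by default).
#' @param provenance extra provenance entries to record.
#' @return a \linkS4class{GeneSignature}.
#' @export
deriveSignature <- function(markers, aucs, k = 20, provenance = list()) {
    .stop_if(!all(markers$gene %in% names(aucs)),
             "'aucs' must cover the marker gene universe")
    cand <- markers$gene[markers$candidate & markers$up]
    .stop_if(!length(cand), "no candidate genes at the given FDR threshold")
    a <- aucs[cand]
    ord <- order(-a, cand)
    sel <- ord[seq_len(min(k, length(cand)))]
    undersupplied <- length(cand) < k
    if (undersupplied)
        warning("only ", length(cand), " candidates for k = ", k)
    GeneSignature(genes = cand[sel], auc = unname(a[sel]), k = k,
                  provenance = c(provenance,
                                 list(n_candidates = length(cand),
                                      undersupplied = undersupplied)))
}

#' Derive a tumor-reactive signature from a labeled expression matrix
#'
#' Convenience wrapper running \code{\link{wilcoxonMarkers}},
#' \code{\link{geneAUC}} and \code{\link{deriveSignature}} in sequence.
#'
#' @inheritParams wilcoxonMarkers
#' @inheritParams deriveSignature
#' @return a \linkS4class{GeneSignature}.
#' @examples
#' sc <- simulateScDataset(scDesign(nGenes = 300, nCells = 200, seed = 11))
#' sig <- deriveTRS(sc, target = metadata(sc)$reactiveState)
#' sig
#' @export
deriveTRS <- function(expr, labels = NULL, target, k = 20, alphaFdr = 0.05,
                      alternative = "greater") {
    markers <- wilcoxonMarkers(expr, labels, target, alphaFdr = alphaFdr,
                               alternative = alternative)
    aucs <- geneAUC(expr, labels, target)
    deriveSignature(markers, aucs, k = k,
                    provenance = list(target = target, alphaFdr = alphaFdr))
}
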