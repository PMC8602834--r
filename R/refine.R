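#' @include AllClasses.R scoring.R survival.R
NULL

#' Stepwise AIC refinement of a signature under a univariate Cox objective
#'
#' Backward elimination in which every candidate deletion triggers a full
#' re-scoring of the remaining gene set before the Cox refit: (1) score the
#' samples on the current set; (2) fit the univariate Cox model on the score
#' and record its AIC; (3) for each gene, re-score on the set minus that
#' gene and refit; (4) if the best candidate AIC is strictly lower, remove
#' that gene (ties broken by the lexicographically smallest gene id) and
#' repeat, otherwise stop.  Because every fit is univariate, an accepted
#' removal is exactly an increase in partial log-likelihood; this
#' equivalence is asserted at every step.  Candidates whose Cox fit fails
#' are skipped with a note; the loop never empties the signature.
#'
#' For the kernel-CDF scorer the kernel statistic is computed once on the
#' full matrix and shared across all candidate subsets (it does not depend
#' on the gene set).
#'
#' @param expr matrix or \linkS4class{ReactivityExperiment} over the
#'   scoring gene universe.
#' @param signature starting \linkS4class{GeneSignature}.
#' @param survival data.frame with columns sample_id, time, event (aligned
#'   to the matrix columns by sample_id).
#' @param scoring a \code{\link{scoringConfig}} (default: kernel-CDF KS
#'   scorer).
#' @param evaluation an \code{\link{evalConfig}}.
#' @return list with \code{signature} (refined \linkS4class{GeneSignature})
#'   and \code{trace} (data.frame: step, gene_removed, aic_before,
#'   aic_after, n_genes_after, loglik_after, note).
#' @examples
#' sig <- GeneSignature(paste0("SIG", 1:5))
#' coh <- simulateBulkCohort(cohortDesign(nSamples = 60, seed = 5), sig)
#' ref <- refineSignature(coh$expr, sig, coh$survival,
#'                        scoringConfig(method = "combined_z"))
#' ref$trace
#' @export
refineSignature <- function(expr, signature, survival,
                            scoring = scoringConfig(),
                            evaluation = evalConfig()) {
    mat <- .expr_input(expr)$values
    .stop_if(!is(signature, "GeneSignature"), "'signature' must be a GeneSignature")
    .stop_if(!all(c("sample_id", "time", "event") %in% names(survival)),
             "'survival' needs columns sample_id, time, event")
    idx <- match(colnames(mat), survival$sample_id)
    .stop_if(anyNA(idx), "every matrix column needs a survival record")
    surv <- survival[idx, ]
    .stop_if(sum(surv$event) < 1, "need at least one event")
    current <- intersect(sigGenes(signature), rownames(mat))
    .stop_if(!length(current), "no signature gene present in 'expr'")

    stat <- if (scoring$method == "kcdf_ks")
        kernelCdfStat(expr, kernel = scoring$kernel,
                      poissonOffset = scoring$poissonOffset)
    else NULL
    fit_set <- function(genes) {
        sv <- scoreSamples(mat, genes, scoring, statMatrix = stat)
        f <- coxFit(scores(sv), surv$time, surv$event, evaluation)
        .stop_if(!f@converged, "Cox fit did not converge")
        list(aic = f@aic, loglik = f@loglik)
    }

    trace <- data.frame(step = integer(), gene_removed = character(),
                        aic_before = numeric(), aic_after = numeric(),
                        n_genes_after = integer(), loglik_after = numeric(),
                        note = character(), stringsAsFactors = FALSE)
    base <- fit_set(current)
    step <- 0L
    while (length(current) > 1L) {
        cand_aic <- rep(NA_real_, length(current))
        cand_ll <- rep(NA_real_, length(current))
        notes <- character(length(current))
        for (i in seq_along(current)) {
            res <- tryCatch(fit_set(setdiff(current, current[i])),
                            error = function(e) e)
            if (inherits(res, "error")) {
                notes[i] <- conditionMessage(res)
            } else {
                cand_aic[i] <- res$aic
                cand_ll[i] <- res$loglik
            }
        }
        if (all(is.na(cand_aic))) {
            warning("all candidate deletions failed to fit; stopping")
            break
        }
        best <- min(cand_aic, na.rm = TRUE)
        if (!(best < base$aic)) break     # strict improvement required
        pick <- which(cand_aic == best)
        pick <- pick[order(current[pick])][1L]   # lexicographic tie-break
        # univariate equivalence: lower AIC <=> higher partial log-likelihood
        stopifnot(cand_ll[pick] > base$loglik)
        step <- step + 1L
        trace <- rbind(trace, data.frame(
            step = step, gene_removed = current[pick],
            aic_before = base$aic, aic_after = best,
            n_genes_after = length(current) - 1L,
            loglik_after = cand_ll[pick],
            note = if (any(nzchar(notes)))
                paste(notes[nzchar(notes)], collapse = "; ") else "",
            stringsAsFactors = FALSE))
        current <- setdiff(current, current[pick])
        base <- list(aic = best, loglik = cand_ll[pick])
    }
    auc <- sigAUC(signature)[current]
    refined <- GeneSignature(
        genes = current, auc = unname(auc), k = signature@k,
        provenance = c(signature@provenance,
                       list(refined = TRUE, steps = step,
                            final_aic = base$aic,
                            scoring_method = scoring$method)))
    list(signature = refined, trace = trace)
}
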