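#' @include AllClasses.R AllGenerics.R
NULL

#' Simulate a single-cell expression matrix with a planted reactive state
#'
#' Generates a log2-scale gene-by-cell matrix over \code{nStates} discrete
#' transcriptional states.  Exactly \code{nSignatureGenes} planted genes have
#' their mean shifted upward by \code{markerShift} log2 units in the reactive
#' state only; all genes are subject to independent Bernoulli dropout and the
#' result is truncated at zero to emulate log-normalized single-cell data.
#' The planted gene ids, the state labels and the patient assignment are
#' returned as ground truth so recovery can be tested downstream.
#'
#' @param design a \linkS4class{ScDesign}.
#' @return A \linkS4class{ReactivityExperiment} (scale \code{"log2"}) whose
#'   \code{colData} holds \code{cell_id}, \code{state}, \code{patient}, and
#'   whose metadata holds \code{plantedGenes}, \code{reactiveState} and the
#'   design.
#' @examples
#' sc <- simulateScDataset(scDesign(nGenes = 100, nCells = 60, seed = 7))
#' table(colData(sc)$state)
#' @export
simulateScDataset <- function(design = scDesign()) {
    validObject(design)
    d <- design
    .with_seed(d@seed, {
        genes <- sprintf("G%05d", seq_len(d@nGenes))
        cells <- sprintf("C%05d", seq_len(d@nCells))
        states <- paste0("S", seq_len(d@nStates))
        reactive <- states[d@reactiveState]
        # balanced random state / patient assignment
        state <- sample(rep_len(states, d@nCells))
        patient <- sample(rep_len(sprintf("P%02d", seq_len(d@nPatients)),
                                  d@nCells))
        planted <- sort(sample(genes, d@nSignatureGenes))
        mu <- stats::rnorm(d@nGenes, d@baseMean, 0.5)
        mat <- mu + matrix(stats::rnorm(d@nGenes * d@nCells, 0, d@noiseSd),
                           d@nGenes, d@nCells)
        dimnames(mat) <- list(genes, cells)
        is_reactive <- state == reactive
        if (any(is_reactive))
            mat[planted, is_reactive] <- mat[planted, is_reactive] +
                d@markerShift
        if (d@dropoutRate > 0) {
            drop <- matrix(stats::runif(length(mat)) < d@dropoutRate,
                           d@nGenes, d@nCells)
            mat[drop] <- 0
        }
        mat <- pmax(mat, 0)
        ReactivityExperiment(
            mat, scale = "log2",
            colData = DataFrame(cell_id = cells, state = state,
                                patient = patient, row.names = cells),
            metadata = list(plantedGenes = planted, reactiveState = reactive,
                            design = d))
    })
}

#' Simulate a clonotype table enriched for expansion in the reactive state
#'
#' Every cell is assigned exactly one clonotype (an opaque
#' \code{"TRA:<k>|TRB:<k>"} alpha-beta pair).  Assignment is sequential in
#' random order with preferential attachment: an unoccupied clonotype has
#' weight 1 and an occupied one weight equal to its current size, so clones
#' grow; for cells of the reactive state the odds of joining an occupied
#' (expanding) clonotype are multiplied by \code{clonalEnrichment}.  Clone
#' sizes are capped at \code{maxCloneSize}.
#'
#' @param annotation a \linkS4class{ReactivityExperiment} from
#'   \code{\link{simulateScDataset}} or a data.frame with columns
#'   \code{cell_id}, \code{state} and \code{patient}.
#' @param design a \linkS4class{TcrDesign}.
#' @param reactiveState the state treated as reactive; taken from the
#'   experiment's metadata when \code{annotation} is a
#'   \linkS4class{ReactivityExperiment}.
#' @return A \linkS4class{ClonotypeTable} (global scope) with clone sizes and
#'   clonality classes filled in.
#' @export
simulateTcrTable <- function(annotation, design = tcrDesign(),
                             reactiveState = NULL) {
    validObject(design)
    if (is(annotation, "ReactivityExperiment")) {
        reactiveState <- reactiveState %||% metadata(annotation)$reactiveState
        annotation <- as.data.frame(colData(annotation))
    }
    .stop_if(!NROW(annotation), "'annotation' must be non-empty")
    .stop_if(is.null(reactiveState),
             "'reactiveState' must be given when annotation is a data.frame")
    n <- nrow(annotation)
    d <- design
    .with_seed(d@seed, {
        counts <- integer(d@nClonotypes)
        assign <- integer(n)
        is_reactive <- annotation$state == reactiveState
        for (i in sample.int(n)) {
            w <- ifelse(counts > 0, as.numeric(counts), 1)
            if (is_reactive[i])
                w[counts > 0] <- w[counts > 0] * d@clonalEnrichment
            w[counts >= d@maxCloneSize] <- 0
            .stop_if(all(w == 0),
                     "all clonotypes saturated; increase nClonotypes or ",
                     "maxCloneSize")
            k <- sample.int(d@nClonotypes, 1L, prob = w)
            counts[k] <- counts[k] + 1L
            assign[i] <- k
        }
        records <- data.frame(
            cell_id = annotation$cell_id,
            sample_id = annotation$patient,
            alpha = sprintf("TRA:%d", assign),
            beta = sprintf("TRB:%d", assign),
            stringsAsFactors = FALSE)
        classifyClonality(buildClonotypes(records, scope = "global"))
    })
}

# expression matrix shared by the bulk and response cohort generators
.cohort_expression <- function(d, signature) {
    sig <- sigGenes(signature)
    u <- stats::rnorm(d@nSamples)
    bg <- if (d@nBackgroundGenes > 0)
        sprintf("BG%05d", seq_len(d@nBackgroundGenes)) else character()
    genes <- c(sig, setdiff(bg, sig))
    samples <- sprintf("SAMP%04d", seq_len(d@nSamples))
    mu <- stats::rnorm(length(genes), 5, 1)
    mat <- mu + matrix(stats::rnorm(length(genes) * d@nSamples),
                       length(genes), d@nSamples)
    dimnames(mat) <- list(genes, samples)
    mat[sig, ] <- mat[sig, ] +
        matrix(d@signatureLoading * u, length(sig), d@nSamples, byrow = TRUE)
    list(u = u,
         expr = ReactivityExperiment(
             mat, scale = "log2",
             colData = DataFrame(sample_id = samples, row.names = samples),
             metadata = list(latentScore = u, design = d)))
}

#' Simulate a bulk cohort whose latent reactivity drives survival
#'
#' Each sample carries a latent reactivity score u ~ N(0, 1) that raises the
#' expression of the signature genes by \code{signatureLoading * u} (unit
#' Gaussian noise, log2 scale) and scales an exponential survival hazard,
#' \code{baselineHazard * exp(latentEffect * u)}, with independent
#' exponential censoring at rate \code{censorRate}.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @param signature a non-empty \linkS4class{GeneSignature} naming the genes
#'   coupled to the latent score.
#' @return list with \code{expr} (a \linkS4class{ReactivityExperiment}),
#'   \code{survival} (data.frame sample_id, time, event) and \code{latent}
#'   (the true scores).
#' @examples
#' sig <- GeneSignature(paste0("SIG", 1:5))
#' coh <- simulateBulkCohort(cohortDesign(nSamples = 50, seed = 3), sig)
#' head(coh$survival)
#' @export
simulateBulkCohort <- function(design = cohortDesign(), signature) {
    validObject(design)
    .stop_if(!is(signature, "GeneSignature") || !length(sigGenes(signature)),
             "'signature' must be a non-empty GeneSignature")
    d <- design
    .with_seed(d@seed, {
        base <- .cohort_expression(d, signature)
        haz <- d@baselineHazard * exp(d@latentEffect * base$u)
        t_event <- stats::rexp(d@nSamples, rate = haz)
        t_cens <- if (d@censorRate > 0)
            stats::rexp(d@nSamples, rate = d@censorRate) else Inf
        surv <- data.frame(
            sample_id = colnames(base$expr),
            time = pmin(t_event, t_cens),
            event = as.integer(t_event <= t_cens),
            stringsAsFactors = FALSE)
        list(expr = base$expr, survival = surv, latent = base$u)
    })
}

#' Simulate an immunotherapy-response cohort
#'
#' Expression is built exactly as in \code{\link{simulateBulkCohort}};
#' responder labels are Bernoulli with
#' \code{P(responder | u) = plogis(responseLogitSlope * u)}.
#'
#' @inheritParams simulateBulkCohort
#' @return list with \code{expr}, \code{response} (data.frame sample_id,
#'   responder) and \code{latent}.
#' @export
simulateResponseCohort <- function(design = cohortDesign(), signature) {
    validObject(design)
    .stop_if(!is(signature, "GeneSignature") || !length(sigGenes(signature)),
             "'signature' must be a non-empty GeneSignature")
    d <- design
    .with_seed(d@seed, {
        base <- .cohort_expression(d, signature)
        pr <- stats::plogis(d@responseLogitSlope * base$u)
        resp <- data.frame(
            sample_id = colnames(base$expr),
            responder = stats::rbinom(d@nSamples, 1L, pr),
            stringsAsFactors = FALSE)
        list(expr = base$expr, response = resp, latent = base$u)
    })
}
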