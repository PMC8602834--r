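#' @import methods
#' @importFrom S4Vectors metadata DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

## ---------------------------------------------------------------------------
## Expression container
## ---------------------------------------------------------------------------

.VALID_SCALES <- c("log2", "tpm", "counts")

#' Expression matrix with a declared scale
#'
#' A thin extension of \linkS4class{SummarizedExperiment} whose metadata must
#' declare the scale of the expression values (\code{"log2"}, \code{"tpm"} or
#' \code{"counts"}).  Downstream operations that are only meaningful on a
#' particular scale (e.g. the Poisson kernel CDF statistic, which expects raw
#' counts) consult this declaration and refuse undeclared input.
#'
#' @export
setClass("ReactivityExperiment", contains = "SummarizedExperiment")

setValidity("ReactivityExperiment", function(object) {
    sc <- metadata(object)$scale
    if (is.null(sc) || length(sc) != 1L || !sc %in% .VALID_SCALES)
        return(sprintf("metadata(object)$scale must be one of %s",
                       paste(.VALID_SCALES, collapse = ", ")))
    if (is.null(rownames(object)) || is.null(colnames(object)))
        return("row (gene) and column (observation) names are required")
    TRUE
})

#' Construct a ReactivityExperiment
#'
#' @param values numeric gene-by-observation matrix with dimnames.
#' @param scale one of \code{"log2"}, \code{"tpm"}, \code{"counts"}.
#' @param colData optional per-observation annotation (data.frame/DataFrame).
#' @param metadata optional list of extra metadata (merged with the scale).
#' @return A \linkS4class{ReactivityExperiment}.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("G", 1:4), paste0("C", 1:5)))
#' re <- ReactivityExperiment(m, scale = "log2")
#' exprScale(re)
#' @export
ReactivityExperiment <- function(values, scale = c("log2", "tpm", "counts"),
                                 colData = NULL, metadata = list()) {
    scale <- match.arg(scale)
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must have row and column names")
    metadata$scale <- scale
    if (is.null(colData))
        colData <- DataFrame(row.names = colnames(values))
    se <- SummarizedExperiment(assays = list(exprs = values),
                               colData = colData, metadata = metadata)
    new("ReactivityExperiment", se)
}

## ---------------------------------------------------------------------------
## Synthetic-data designs
## ---------------------------------------------------------------------------

#' Single-cell simulation design
#'
#' Parameters of the synthetic single-cell expression generator: a discrete
#' transcriptional-state landscape in which one ("reactive") state
#' over-expresses a planted gene set by \code{markerShift} log2 units.
#'
#' @slot nGenes,nCells,nStates,nPatients counts.
#' @slot reactiveState 1-based index of the reactive state.
#' @slot nSignatureGenes number of planted signature genes.
#' @slot markerShift additive log2-expression shift of planted genes in the
#'   reactive state (> 0, or 0 for null simulations).
#' @slot dropoutRate independent zero-inflation probability in [0, 1).
#' @slot baseMean,noiseSd log2-expression location and scale.
#' @slot seed integer RNG seed; the generator is a pure function of the design.
#' @export
setClass("ScDesign", representation(
    nGenes = "numeric", nCells = "numeric", nStates = "numeric",
    reactiveState = "numeric", nSignatureGenes = "numeric",
    markerShift = "numeric", dropoutRate = "numeric",
    baseMean = "numeric", noiseSd = "numeric",
    nPatients = "numeric", seed = "numeric"))

.chk_count <- function(x, name, min = 1) {
    if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
        sprintf("'%s' must be a single integer >= %d", name, min)
    else NULL
}

setValidity("ScDesign", function(object) {
    msgs <- c(
        .chk_count(object@nGenes, "nGenes"),
        .chk_count(object@nCells, "nCells"),
        .chk_count(object@nStates, "nStates", min = 2),
        .chk_count(object@reactiveState, "reactiveState"),
        .chk_count(object@nSignatureGenes, "nSignatureGenes"),
        .chk_count(object@nPatients, "nPatients"),
        .chk_count(object@seed, "seed", min = -.Machine$integer.max))
    if (object@nSignatureGenes >= object@nGenes)
        msgs <- c(msgs, "'nSignatureGenes' must be < 'nGenes'")
    if (object@reactiveState > object@nStates)
        msgs <- c(msgs, "'reactiveState' must be <= 'nStates'")
    if (object@markerShift < 0)
        msgs <- c(msgs, "'markerShift' must be >= 0")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
        msgs <- c(msgs, "'dropoutRate' must be in [0, 1)")
    if (object@noiseSd <= 0)
        msgs <- c(msgs, "'noiseSd' must be > 0")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @rdname ScDesign-class
#' @param nGenes,nCells,nStates,reactiveState,nSignatureGenes,markerShift,dropoutRate,baseMean,noiseSd,nPatients,seed see slots.
#' @return A validated \code{ScDesign}.
#' @export
scDesign <- function(nGenes = 1000, nCells = 600, nStates = 7,
                     reactiveState = 1, nSignatureGenes = 40,
                     markerShift = 2, dropoutRate = 0.3,
                     baseMean = 2, noiseSd = 1, nPatients = 10, seed = 1) {
    new("ScDesign", nGenes = nGenes, nCells = nCells, nStates = nStates,
        reactiveState = reactiveState, nSignatureGenes = nSignatureGenes,
        markerShift = markerShift, dropoutRate = dropoutRate,
        baseMean = baseMean, noiseSd = noiseSd, nPatients = nPatients,
        seed = seed)
}

#' TCR simulation design
#'
#' Parameters of the synthetic clonotype generator.  Cells join clonotypes by
#' preferential attachment; for cells of the reactive state, the odds of
#' joining an already-occupied (expanding) clonotype are multiplied by
#' \code{clonalEnrichment}.
#'
#' @slot clonalEnrichment odds multiplier (>= 1).
#' @slot maxCloneSize hard cap on clone size (>= 3).
#' @slot nClonotypes number of available clonotypes (>= 1).
#' @slot seed integer RNG seed.
#' @export
setClass("TcrDesign", representation(
    clonalEnrichment = "numeric", maxCloneSize = "numeric",
    nClonotypes = "numeric", seed = "numeric"))

setValidity("TcrDesign", function(object) {
    msgs <- c(
        .chk_count(object@maxCloneSize, "maxCloneSize", min = 3),
        .chk_count(object@nClonotypes, "nClonotypes"),
        .chk_count(object@seed, "seed", min = -.Machine$integer.max))
    if (object@clonalEnrichment < 1)
        msgs <- c(msgs, "'clonalEnrichment' must be >= 1")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @rdname TcrDesign-class
#' @param clonalEnrichment,maxCloneSize,nClonotypes,seed see slots.
#' @export
tcrDesign <- function(clonalEnrichment = 5, maxCloneSize = 50,
                      nClonotypes = 400, seed = 1) {
    new("TcrDesign", clonalEnrichment = clonalEnrichment,
        maxCloneSize = maxCloneSize, nClonotypes = nClonotypes, seed = seed)
}

#' Bulk/response cohort simulation design
#'
#' A latent per-sample reactivity score u ~ N(0,1) drives (i) expression of
#' the signature genes (loading \code{signatureLoading} per unit u), (ii) an
#' exponential survival hazard \code{baselineHazard * exp(latentEffect * u)}
#' with independent exponential censoring, and (iii) responder probability
#' \code{plogis(responseLogitSlope * u)}.
#'
#' @slot nSamples cohort size (>= 10).
#' @slot latentEffect hazard log-ratio per unit latent score.
#' @slot baselineHazard,censorRate exponential rates (1/time); censorRate may
#'   be 0 (no censoring).
#' @slot signatureLoading expression units per unit latent score.
#' @slot responseLogitSlope logit units per unit latent score.
#' @slot nBackgroundGenes non-signature genes included so that whole-matrix
#'   scorers have a gene universe to rank against.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortDesign", representation(
    nSamples = "numeric", latentEffect = "numeric",
    baselineHazard = "numeric", censorRate = "numeric",
    signatureLoading = "numeric", responseLogitSlope = "numeric",
    nBackgroundGenes = "numeric", seed = "numeric"))

setValidity("CohortDesign", function(object) {
    msgs <- c(
        .chk_count(object@nSamples, "nSamples", min = 10),
        .chk_count(object@nBackgroundGenes, "nBackgroundGenes", min = 0),
        .chk_count(object@seed, "seed", min = -.Machine$integer.max))
    if (object@baselineHazard <= 0)
        msgs <- c(msgs, "'baselineHazard' must be > 0")
    if (object@censorRate < 0)
        msgs <- c(msgs, "'censorRate' must be >= 0")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @rdname CohortDesign-class
#' @param nSamples,latentEffect,baselineHazard,censorRate,signatureLoading,responseLogitSlope,nBackgroundGenes,seed see slots.
#' @export
cohortDesign <- function(nSamples = 200, latentEffect = -0.7,
                         baselineHazard = 0.1, censorRate = 0.05,
                         signatureLoading = 1, responseLogitSlope = 1.5,
                         nBackgroundGenes = 200, seed = 1) {
    new("CohortDesign", nSamples = nSamples, latentEffect = latentEffect,
        baselineHazard = baselineHazard, censorRate = censorRate,
        signatureLoading = signatureLoading,
        responseLogitSlope = responseLogitSlope,
        nBackgroundGenes = nBackgroundGenes, seed = seed)
}

## ---------------------------------------------------------------------------
## GeneSignature
## ---------------------------------------------------------------------------

#' Gene signature with per-gene discrimination AUCs
#'
#' An ordered gene list (decreasing one-vs-rest ROC AUC, ties broken
#' lexicographically by gene id) together with the target size \code{k},
#' optional per-gene coefficients, and a provenance record.
#'
#' @slot genes unique gene ids, sorted by decreasing AUC.
#' @slot auc per-gene AUC in [0, 1], parallel to \code{genes}.
#' @slot coef optional per-gene coefficients (length 0 or length(genes)).
#' @slot k requested signature size.
#' @slot provenance free-form list (source cluster, thresholds, warnings).
#' @export
setClass("GeneSignature", representation(
    genes = "character", auc = "numeric", coef = "numeric",
    k = "integer", provenance = "list"))

setValidity("GeneSignature", function(object) {
    msgs <- character()
    if (anyDuplicated(object@genes))
        msgs <- c(msgs, "gene ids must be unique")
    if (length(object@auc) != length(object@genes))
        msgs <- c(msgs, "'auc' must be parallel to 'genes'")
    auc <- object@auc[!is.na(object@auc)]    # AUCs are optional (NA)
    if (length(auc) && (any(auc < 0) || any(auc > 1)))
        msgs <- c(msgs, "AUCs must lie in [0, 1]")
    if (!anyNA(object@auc) && length(auc) > 1 &&
        any(diff(auc) > 1e-12))
        msgs <- c(msgs, "genes must be sorted by decreasing AUC")
    if (length(object@coef) && length(object@coef) != length(object@genes))
        msgs <- c(msgs, "'coef' must be empty or parallel to 'genes'")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @rdname GeneSignature-class
#' @param genes,auc,coef,k,provenance see slots; genes/auc are re-sorted by
#'   decreasing AUC (lexicographic tie-break) on construction.
#' @export
GeneSignature <- function(genes, auc = rep(NA_real_, length(genes)),
                          coef = numeric(), k = length(genes),
                          provenance = list()) {
    genes <- as.character(genes)
    if (!length(genes)) stop("a GeneSignature must contain at least one gene")
    if (length(coef)) {
        if (is.null(names(coef))) names(coef) <- genes
        coef <- coef[genes]
    }
    if (all(is.na(auc))) {
        ord <- order(genes)
    } else {
        ord <- order(-auc, genes)
    }
    new("GeneSignature", genes = genes[ord], auc = as.numeric(auc)[ord],
        coef = if (length(coef)) unname(coef[ord]) else numeric(),
        k = as.integer(k), provenance = provenance)
}

## ---------------------------------------------------------------------------
## ScoreVector
## ---------------------------------------------------------------------------

#' Per-observation signature score
#'
#' @slot ids observation (sample or cell) ids.
#' @slot score one finite score per observation.
#' @slot method scoring method id.
#' @slot config snapshot of the scoring configuration used.
#' @export
setClass("ScoreVector", representation(
    ids = "character", score = "numeric", method = "character",
    config = "list"))

setValidity("ScoreVector", function(object) {
    msgs <- character()
    if (length(object@ids) != length(object@score))
        msgs <- c(msgs, "one score per observation id is required")
    if (length(object@score) && !all(is.finite(object@score)))
        msgs <- c(msgs, "scores must be finite")
    if (length(object@method) != 1L)
        msgs <- c(msgs, "'method' must be a single string")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

ScoreVector <- function(ids, score, method, config = list()) {
    new("ScoreVector", ids = as.character(ids), score = as.numeric(score),
        method = method, config = config)
}

## ---------------------------------------------------------------------------
## ClonotypeTable
## ---------------------------------------------------------------------------

#' Per-cell clonotype table
#'
#' Maps every cell to one clonotype (its exact alpha-beta chain pair), with
#' clone sizes counted within the declared scope and, once classified, a
#' clonality class (\code{unique} size 1, \code{repeated} size 2,
#' \code{clonal} size >= the clonal threshold, 3 by default).
#'
#' @slot data data.frame with columns cell_id, sample_id, alpha, beta,
#'   clonotype, clone_size and (optionally filled) clonality.
#' @slot scope \code{"global"} or \code{"per_sample"}: the grouping within
#'   which clone sizes are counted.
#' @slot rejected number of input records dropped for a missing chain.
#' @export
setClass("ClonotypeTable", representation(
    data = "data.frame", scope = "character", rejected = "integer"))

setValidity("ClonotypeTable", function(object) {
    d <- object@data
    need <- c("cell_id", "sample_id", "alpha", "beta", "clonotype",
              "clone_size", "clonality")
    if (!all(need %in% names(d)))
        return(paste("missing columns:",
                     paste(setdiff(need, names(d)), collapse = ", ")))
    if (!object@scope %in% c("global", "per_sample"))
        return("scope must be 'global' or 'per_sample'")
    if (nrow(d)) {
        if (any(d$clone_size < 1))
            return("clone sizes must be >= 1")
        grp <- if (object@scope == "per_sample")
            paste(d$sample_id, d$clonotype, sep = "\r") else d$clonotype
        sz <- vapply(split(d$clone_size, grp), function(s) {
            if (length(unique(s)) != 1L) return(NA_real_)
            s[1]
        }, numeric(1))
        if (anyNA(sz) || sum(sz) != nrow(d))
            return("clone sizes inconsistent with cell assignments")
    }
    TRUE
})

## ---------------------------------------------------------------------------
## CoxFit
## ---------------------------------------------------------------------------

#' Cox proportional-hazards fit
#'
#' Result of a Newton-Raphson maximization of the partial likelihood (Efron
#' tie handling by default).  \code{AIC = -2 logL + 2 p} exactly and
#' \code{HR = exp(beta)} exactly.
#'
#' @slot coef,se named coefficient and standard-error vectors.
#' @slot vcov inverse observed information.
#' @slot loglik,loglik0 partial log-likelihood at the optimum and at beta = 0.
#' @slot aic Akaike information criterion.
#' @slot n,nevent sample and event counts.
#' @slot iter,converged Newton-Raphson iteration count and convergence flag.
#' @slot flags character vector of anomalies (e.g. "monotone_likelihood").
#' @slot ties "efron" or "breslow".
#' @export
setClass("CoxFit", representation(
    coef = "numeric", se = "numeric", vcov = "matrix",
    loglik = "numeric", loglik0 = "numeric", aic = "numeric",
    n = "integer", nevent = "integer", iter = "integer",
    converged = "logical", flags = "character", ties = "character"))

setValidity("CoxFit", function(object) {
    p <- length(object@coef)
    if (length(object@se) != p) return("'se' must be parallel to 'coef'")
    if (abs(object@aic - (-2 * object@loglik + 2 * p)) > 1e-8)
        return("AIC inconsistent with log-likelihood")
    TRUE
})
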