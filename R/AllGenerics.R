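#' @include AllClasses.R
NULL

#' Accessors for TRSig classes
#'
#' \code{exprScale} returns the declared expression scale; \code{exprValues}
#' the gene-by-observation matrix; \code{sigGenes}, \code{sigAUC} and
#' \code{sigCoefs} the components of a \linkS4class{GeneSignature};
#' \code{scores} the named numeric score vector of a
#' \linkS4class{ScoreVector}; \code{scoreMethod} its method id;
#' \code{clonotypeData} the per-cell data.frame of a
#' \linkS4class{ClonotypeTable} and \code{cloneSizes} the per-clonotype size
#' table.
#'
#' @param x an object of the respective class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))
#' @rdname accessors
#' @export
setMethod("exprScale", "ReactivityExperiment",
          function(x) metadata(x)$scale)

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ReactivityExperiment", function(x) assay(x, 1L))

#' @rdname accessors
#' @export
setGeneric("sigGenes", function(x) standardGeneric("sigGenes"))
#' @rdname accessors
#' @export
setMethod("sigGenes", "GeneSignature", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("sigAUC", function(x) standardGeneric("sigAUC"))
#' @rdname accessors
#' @export
setMethod("sigAUC", "GeneSignature",
          function(x) structure(x@auc, names = x@genes))

#' @rdname accessors
#' @export
setGeneric("sigCoefs", function(x) standardGeneric("sigCoefs"))
#' @rdname accessors
#' @export
setMethod("sigCoefs", "GeneSignature", function(x) {
    if (!length(x@coef)) return(NULL)
    structure(x@coef, names = x@genes)
})

#' @rdname accessors
#' @export
setMethod("length", "GeneSignature", function(x) length(x@genes))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setMethod("scores", "ScoreVector",
          function(x) structure(x@score, names = x@ids))

#' @rdname accessors
#' @export
setGeneric("scoreMethod", function(x) standardGeneric("scoreMethod"))
#' @rdname accessors
#' @export
setMethod("scoreMethod", "ScoreVector", function(x) x@method)

#' @rdname accessors
#' @export
setGeneric("clonotypeData", function(x) standardGeneric("clonotypeData"))
#' @rdname accessors
#' @export
setMethod("clonotypeData", "ClonotypeTable", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("cloneSizes", function(x) standardGeneric("cloneSizes"))
#' @rdname accessors
#' @export
setMethod("cloneSizes", "ClonotypeTable", function(x) {
    d <- x@data
    if (!nrow(d)) return(integer())
    key <- if (x@scope == "per_sample")
        paste(d$sample_id, d$clonotype, sep = "\r") else d$clonotype
    sz <- d$clone_size[!duplicated(key)]
    names(sz) <- d$clonotype[!duplicated(key)]
    sz
})

## show methods ---------------------------------------------------------------

setMethod("show", "GeneSignature", function(object) {
    cat(sprintf("GeneSignature of %d gene(s) (k = %d)\n",
                length(object@genes), object@k))
    head_n <- min(5L, length(object@genes))
    cat("  top genes:",
        paste(sprintf("%s (AUC %.3f)", object@genes[seq_len(head_n)],
                      object@auc[seq_len(head_n)]), collapse = ", "), "\n")
    if (length(object@coef)) cat("  per-gene coefficients attached\n")
    if (isTRUE(object@provenance$undersupplied))
        cat("  note: fewer candidates than requested k\n")
})

setMethod("show", "ScoreVector", function(object) {
    cat(sprintf("ScoreVector: %d observation(s), method '%s'\n",
                length(object@ids), object@method))
    if (length(object@score))
        cat(sprintf("  range [%.4g, %.4g]\n",
                    min(object@score), max(object@score)))
})

setMethod("show", "ClonotypeTable", function(object) {
    d <- object@data
    cat(sprintf("ClonotypeTable: %d cell(s), %d clonotype(s), scope '%s'\n",
                nrow(d), length(unique(d$clonotype)), object@scope))
    if (object@rejected > 0L)
        cat(sprintf("  %d record(s) rejected for missing chains\n",
                    object@rejected))
    if (nrow(d) && !all(is.na(d$clonality)))
        print(table(d$clonality))
})

setMethod("show", "CoxFit", function(object) {
    cat(sprintf("CoxFit (%s ties): n = %d, events = %d, %s in %d iter\n",
                object@ties, object@n, object@nevent,
                if (object@converged) "converged" else "NOT converged",
                object@iter))
    ci <- confint(object)
    for (i in seq_along(object@coef))
        cat(sprintf("  %s: beta = %.4f (se %.4f), HR = %.4f [%.4f, %.4f]\n",
                    names(object@coef)[i], object@coef[i], object@se[i],
                    exp(object@coef[i]), ci[i, 1], ci[i, 2]))
    cat(sprintf("  logLik = %.4f, AIC = %.4f\n", object@loglik, object@aic))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @rdname CoxFit-class
#' @param object,parm,level as in \code{stats::confint}.
#' @param ... ignored.
#' @export
setMethod("confint", "CoxFit", function(object, parm, level = 0.95, ...) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    hr <- exp(object@coef)
    out <- cbind(lower = exp(object@coef - z * object@se),
                 upper = exp(object@coef + z * object@se))
    rownames(out) <- names(object@coef)
    out
})

#' Hazard ratios of a Cox fit
#' @param x a \linkS4class{CoxFit}.
#' @return named numeric vector \code{exp(beta)}.
#' @export
setGeneric("hazardRatio", function(x) standardGeneric("hazardRatio"))
#' @rdname hazardRatio
#' @export
setMethod("hazardRatio", "CoxFit", function(x) exp(x@coef))

#' @rdname CoxFit-class
#' @export
setMethod("coef", "CoxFit", function(object, ...) object@coef)

#' @rdname CoxFit-class
#' @export
setMethod("logLik", "CoxFit", function(object, ...) {
    structure(object@loglik, df = length(object@coef), class = "logLik")
})
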