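#' @include AllClasses.R
NULL

#' Gating configuration for CD8+ T cell selection
#'
#' Defaults implement the rule CD8 > 2 and CD4 < 2 (strict inequalities) on
#' log-normalized expression, where CD8 is the mean of the available CD8
#' chain genes.  The CD8 gene list is configurable because the chain pairing
#' (CD8A with CD8B) is a convention, not a constraint.
#'
#' @param cd8Genes gene ids averaged for the CD8 level.
#' @param cd4Gene gene id used for the CD4 level.
#' @param cd8Threshold retained cells need mean CD8 strictly above this.
#' @param cd4Threshold retained cells need CD4 strictly below this.
#' @return a validated config list.
#' @export
gatingConfig <- function(cd8Genes = c("CD8A", "CD8B"), cd4Gene = "CD4",
                         cd8Threshold = 2, cd4Threshold = 2) {
    .stop_if(!length(cd8Genes), "'cd8Genes' must be non-empty")
    .stop_if(length(cd4Gene) != 1L, "'cd4Gene' must be a single gene id")
    .stop_if(!is.finite(cd8Threshold) || !is.finite(cd4Threshold),
             "thresholds must be finite")
    structure(list(cd8Genes = as.character(cd8Genes),
                   cd4Gene = as.character(cd4Gene),
                   cd8Threshold = cd8Threshold,
                   cd4Threshold = cd4Threshold),
              class = "gating_config")
}

#' Gate CD8+ T cells
#'
#' Retains exactly the cells whose mean expression over the available CD8
#' genes is strictly greater than \code{cd8Threshold} and whose CD4
#' expression is strictly less than \code{cd4Threshold}.  Input column order
#' is preserved.
#'
#' @param expr matrix or \linkS4class{ReactivityExperiment}
#'   (log-normalized scale expected).
#' @param config a \code{\link{gatingConfig}}.
#' @return character vector of retained cell ids, in input order.
#' @examples
#' m <- rbind(CD8A = c(3, 1), CD8B = c(3, 1), CD4 = c(0, 5))
#' colnames(m) <- c("cell1", "cell2")
#' gateCD8(m)
#' @export
gateCD8 <- function(expr, config = gatingConfig()) {
    mat <- .expr_input(expr)$values
    cd8 <- intersect(config$cd8Genes, rownames(mat))
    .stop_if(!length(cd8), "none of the CD8 genes (",
             paste(config$cd8Genes, collapse = ", "), ") are present")
    .stop_if(!config$cd4Gene %in% rownames(mat),
             "CD4 gene '", config$cd4Gene, "' is absent")
    cd8_level <- colMeans(mat[cd8, , drop = FALSE])
    cd4_level <- mat[config$cd4Gene, ]
    keep <- cd8_level > config$cd8Threshold & cd4_level < config$cd4Threshold
    colnames(mat)[keep]
}

#' Protocol-specific gene/cell filter profiles
#'
#' \code{"smartseq2_bulklike"} keeps genes with mean expression strictly
#' above 0.5 and detection rate strictly above 0.1 (suitable for TPM-scale
#' full-length protocols and bulk profiles).  \code{"marsseq"} expects raw
#' counts: cells must have an expressed-gene count within
#' [\code{cellMinGenes}, \code{cellMaxGenes}] (inclusive), then genes must
#' have detection rate strictly above 0.01 among the surviving cells.
#' "Expressed" means strictly greater than zero.
#'
#' @param name profile name.
#' @param minGeneMean,minGeneDetectRate,cellMinGenes,cellMaxGenes override
#'   the profile defaults.
#' @return a validated profile list.
#' @export
filterProfile <- function(name = c("smartseq2_bulklike", "marsseq"),
                          minGeneMean = NULL, minGeneDetectRate = NULL,
                          cellMinGenes = NULL, cellMaxGenes = NULL) {
    name <- match.arg(name)
    prof <- if (name == "smartseq2_bulklike")
        list(name = name, minGeneMean = 0.5, minGeneDetectRate = 0.1,
             cellMinGenes = NA_real_, cellMaxGenes = NA_real_)
    else
        list(name = name, minGeneMean = NA_real_, minGeneDetectRate = 0.01,
             cellMinGenes = 500, cellMaxGenes = 3000)
    if (!is.null(minGeneMean)) prof$minGeneMean <- minGeneMean
    if (!is.null(minGeneDetectRate)) prof$minGeneDetectRate <- minGeneDetectRate
    if (!is.null(cellMinGenes)) prof$cellMinGenes <- cellMinGenes
    if (!is.null(cellMaxGenes)) prof$cellMaxGenes <- cellMaxGenes
    with(prof, {
        .stop_if(!is.na(minGeneDetectRate) &&
                     (minGeneDetectRate < 0 || minGeneDetectRate > 1),
                 "'minGeneDetectRate' must be in [0, 1]")
        .stop_if(!is.na(cellMinGenes) && !is.na(cellMaxGenes) &&
                     cellMinGenes >= cellMaxGenes,
                 "'cellMinGenes' must be < 'cellMaxGenes'")
    })
    structure(prof, class = "filter_profile")
}

#' Apply a gene/cell filter profile
#'
#' @param expr matrix or \linkS4class{ReactivityExperiment}; raw counts are
#'   required for the \code{"marsseq"} profile.
#' @param profile a \code{\link{filterProfile}}.
#' @param scale optional scale declaration for bare matrices.
#' @return the filtered object, of the same class as the input.
#' @export
filterGenesCells <- function(expr, profile = filterProfile(), scale = NULL) {
    need <- if (profile$name == "marsseq") "counts" else NULL
    mat <- .expr_input(expr, scale = scale, need = need)$values
    .stop_if(nrow(mat) == 0L || ncol(mat) == 0L, "'expr' is empty")
    keep_cells <- rep(TRUE, ncol(mat))
    if (profile$name == "marsseq") {
        n_expressed <- colSums(mat > 0)
        keep_cells <- n_expressed >= profile$cellMinGenes &
            n_expressed <= profile$cellMaxGenes
        mat <- mat[, keep_cells, drop = FALSE]
        .stop_if(ncol(mat) == 0L,
                 "no cells survive the expressed-gene-count filter; ",
                 "review cellMinGenes/cellMaxGenes")
        keep_genes <- rowMeans(mat > 0) > profile$minGeneDetectRate
    } else {
        keep_genes <- rowMeans(mat) > profile$minGeneMean &
            rowMeans(mat > 0) > profile$minGeneDetectRate
    }
    .stop_if(!any(keep_genes),
             "all genes removed by the filter; review the thresholds")
    if (is(expr, "ReactivityExperiment"))
        expr[keep_genes, keep_cells]
    else
        as.matrix(expr)[keep_genes, keep_cells, drop = FALSE]
}
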