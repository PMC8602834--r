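#' @include AllClasses.R
#' @importFrom Matrix readMM writeMM
NULL

#' Read an expression matrix
#'
#' Reads dense TSV/CSV (genes in rows, first column gene ids, header of
#' observation ids) or MTX triplet format with separate one-id-per-line row
#' and column name files.
#'
#' @param path matrix file.
#' @param format "auto" (by extension), "tsv", "csv" or "mtx".
#' @param rowsFile,colsFile row/column name files (mtx only).
#' @param scale declared expression scale; when given, a
#'   \linkS4class{ReactivityExperiment} is returned, otherwise a bare
#'   matrix.
#' @return matrix or \linkS4class{ReactivityExperiment}.
#' @export
readExprMatrix <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                           rowsFile = NULL, colsFile = NULL, scale = NULL) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
    }
    if (format == "mtx") {
        .stop_if(is.null(rowsFile) || is.null(colsFile),
                 "MTX input needs 'rowsFile' and 'colsFile'")
        mat <- as.matrix(readMM(path))
        rownames(mat) <- readLines(rowsFile)
        colnames(mat) <- readLines(colsFile)
    } else {
        sep <- if (format == "csv") "," else "\t"
        df <- utils::read.table(path, header = TRUE, sep = sep,
                                row.names = 1, check.names = FALSE,
                                comment.char = "#")
        mat <- as.matrix(df)
    }
    storage.mode(mat) <- "double"
    if (!is.null(scale)) ReactivityExperiment(mat, scale = scale) else mat
}

#' Write an expression matrix
#'
#' @param x matrix or \linkS4class{ReactivityExperiment}.
#' @param path output file (TSV; or the MTX file when
#'   \code{format = "mtx"}, in which case \code{<path>.rows} and
#'   \code{<path>.cols} are written next to it).
#' @param format "tsv" or "mtx".
#' @param header optional provenance comment line (TSV only).
#' @return invisibly, the path.
#' @export
writeExprMatrix <- function(x, path, format = c("tsv", "mtx"),
                            header = NULL) {
    format <- match.arg(format)
    mat <- .expr_input(x)$values
    if (format == "mtx") {
        writeMM(methods::as(methods::as(mat, "CsparseMatrix"),
                            "generalMatrix"), path)
        writeLines(rownames(mat), paste0(path, ".rows"))
        writeLines(colnames(mat), paste0(path, ".cols"))
    } else {
        con <- file(path, "w")
        on.exit(close(con))
        if (!is.null(header)) writeLines(paste0("# ", header), con)
        writeLines(paste(c("gene", colnames(mat)), collapse = "\t"), con)
        utils::write.table(mat, con, sep = "\t", quote = FALSE,
                           col.names = FALSE)
    }
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (multi-set files supported).
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
    fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets a \linkS4class{GeneSignature}, a character vector, or a
#'   named list of character vectors.
#' @param path output file.
#' @param description description field of each record.
#' @return invisibly, the path.
#' @export
writeGMT <- function(sets, path, description = "TRSig") {
    if (is(sets, "GeneSignature")) sets <- list(TRS = sigGenes(sets))
    if (is.character(sets)) sets <- list(set1 = sets)
    lines <- vapply(names(sets), function(nm) {
        paste(c(nm, description, sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a survival table
#'
#' TSV with columns sample_id, time, event (plus optional covariates).
#' @param path input file.
#' @return data.frame.
#' @export
readSurvivalTable <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#")
    .stop_if(!all(c("sample_id", "time", "event") %in% names(df)),
             "survival table needs columns sample_id, time, event")
    df
}

#' Read per-cell clonotype records
#'
#' TSV with columns cell_id, sample_id, alpha, beta.
#' @param path input file.
#' @return data.frame suitable for \code{\link{buildClonotypes}}.
#' @export
readClonotypeRecords <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#")
    .stop_if(!all(c("cell_id", "sample_id", "alpha", "beta") %in% names(df)),
             "clonotype records need columns cell_id, sample_id, alpha, beta")
    df
}

#' Write a score vector as TSV
#'
#' @param x a \linkS4class{ScoreVector}.
#' @param path output file.
#' @param header optional provenance comment line.
#' @return invisibly, the path.
#' @export
writeScores <- function(x, path, header = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(
        data.frame(observation_id = x@ids, score = x@score,
                   method = x@method),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
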