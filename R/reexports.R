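# Re-exported Bioconductor accessors so users of the synthetic generators
# can reach annotation and ground truth without attaching the stack.

#' @importFrom SummarizedExperiment colData
#' @export
SummarizedExperiment::colData

#' @importFrom S4Vectors metadata
#' @export
S4Vectors::metadata
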