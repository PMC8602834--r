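#' @include AllClasses.R
NULL

#' Clonality configuration
#'
#' @param clonalMinSize clone size from which cells are classed
#'   \code{clonal} (default 3; sizes 1 and 2 are \code{unique} and
#'   \code{repeated}).
#' @param depth rarefaction depth: a count, or \code{"min"} for the minimum
#'   repertoire size across samples.
#' @param reps number of downsampling replicates (default 1000).
#' @param logBase base of the Shannon entropy logarithm (natural by
#'   default).
#' @param seed RNG seed of the downsampling.
#' @export
clonalityConfig <- function(clonalMinSize = 3, depth = "min", reps = 1000,
                            logBase = exp(1), seed = 1L) {
    .stop_if(clonalMinSize < 2, "'clonalMinSize' must be >= 2")
    .stop_if(reps < 1, "'reps' must be >= 1")
    if (is.numeric(depth)) .stop_if(depth < 1, "'depth' must be >= 1")
    structure(list(clonalMinSize = clonalMinSize, depth = depth,
                   reps = as.integer(reps), logBase = logBase,
                   seed = as.integer(seed)),
              class = "clonality_config")
}

#' Build clonotypes from paired alpha/beta chains
#'
#' Each unique alpha-beta string pair defines a clonotype; the number of
#' cells harboring the same clonotype (within the declared scope) is its
#' clone size.  Records with a missing or empty chain are rejected and
#' counted.
#'
#' @param records data.frame with columns \code{cell_id}, \code{sample_id},
#'   \code{alpha}, \code{beta}.
#' @param scope \code{"global"} (sizes counted over the whole table) or
#'   \code{"per_sample"}.
#' @return a \linkS4class{ClonotypeTable} (clonality classes unset; see
#'   \code{\link{classifyClonality}}).
#' @examples
#' rec <- data.frame(cell_id = paste0("c", 1:4), sample_id = "s1",
#'                   alpha = c("a1", "a1", "a1", "a1"),
#'                   beta = c("b1", "b1", "b1", "b2"))
#' cloneSizes(buildClonotypes(rec))
#' @export
buildClonotypes <- function(records, scope = c("global", "per_sample")) {
    scope <- match.arg(scope)
    need <- c("cell_id", "sample_id", "alpha", "beta")
    .stop_if(!all(need %in% names(records)),
             "records must have columns ", paste(need, collapse = ", "))
    bad <- is.na(records$alpha) | is.na(records$beta) |
        !nzchar(records$alpha) | !nzchar(records$beta)
    if (any(bad))
        message(sum(bad), " record(s) rejected for a missing chain")
    d <- records[!bad, need, drop = FALSE]
    .stop_if(!nrow(d), "no record with both chains present")
    d$clonotype <- paste(d$alpha, d$beta, sep = "|")
    key <- if (scope == "per_sample")
        paste(d$sample_id, d$clonotype, sep = "\r") else d$clonotype
    d$clone_size <- as.integer(ave(seq_along(key), key, FUN = length))
    d$clonality <- NA_character_
    rownames(d) <- NULL
    new("ClonotypeTable", data = d, scope = scope,
        rejected = as.integer(sum(bad)))
}

#' Classify cells by clonal expansion
#'
#' Pure function of clone size: 1 is \code{unique}, 2 is \code{repeated},
#' and at least \code{clonalMinSize} (3 by default) is \code{clonal}.
#'
#' @param table a \linkS4class{ClonotypeTable}.
#' @param config a \code{\link{clonalityConfig}}.
#' @return the table with the clonality column filled.
#' @export
classifyClonality <- function(table, config = clonalityConfig()) {
    .stop_if(!is(table, "ClonotypeTable"), "'table' must be a ClonotypeTable")
    d <- table@data
    d$clonality <- ifelse(d$clone_size >= config$clonalMinSize, "clonal",
                          ifelse(d$clone_size == 2L, "repeated", "unique"))
    new("ClonotypeTable", data = d, scope = table@scope,
        rejected = table@rejected)
}

.shannon <- function(x, logBase) {
    p <- as.numeric(table(x)) / length(x)
    -sum(p * log(p)) / log(logBase)
}

#' Downsampling-rarefied Shannon diversity per sample
#'
#' Corrects Shannon entropy for repertoire-size differences by repeatedly
#' subsampling a common depth d of cells without replacement from each
#' sample's repertoire and averaging the entropy of clonotype frequencies
#' over replicates.  Samples with fewer than d cells are reported as missing
#' (never extrapolated).
#'
#' @param table a \linkS4class{ClonotypeTable}.
#' @param config a \code{\link{clonalityConfig}}; \code{depth = "min"} uses
#'   the smallest repertoire.
#' @return data.frame with one row per sample: n_cells, depth, mean_entropy,
#'   sd_entropy, n_reps, reason (NA when computed, "below_depth" when
#'   skipped); the depth, replicate count and seed used are attached as
#'   attributes.
#' @export
rarefiedEntropy <- function(table, config = clonalityConfig()) {
    .stop_if(!is(table, "ClonotypeTable"), "'table' must be a ClonotypeTable")
    d <- table@data
    .stop_if(!nrow(d), "empty clonotype table")
    groups <- split(d$clonotype, d$sample_id)
    sizes <- lengths(groups)
    depth <- if (identical(config$depth, "min")) min(sizes)
             else as.integer(config$depth)
    .stop_if(depth < 1, "rarefaction depth must be >= 1")
    res <- .with_seed(config$seed, {
        lapply(names(groups), function(s) {
            rep_ct <- groups[[s]]
            n <- length(rep_ct)
            if (n < depth)
                return(data.frame(sample_id = s, n_cells = n, depth = depth,
                                  mean_entropy = NA_real_,
                                  sd_entropy = NA_real_,
                                  n_reps = 0L, reason = "below_depth",
                                  stringsAsFactors = FALSE))
            h <- vapply(seq_len(config$reps), function(b) {
                .shannon(sample(rep_ct, depth, replace = FALSE),
                         config$logBase)
            }, numeric(1))
            data.frame(sample_id = s, n_cells = n, depth = depth,
                       mean_entropy = mean(h), sd_entropy = stats::sd(h),
                       n_reps = config$reps, reason = NA_character_,
                       stringsAsFactors = FALSE)
        })
    })
    out <- do.call(rbind, res)
    attr(out, "depth") <- depth
    attr(out, "reps") <- config$reps
    attr(out, "seed") <- config$seed
    out
}
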