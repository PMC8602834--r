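# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generators and seeded tie-breaks go through this so they are pure
# functions of their design/config.
.with_seed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# Normalize expression input to a plain matrix plus its declared scale.
# `scale` overrides/declares the scale for bare matrices; operations that
# require a particular scale pass `need`.
.expr_input <- function(x, scale = NULL, need = NULL, what = "expression") {
    if (is(x, "ReactivityExperiment")) {
        mat <- exprValues(x)
        sc <- exprScale(x)
    } else if (is.matrix(x) || is(x, "Matrix")) {
        mat <- as.matrix(x)
        sc <- if (!is.null(scale)) scale else attr(x, "scale")
    } else {
        stop("'", what, "' must be a matrix or a ReactivityExperiment")
    }
    if (is.null(rownames(mat)) || is.null(colnames(mat)))
        stop("'", what, "' must carry gene (row) and observation (column) names")
    if (!is.null(need)) {
        if (is.null(sc))
            stop("this operation requires the expression scale to be declared ",
                 "(expected '", need, "'); supply a ReactivityExperiment or ",
                 "the 'scale' argument")
        if (!identical(sc, need))
            stop("expression scale is '", sc, "' but '", need, "' is required")
    }
    list(values = mat, scale = sc)
}

.stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# Midranks of each row of a matrix (ties averaged).
.row_ranks <- function(mat) {
    t(apply(mat, 1L, rank, ties.method = "average"))
}

# Sum of (t^3 - t) over tie groups, per row; 0 when all values distinct.
.row_tie_term <- function(mat) {
    apply(mat, 1L, function(x) {
        tt <- tabulate(match(x, unique(x)))
        sum(tt^3 - tt)
    })
}

# all permutations of seq_len(n) as an n! x n matrix (small n only)
.permutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .permutations(n - 1L)
    out <- vector("list", n)
    for (i in seq_len(n)) {
        rest <- seq_len(n)[-i]
        out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    }
    do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
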