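# Internal helpers shared across modules.

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's state afterwards so package functions never leak RNG effects.
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    expr
}

# Dense base matrix from a possibly sparse matrix, with explicit S4
# coercion (never relies on as.matrix dispatch for Matrix classes).
.asDense <- function(m) {
    if (methods::is(m, "Matrix")) m <- methods::as(m, "matrix")
    m <- as.matrix(m)
    stopifnot(is.matrix(m), !is.null(rownames(m)) || nrow(m) == 0)
    m
}

# Dense matrix from a possibly sparse assay.
.denseLognorm <- function(x) {
    .asDense(lognorm(x))
}

# z-scale a vector; zero-variance input returns zeros (flagged by caller).
.zscale <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
}

# Per-gene (row) z-score of a dense matrix across columns; zero-variance
# rows become all-zero.
.rowZscore <- function(m) {
    mu <- rowMeans(m)
    n <- ncol(m)
    s <- sqrt(pmax(rowSums((m - mu)^2) / (n - 1), 0))
    z <- (m - mu) / ifelse(s == 0, Inf, s)
    z
}

# As .asDense but without dimname assertion (validity-time use).
.asDenseNoCheck <- function(m) {
    if (methods::is(m, "Matrix")) methods::as(m, "matrix") else as.matrix(m)
}
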