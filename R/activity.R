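#' Infer per-cell TF activity from regulon target expression
#'
#' Per gene, lognorm expression is z-scored across cells. Per TF and cell,
#' activity is the weighted signed Stouffer combination over the TF's
#' regulon targets present in the matrix,
#' \deqn{a = \sum_t w_t m_t z_{t} / \sqrt{\sum_t w_t^2},}
#' with mode \eqn{m_t \in \{-1, +1\}} and weight \eqn{w_t > 0}, then
#' z-scaled per TF across cells. TFs with fewer than \code{minRegulon}
#' present (non-constant) targets are skipped with a warning; if no TF
#' passes, an error is raised.
#'
#' This signed weighted score preserves the contract of rank-enrichment
#' activity inference (signed, weighted, regulon-driven, z-scaled) in an
#' exactly testable closed form; see the methods vignette.
#'
#' @param x an \linkS4class{ExoExperiment} with lognorm populated.
#' @param regulon a \linkS4class{Regulon}.
#' @param minRegulon minimum present regulon size (default 5).
#' @return an \linkS4class{ActivityMatrix} (cells x TFs).
#' @export
inferActivity <- function(x, regulon, minRegulon = 5L) {
    if (ncol(x) == 0)
        stop("no cells in the experiment (did QC remove everything?)")
    ln <- .denseLognorm(x)
    z <- .rowZscore(ln)
    sds <- apply(ln, 1, sd)
    usable <- rownames(ln)[sds > 0]
    edges <- regulonEdges(regulon)
    tfs <- unique(edges$tf)
    cols <- list()
    degenerate <- character(0)
    for (tf in tfs) {
        e <- edges[edges$tf == tf & edges$target %in% usable, ]
        if (nrow(e) < minRegulon) {
            warning("TF '", tf, "' skipped: only ", nrow(e),
                    " usable regulon target(s) (< ", minRegulon, ")")
            next
        }
        a <- colSums(e$weight * e$mode * z[e$target, , drop = FALSE]) /
            sqrt(sum(e$weight^2))
        s <- sd(a)
        if (!is.finite(s) || s == 0) {
            degenerate <- c(degenerate, tf)
            cols[[tf]] <- rep(0, ncol(ln))
        } else {
            cols[[tf]] <- (a - mean(a)) / s
        }
    }
    if (!length(cols))
        stop("no TF passes the minimum regulon size")
    values <- do.call(cbind, cols)
    dimnames(values) <- list(colnames(ln), names(cols))
    methods::new("ActivityMatrix", values = values, residualized = FALSE,
                 covariatesUsed = character(0), degenerate = degenerate)
}

#' Residualize TF activity against technical covariates
#'
#' For each TF, fits ordinary least squares of activity on an intercept plus
#' the five technical covariates (detected genes per cell, percent
#' mitochondrial, percent ribosomal, ambient contamination, and the first
#' structure principal component) and keeps the residuals, re-z-scaled per
#' TF. Constant covariates are dropped with a warning; a rank-deficient
#' design after drops is an error. The residualized activity is the primary
#' activity measure for all downstream association models.
#'
#' @param a an \linkS4class{ActivityMatrix}.
#' @param meta per-cell metadata (data.frame or DataFrame) with complete
#'   columns \code{n_genes_detected}, \code{pct_mito}, \code{pct_ribo},
#'   \code{contamination}, rows aligned to the activity matrix.
#' @param pc1 numeric vector, first principal component of the structure
#'   space (see \code{\link{computePCSpaces}}).
#' @return a residualized \linkS4class{ActivityMatrix}.
#' @export
residualizeActivity <- function(a, meta, pc1) {
    v <- activityValues(a)
    meta <- as.data.frame(meta)
    design <- data.frame(cngeneson = as.numeric(meta$n_genes_detected),
                         pct_mito = as.numeric(meta$pct_mito),
                         pct_ribo = as.numeric(meta$pct_ribo),
                         contamination = as.numeric(meta$contamination),
                         pc1 = as.numeric(pc1))
    if (nrow(design) != nrow(v))
        stop("metadata rows must align with activity cells")
    if (any(!complete.cases(design)))
        stop("covariates must be complete (no missing values)")
    keep <- vapply(design, function(col) sd(col) > 0, logical(1))
    if (any(!keep))
        warning("constant covariate(s) dropped: ",
                paste(names(design)[!keep], collapse = ", "))
    design <- design[, keep, drop = FALSE]
    X <- cbind(`(Intercept)` = 1, as.matrix(design))
    qx <- qr(X)
    if (qx$rank < ncol(X))
        stop("rank-deficient covariate design after drops")
    res <- qr.resid(qx, v)
    degenerate <- a@degenerate
    # residual SD below numerical noise (inputs are z-scaled, SD 1) means
    # the covariates explain the activity exactly: flag, return zeros
    tol <- 1e-8
    out <- apply(res, 2, function(col) {
        s <- sd(col)
        if (!is.finite(s) || s <= tol) rep(0, length(col))
        else (col - mean(col)) / s
    })
    zeroVar <- colnames(v)[apply(res, 2, sd) <= tol]
    degenerate <- union(degenerate, zeroVar)
    dimnames(out) <- dimnames(v)
    methods::new("ActivityMatrix", values = out, residualized = TRUE,
                 covariatesUsed = colnames(design), degenerate = degenerate)
}

#' Merge two regulon collections into a union regulon
#'
#' Concatenates the edge lists; when the same (tf, target) pair appears in
#' both, the first collection wins (including mode conflicts).
#'
#' @param x,y \linkS4class{Regulon} objects.
#' @return the union \linkS4class{Regulon}.
#' @export
mergeRegulons <- function(x, y) {
    e <- rbind(regulonEdges(x), regulonEdges(y))
    Regulon(e[!duplicated(e[, c("tf", "target")]), ])
}
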