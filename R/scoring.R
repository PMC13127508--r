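#' Bin-controlled gene-module score
#'
#' Computes, per cell, the mean log-normalized expression of the module
#' genes minus the mean over pooled expression-matched control genes. All
#' genes are binned into \code{nBins} equal-count bins by their average
#' lognorm expression across cells; each module gene contributes
#' \code{nCtrl} control genes sampled with replacement from its bin under
#' \code{seed}. Module genes absent from the matrix are dropped with a
#' warning; if none remain, an error is raised.
#'
#' @param x an \linkS4class{ExoExperiment} with lognorm populated.
#' @param genes character vector of module gene symbols.
#' @param nBins number of expression bins (default 24).
#' @param nCtrl control genes sampled per module gene (default 100).
#' @param seed integer seed for control sampling.
#' @return numeric vector of per-cell scores, named by cell id.
#' @export
moduleScore <- function(x, genes, nBins = 24L, nCtrl = 100L, seed = 1L) {
    ln <- .denseLognorm(x)
    present <- intersect(genes, rownames(ln))
    if (!length(present))
        stop("no module gene present in the matrix")
    if (length(present) < length(genes))
        warning(length(genes) - length(present),
                " module gene(s) absent from the matrix, dropped")
    avg <- rowMeans(ln)
    nBins <- min(nBins, nrow(ln))
    bin <- as.integer(cut(rank(avg, ties.method = "first"), breaks = nBins))
    names(bin) <- rownames(ln)
    ctrl <- .withSeed(seed, {
        unlist(lapply(present, function(g) {
            members <- rownames(ln)[bin == bin[g]]
            pool <- setdiff(members, present)  # controls exclude the module
            if (!length(pool)) pool <- members
            sample(pool, nCtrl, replace = TRUE)
        }), use.names = FALSE)
    })
    colMeans(ln[present, , drop = FALSE]) -
        colMeans(ln[ctrl, , drop = FALSE])
}

#' Score a collection of axes or modules per cell
#'
#' @param x an \linkS4class{ExoExperiment} with lognorm populated.
#' @param panels a \linkS4class{GeneSetList}.
#' @param nBins,nCtrl,seed passed to \code{\link{moduleScore}}; each set
#'   uses an offset seed so control draws differ between sets but are
#'   reproducible.
#' @return cells x sets numeric matrix of scores.
#' @export
scoreGeneSets <- function(x, panels, nBins = 24L, nCtrl = 100L, seed = 1L) {
    sets <- geneSets(panels)
    out <- vapply(seq_along(sets), function(i) {
        moduleScore(x, sets[[i]], nBins, nCtrl, seed + i - 1L)
    }, numeric(ncol(x)))
    dimnames(out) <- list(colnames(x), names(sets))
    out
}

#' Assign exocrine subtypes from axis scores
#'
#' Per cell, the axis with the maximum score determines the subtype (via
#' \code{axisToLabel}); the margin is the difference between the top two
#' axis scores and maps to a confidence bucket by \code{marginCuts}. Exact
#' ties are broken by the declared axis (column) order and flagged.
#'
#' @param scores cells x axes numeric matrix (>= 2 axes).
#' @param axisToLabel named character vector mapping every axis to a
#'   subtype label (several axes may share a label).
#' @param marginCuts three ascending cut points mapping margin to
#'   \code{very_low} / \code{low} / \code{moderate} / \code{high}
#'   (defaults 0.05, 0.15, 0.30).
#' @return data.frame with columns \code{cell_id}, \code{axis},
#'   \code{subtype}, \code{margin}, \code{confidence}, \code{tie}.
#' @examples
#' s <- rbind(c(0.9, 0.1))
#' dimnames(s) <- list("c1", c("acinar", "ductal"))
#' assignAxisSubtype(s, c(acinar = "Acinar", ductal = "Ductal"))
#' @export
assignAxisSubtype <- function(scores,
                              axisToLabel = setNames(colnames(scores),
                                                     colnames(scores)),
                              marginCuts = c(0.05, 0.15, 0.30)) {
    if (ncol(scores) < 2) stop("at least 2 axes are required")
    if (!all(colnames(scores) %in% names(axisToLabel)))
        stop("axis missing from axisToLabel: ",
             paste(setdiff(colnames(scores), names(axisToLabel)),
                   collapse = ", "))
    stopifnot(length(marginCuts) == 3, !is.unsorted(marginCuts))
    top <- apply(scores, 1, which.max)  # first maximum: declared-order ties
    topScore <- scores[cbind(seq_len(nrow(scores)), top)]
    second <- vapply(seq_len(nrow(scores)), function(i) {
        max(scores[i, -top[i]])
    }, numeric(1))
    margin <- topScore - second
    tie <- vapply(seq_len(nrow(scores)), function(i) {
        sum(scores[i, ] == topScore[i]) > 1
    }, logical(1))
    conf <- cut(margin, breaks = c(-Inf, marginCuts, Inf),
                labels = c("very_low", "low", "moderate", "high"),
                right = FALSE)
    axis <- colnames(scores)[top]
    data.frame(cell_id = rownames(scores), axis = axis,
               subtype = unname(axisToLabel[axis]), margin = margin,
               confidence = as.character(conf), tie = tie,
               stringsAsFactors = FALSE, row.names = NULL)
}
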