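#' Compute structure-space and axis-space principal components
#'
#' The structure space is a PCA of the per-batch mean-centered lognorm
#' matrix over the top \code{nHvg} highly variable genes (batch-centering
#' attenuates batch shifts before PCA); the axis space is a PCA of the
#' cell x axis score matrix (capped at n_axes - 1 components). Both PC
#' matrices are scaled to unit total variance so the interpolation weight
#' of \code{\link{tuneCombinedEmbedding}} is the only scale knob.
#'
#' @param x an \linkS4class{ExoExperiment} with lognorm.
#' @param axisScores cells x axes numeric matrix (e.g. from
#'   \code{\link{scoreGeneSets}}).
#' @param nHvg number of highly variable genes (default 3000).
#' @param nPcs number of principal components (default 30; reduced with a
#'   warning when it exceeds the achievable rank).
#' @param batch per-cell batch labels; defaults to the \code{sample}
#'   metadata column.
#' @return list with matrices \code{structure_pcs} and \code{axis_pcs}
#'   (cells x dims).
#' @export
computePCSpaces <- function(x, axisScores, nHvg = 3000L, nPcs = 30L,
                            batch = NULL) {
    ln <- .denseLognorm(x)
    if (is.null(batch))
        batch <- as.character(SummarizedExperiment::colData(x)$sample)
    stopifnot(length(batch) == ncol(ln))
    v <- apply(ln, 1, var)
    hvg <- names(sort(v, decreasing = TRUE))[seq_len(min(nHvg, nrow(ln)))]
    X <- t(ln[hvg, , drop = FALSE])
    for (b in unique(batch)) {
        i <- batch == b
        X[i, ] <- sweep(X[i, , drop = FALSE], 2,
                        colMeans(X[i, , drop = FALSE]))
    }
    kS <- min(nPcs, nrow(X) - 1L, ncol(X))
    if (kS < nPcs)
        warning("structure PCs reduced to ", kS, " (rank limit)")
    sPcs <- prcomp(X, center = TRUE, rank. = kS)$x
    kA <- min(nPcs, ncol(axisScores) - 1L, nrow(axisScores) - 1L)
    if (kA < min(nPcs, ncol(axisScores)))
        if (ncol(axisScores) - 1L < nPcs)
            kA <- ncol(axisScores) - 1L
    aPcs <- prcomp(axisScores, center = TRUE, rank. = kA)$x
    rownames(sPcs) <- rownames(aPcs) <- colnames(ln)
    list(structure_pcs = .unitTotalVar(sPcs),
         axis_pcs = .unitTotalVar(aPcs))
}

.unitTotalVar <- function(m) {
    tv <- sum(apply(m, 2, var))
    if (tv > 0) m / sqrt(tv) else m
}

#' Tune the combined embedding interpolation weight
#'
#' For each alpha on the grid, forms
#' \code{cbind(alpha * structure_pcs, (1 - alpha) * axis_pcs)}, computes
#' subtype separation (mean silhouette width over subtype labels) and batch
#' mixing (1 - mean silhouette width over batch labels), and selects the
#' alpha maximizing separation + mixing (ties broken toward the smaller
#' alpha). With a single subtype or single batch the corresponding term is
#' dropped with a warning.
#'
#' @param structurePcs,axisPcs cells x dims matrices from
#'   \code{\link{computePCSpaces}}.
#' @param subtypeLabels,batchLabels complete per-cell label vectors.
#' @param alphaGrid ascending grid containing 0 and 1 (default
#'   \code{seq(0, 1, 0.1)}).
#' @return a \linkS4class{TunedEmbedding}.
#' @export
tuneCombinedEmbedding <- function(structurePcs, axisPcs, subtypeLabels,
                                  batchLabels,
                                  alphaGrid = seq(0, 1, by = 0.1)) {
    stopifnot(nrow(structurePcs) == nrow(axisPcs),
              length(subtypeLabels) == nrow(structurePcs),
              length(batchLabels) == nrow(structurePcs))
    if (!all(c(0, 1) %in% alphaGrid))
        stop("alphaGrid must include 0 and 1")
    useSep <- length(unique(subtypeLabels)) > 1
    useMix <- length(unique(batchLabels)) > 1
    if (!useSep) warning("single subtype: separation term dropped")
    if (!useMix) warning("single batch: mixing term dropped")
    if (!useSep && !useMix)
        stop("need at least two subtypes or two batches")
    subInt <- as.integer(factor(subtypeLabels))
    batInt <- as.integer(factor(batchLabels))
    curve <- do.call(rbind, lapply(alphaGrid, function(a) {
        emb <- cbind(a * structurePcs, (1 - a) * axisPcs)
        d <- dist(emb)
        sep <- if (useSep) .meanSilhouette(subInt, d) else 0
        mix <- if (useMix) 1 - .meanSilhouette(batInt, d) else 0
        data.frame(alpha = a, separation = sep, mixing = mix,
                   objective = sep + mix)
    }))
    # ties (within numerical noise) resolve toward the smaller alpha
    best <- which(curve$objective >= max(curve$objective) - 1e-9)[1]
    a <- curve$alpha[best]
    methods::new("TunedEmbedding", alpha = a,
                 combinedPCs = cbind(a * structurePcs, (1 - a) * axisPcs),
                 objectiveCurve = curve, grid = alphaGrid)
}

.meanSilhouette <- function(labels, d) {
    sil <- cluster::silhouette(labels, d)
    if (is.matrix(sil)) mean(sil[, "sil_width"]) else 0
}

#' K-means fallback clustering on structure PCs
#'
#' Simple seeded k-means on a PC matrix, for synthetic runs where graph
#' cluster labels are not supplied as metadata.
#'
#' @param pcs cells x dims matrix.
#' @param k number of clusters.
#' @param seed integer seed.
#' @return character vector of cluster labels ("k1", "k2", ...).
#' @export
clusterCellsKmeans <- function(pcs, k, seed = 1L) {
    .withSeed(seed, {
        km <- kmeans(pcs, centers = k, nstart = 5, iter.max = 50)
        paste0("k", km$cluster)
    })
}
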