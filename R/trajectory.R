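#' Minimum-spanning-tree pseudotime over cluster centroids
#'
#' The root cluster is the one with the highest fraction of cells labeled
#' with a root subtype (Acinar and Acinar_REG+ by default). A minimum
#' spanning tree is built over cluster centroids in PC space (Euclidean
#' distances); lineages are the root-to-leaf paths. A cell belongs to every
#' lineage containing its cluster; its pseudotime is the centroid-path
#' distance from the root to its cluster plus its signed projection onto
#' the cluster's incoming edge direction (the outgoing edge for root
#' cells), shifted so each lineage's minimum is 0.
#'
#' @param pcs cells x dims embedding matrix (e.g.
#'   \code{\link{combinedPCs}}).
#' @param clusterLabels per-cell cluster labels.
#' @param subtypeLabels per-cell subtype labels.
#' @param rootSubtypes subtype labels defining the root enrichment rule.
#' @return a \linkS4class{LineageSet} with pseudotime and paths filled.
#' @export
inferPseudotime <- function(pcs, clusterLabels, subtypeLabels,
                            rootSubtypes = c("Acinar", "Acinar_REG+")) {
    clusterLabels <- as.character(clusterLabels)
    cl <- sort(unique(clusterLabels))
    if (length(cl) < 2) stop("at least 2 clusters are required")
    cent <- t(vapply(cl, function(k) {
        colMeans(pcs[clusterLabels == k, , drop = FALSE])
    }, numeric(ncol(pcs))))
    if (anyDuplicated(round(cent, 10)))
        stop("coincident cluster centroids: degenerate geometry")
    rootFrac <- vapply(cl, function(k) {
        mean(subtypeLabels[clusterLabels == k] %in% rootSubtypes)
    }, numeric(1))
    root <- cl[which.max(rootFrac)]

    D <- as.matrix(dist(cent))
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE)
    mstG <- igraph::mst(g)
    deg <- igraph::degree(mstG)
    leaves <- setdiff(names(deg)[deg == 1], root)
    if (!length(leaves)) leaves <- setdiff(cl, root)
    paths <- lapply(leaves, function(lf) {
        p <- igraph::shortest_paths(mstG, from = root, to = lf)$vpath[[1]]
        names(p)
    })
    names(paths) <- paste0("Lineage", seq_along(paths))

    pt <- matrix(NA_real_, nrow = nrow(pcs), ncol = length(paths),
                 dimnames = list(rownames(pcs), names(paths)))
    for (j in seq_along(paths)) {
        path <- paths[[j]]
        cum <- c(0, cumsum(vapply(seq_len(length(path) - 1), function(i) {
            D[path[i], path[i + 1]]
        }, numeric(1))))
        names(cum) <- path
        for (i in seq_along(path)) {
            k <- path[i]
            cells <- clusterLabels == k
            if (!any(cells)) next
            # incoming edge direction; the root uses its outgoing edge
            a <- if (i == 1) k else path[i - 1]
            b <- if (i == 1) path[2] else k
            dir <- cent[b, ] - cent[a, ]
            dir <- dir / sqrt(sum(dir^2))
            proj <- as.vector(
                (pcs[cells, , drop = FALSE] -
                 matrix(cent[k, ], sum(cells), ncol(pcs),
                        byrow = TRUE)) %*% dir)
            pt[cells, j] <- cum[k] + proj
        }
        pt[, j] <- pt[, j] - min(pt[, j], na.rm = TRUE)
    }
    methods::new("LineageSet", pseudotime = pt, rootCluster = root,
                 lineagePaths = paths,
                 metrics = data.frame(), redundancy = matrix(numeric(0),
                                                             0, 0),
                 selectionScores = numeric(0), selected = character(0))
}

#' Per-lineage metrics and the redundancy matrix
#'
#' Fills per-lineage cell counts, pseudotime range, and the change in
#' ductal-like subtype fraction between the early (bottom-q) and late
#' (top-q) pseudotime windows, plus the lineage-lineage Pearson correlation
#' of pseudotime over jointly assigned cells (NA when fewer than 10
#' overlap). Lineages with fewer than 2 cells get missing metrics.
#'
#' @param ls a \linkS4class{LineageSet}.
#' @param subtypeLabels per-cell subtype labels aligned to the pseudotime
#'   rows.
#' @param ductalLike labels counted as ductal-like.
#' @param q early/late quantile window (default 0.2, i.e. quintiles).
#' @return the \linkS4class{LineageSet} with metrics and redundancy filled.
#' @export
computeLineageMetrics <- function(ls, subtypeLabels,
                                  ductalLike = c("Ductal", "Ductal-CFTRhi",
                                                 "Ductal-MUC5B",
                                                 "Ductal-injury"),
                                  q = 0.2) {
    pt <- ls@pseudotime
    L <- colnames(pt)
    met <- data.frame(lineage = L, n_cells = NA_integer_,
                      pt_range = NA_real_, ductal_delta = NA_real_,
                      stringsAsFactors = FALSE)
    for (j in seq_along(L)) {
        v <- pt[, j]
        on <- !is.na(v)
        met$n_cells[j] <- sum(on)
        if (sum(on) < 2) next
        met$pt_range[j] <- max(v[on]) - min(v[on])
        lo <- quantile(v[on], q)
        hi <- quantile(v[on], 1 - q)
        isD <- subtypeLabels %in% ductalLike
        met$ductal_delta[j] <- mean(isD[on & v >= hi]) -
            mean(isD[on & v <= lo])
    }
    R <- matrix(NA_real_, length(L), length(L), dimnames = list(L, L))
    diag(R) <- 1
    for (i in seq_along(L)) for (j in seq_along(L)) {
        if (i >= j) next
        both <- !is.na(pt[, i]) & !is.na(pt[, j])
        if (sum(both) >= 10) {
            R[i, j] <- R[j, i] <- suppressWarnings(
                cor(pt[both, i], pt[both, j]))
        }
    }
    ls@metrics <- met
    ls@redundancy <- R
    ls
}

#' Redundancy-aware representative lineage selection
#'
#' Each lineage's base score is the mean of its z-scaled metrics (n_cells,
#' pt_range, ductal_delta). Selection is greedy: pick the top base score,
#' then repeatedly pick the lineage maximizing base score minus
#' \code{lambdaPenalty} times its maximum absolute redundancy with the
#' already-selected set, \code{k} times. Fewer than \code{k} eligible
#' lineages returns all of them with a warning.
#'
#' @param ls a \linkS4class{LineageSet} with metrics filled.
#' @param k number of representatives (default 3).
#' @param lambdaPenalty redundancy penalty weight (default 1).
#' @return the \linkS4class{LineageSet} with selectionScores and selected
#'   filled.
#' @export
selectRepresentativeLineages <- function(ls, k = 3L, lambdaPenalty = 1) {
    met <- ls@metrics
    if (!nrow(met)) stop("run computeLineageMetrics() first")
    eligible <- met$lineage[complete.cases(met)]
    zcols <- vapply(c("n_cells", "pt_range", "ductal_delta"), function(cn) {
        v <- met[[cn]][match(eligible, met$lineage)]
        s <- sd(v)
        if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }, numeric(length(eligible)))
    base <- setNames(rowMeans(matrix(zcols, nrow = length(eligible))),
                     eligible)
    if (length(eligible) < k) {
        warning("only ", length(eligible), " eligible lineage(s); ",
                "returning all")
        k <- length(eligible)
    }
    R <- ls@redundancy
    selected <- character(0)
    while (length(selected) < k) {
        cand <- setdiff(eligible, selected)
        penal <- vapply(cand, function(l) {
            if (!length(selected)) return(base[l])
            r <- abs(R[l, selected])
            r <- r[!is.na(r)]
            base[l] - lambdaPenalty * if (length(r)) max(r) else 0
        }, numeric(1))
        selected <- c(selected, cand[which.max(penal)])
    }
    ls@selectionScores <- base
    ls@selected <- selected
    ls
}

#' Activity and subtype composition profiles along pseudotime
#'
#' For each selected lineage (all lineages when none are selected), scales
#' pseudotime to [0, 1], cuts it into \code{nBins} equal-width bins, and
#' reports per-bin subtype fractions (summing to 1 over observed subtypes)
#' and the running-mean smoothed activity (window of \code{smoothWindow}
#' bins, edge-truncated; empty bins are skipped).
#'
#' @param ls a \linkS4class{LineageSet}.
#' @param activity per-cell activity vector aligned to pseudotime rows.
#' @param subtypeLabels per-cell subtype labels.
#' @param nBins number of pseudotime bins (default 20).
#' @param smoothWindow running-mean window in bins (default 3).
#' @return data.frame with columns \code{lineage}, \code{bin},
#'   \code{bin_mid}, \code{n_cells}, \code{activity_mean},
#'   \code{activity_smooth}, then one fraction column per subtype.
#' @export
activityCompositionProfile <- function(ls, activity, subtypeLabels,
                                       nBins = 20L, smoothWindow = 3L) {
    pt <- ls@pseudotime
    lineages <- if (length(ls@selected)) ls@selected else colnames(pt)
    subs <- sort(unique(subtypeLabels))
    out <- list()
    for (l in lineages) {
        v <- pt[, l]
        on <- !is.na(v)
        s <- (v[on] - min(v[on])) / max(v[on] - min(v[on]), .Machine$double.eps)
        bin <- pmin(floor(s * nBins) + 1L, nBins)
        df <- data.frame(lineage = l, bin = seq_len(nBins),
                         bin_mid = (seq_len(nBins) - 0.5) / nBins,
                         n_cells = as.integer(tabulate(bin, nBins)))
        df$activity_mean <- vapply(seq_len(nBins), function(b) {
            if (df$n_cells[b] == 0) NA_real_
            else mean(activity[on][bin == b])
        }, numeric(1))
        nonEmpty <- which(df$n_cells > 0)
        half <- (smoothWindow - 1L) %/% 2L
        sm <- rep(NA_real_, nBins)
        for (ii in seq_along(nonEmpty)) {
            w <- nonEmpty[seq(max(1, ii - half),
                              min(length(nonEmpty), ii + half))]
            sm[nonEmpty[ii]] <- mean(df$activity_mean[w])
        }
        df$activity_smooth <- sm
        fr <- vapply(subs, function(stp) {
            vapply(seq_len(nBins), function(b) {
                if (df$n_cells[b] == 0) return(NA_real_)
                mean(subtypeLabels[on][bin == b] == stp)
            }, numeric(1))
        }, numeric(nBins))
        colnames(fr) <- paste0("frac_", gsub("[^A-Za-z0-9]+", "_", subs))
        out[[l]] <- cbind(df, fr)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
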