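#' MAD-based trimming bounds
#'
#' Returns \code{median(x) +/- k * 1.4826 * median(|x - median(x)|)}, the
#' two-sided trimming interval used for adaptive filtering on the number of
#' detected genes. The 1.4826 constant makes the MAD consistent with the
#' normal SD.
#'
#' @param x non-empty finite numeric vector.
#' @param k positive multiplier (default 3).
#' @return named numeric vector \code{c(lower, upper)}.
#' @examples
#' madBounds(c(100, 200, 300, 400, 10000), 3)  # (-144.78, 744.78)
#' @export
madBounds <- function(x, k = 3) {
    if (!length(x)) stop("x must be non-empty")
    if (!all(is.finite(x))) stop("x must be finite")
    med <- median(x)
    m <- mad(x)  # constant 1.4826
    c(lower = med - k * m, upper = med + k * m)
}

#' QC threshold presets
#'
#' Builds the threshold set used by \code{\link{applyQCFilter}}. Two named
#' presets reproduce the two pipelines: \code{exocrine} (snRNA-seq; 3-MAD
#' per-sample trimming on detected genes, minimum 150 genes, < 10 percent
#' mitochondrial, < 35 percent ribosomal, contamination < 0.5) and
#' \code{tumor} (scRNA-seq; fixed thresholds only, minimum 500 genes, < 25
#' percent mitochondrial, < 20 percent ribosomal, contamination < 0.5).
#' Keep requires strictly-less-than each upper threshold ("cells >= 25
#' percent mitochondrial were removed" fixes the convention).
#'
#' @param preset \code{"exocrine"} or \code{"tumor"}.
#' @param ... named overrides of individual fields.
#' @return list of class \code{qc_thresholds}.
#' @export
qcThresholds <- function(preset = c("exocrine", "tumor"), ...) {
    preset <- match.arg(preset)
    t <- if (preset == "exocrine") {
        list(mad_k = 3, min_genes = 150L, max_pct_mito = 10,
             max_pct_ribo = 35, max_contamination = 0.5,
             use_mad_on_genes = TRUE, per_sample = TRUE)
    } else {
        list(mad_k = 3, min_genes = 500L, max_pct_mito = 25,
             max_pct_ribo = 20, max_contamination = 0.5,
             use_mad_on_genes = FALSE, per_sample = FALSE)
    }
    dots <- list(...)
    bad <- setdiff(names(dots), names(t))
    if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    t[names(dots)] <- dots
    if (t$mad_k < 0 || t$max_contamination < 0 || t$max_contamination > 1)
        stop("thresholds out of range")
    class(t) <- "qc_thresholds"
    t
}

#' Apply QC filtering to cells
#'
#' A cell is kept iff it passes all active criteria: detected genes within
#' the MAD bounds (computed within each sample when \code{per_sample}),
#' detected genes >= \code{min_genes}, \code{pct_mito < max_pct_mito},
#' \code{pct_ribo < max_pct_ribo} and
#' \code{contamination < max_contamination}. The report counts removals per
#' criterion (a cell failing several is counted under each) plus the total
#' removed.
#'
#' @param x an \linkS4class{ExoExperiment} with metadata columns
#'   \code{pct_mito}, \code{pct_ribo}, \code{contamination} (and
#'   \code{sample} when \code{per_sample}).
#' @param thresholds a \code{\link{qcThresholds}} list.
#' @return list with \code{kept} (filtered \linkS4class{ExoExperiment}) and
#'   \code{report} (data.frame of removal counts per criterion).
#' @export
applyQCFilter <- function(x, thresholds = qcThresholds("exocrine")) {
    stopifnot(inherits(thresholds, "qc_thresholds"))
    cd <- SummarizedExperiment::colData(x)
    need <- c("pct_mito", "pct_ribo", "contamination")
    if (thresholds$per_sample) need <- c(need, "sample")
    for (cn in need)
        if (!cn %in% colnames(cd))
            stop("missing metadata column: ", cn)
    ngd <- cd$n_genes_detected
    n <- ncol(x)

    failMad <- rep(FALSE, n)
    if (thresholds$use_mad_on_genes) {
        grp <- if (thresholds$per_sample) as.character(cd$sample)
               else rep("all", n)
        for (g in unique(grp)) {
            i <- grp == g
            b <- madBounds(ngd[i], thresholds$mad_k)
            failMad[i] <- ngd[i] < b["lower"] | ngd[i] > b["upper"]
        }
    }
    failMin <- ngd < thresholds$min_genes
    failMito <- !(cd$pct_mito < thresholds$max_pct_mito)
    failRibo <- !(cd$pct_ribo < thresholds$max_pct_ribo)
    failCont <- !(cd$contamination < thresholds$max_contamination)
    keep <- !(failMad | failMin | failMito | failRibo | failCont)

    report <- data.frame(
        criterion = c("mad_genes", "min_genes", "pct_mito", "pct_ribo",
                      "contamination", "total_removed"),
        removed = c(sum(failMad), sum(failMin), sum(failMito),
                    sum(failRibo), sum(failCont), sum(!keep)))
    list(kept = x[, keep], report = report)
}

#' Select exocrine clusters by marker-module enrichment
#'
#' Scores every cell for acinar and ductal marker panels and for each
#' exclusion panel (endocrine, stromal, immune, ...) with
#' \code{\link{moduleScore}}, averages scores within clusters, and retains
#' clusters whose best exocrine (acinar-or-ductal) mean score exceeds their
#' maximal exclusion-panel mean score by at least \code{scoreMargin}. With
#' no exclusion panels, clusters with positive exocrine score are retained.
#'
#' @param x an \linkS4class{ExoExperiment} with lognorm and a
#'   \code{cluster} metadata column.
#' @param acinarPanel,ductalPanel character vectors of marker genes.
#' @param exclusionPanels \linkS4class{GeneSetList} of lineages to exclude
#'   (may be empty).
#' @param scoreMargin required margin (default 0).
#' @param nBins,nCtrl,seed passed to \code{\link{moduleScore}}.
#' @return the cell subset \linkS4class{ExoExperiment} of retained clusters.
#' @export
selectExocrine <- function(x, acinarPanel, ductalPanel,
                           exclusionPanels = GeneSetList(list(),
                                                         "axis_panel"),
                           scoreMargin = 0, nBins = 24L, nCtrl = 100L,
                           seed = 1L) {
    cd <- SummarizedExperiment::colData(x)
    if (!"cluster" %in% colnames(cd) || all(is.na(cd$cluster)))
        stop("cluster labels are required")
    cl <- as.character(cd$cluster)
    acS <- moduleScore(x, acinarPanel, nBins, nCtrl, seed)
    duS <- moduleScore(x, ductalPanel, nBins, nCtrl, seed + 1L)
    exo <- pmax(tapply(acS, cl, mean), tapply(duS, cl, mean))
    excl <- geneSets(exclusionPanels)
    if (length(excl)) {
        exMeans <- vapply(seq_along(excl), function(i) {
            tapply(moduleScore(x, excl[[i]], nBins, nCtrl, seed + 1L + i),
                   cl, mean)
        }, numeric(length(unique(cl))))
        exMax <- apply(matrix(exMeans, ncol = length(excl)), 1, max)
        keepCl <- names(exo)[exo >= exMax + scoreMargin]
    } else {
        keepCl <- names(exo)[exo > 0]
    }
    if (!length(keepCl))
        stop("no cluster passes the exocrine selection margin")
    x[, cl %in% keepCl]
}
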