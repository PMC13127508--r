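#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames colData
#'   colData<- rowData rowData<-
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median mad quantile rnorm rbinom rnbinom runif rbeta
#'   qnorm pnorm pchisq p.adjust lm glm binomial coef prcomp dist cor sd var
#'   setNames complete.cases model.matrix kmeans rlnorm qlogis plogis
#'   cor.test as.formula aggregate
#' @importFrom utils read.delim write.table head
NULL

#' Single-cell container for exocrine activity analyses
#'
#' \code{ExoExperiment} extends
#' \code{\link[SingleCellExperiment]{SingleCellExperiment}} with validity
#' checks tailored to this package: a non-negative integer \code{counts}
#' assay, an optional \code{lognorm} assay sharing the zero pattern of
#' \code{counts}, unique gene and cell identifiers, and a
#' \code{n_genes_detected} column in \code{colData} equal to the number of
#' nonzero count entries per cell. Genes are rows, cells are columns,
#' following the Bioconductor convention.
#'
#' Standard per-cell technical metadata used throughout the pipeline lives in
#' \code{colData}: \code{donor}, \code{context}, \code{sample},
#' \code{cluster}, \code{n_genes_detected}, \code{pct_mito}, \code{pct_ribo}
#' (percentages in [0, 100]) and \code{contamination} (fraction in [0, 1]).
#'
#' @slot int_elementType inherited machinery; no new slots are added.
#' @name ExoExperiment-class
#' @aliases ExoExperiment-class
#' @exportClass ExoExperiment
setClass("ExoExperiment", contains = "SingleCellExperiment")

.validExoExperiment <- function(object) {
    msg <- character(0)
    anames <- SummarizedExperiment::assayNames(object)
    if (!"counts" %in% anames)
        return("assay 'counts' is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene symbols (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "cell ids (colnames) must be present and unique")
    v <- if (methods::is(cts, "sparseMatrix")) cts@x else as.vector(cts)
    if (length(v) && (any(v < 0) || any(v != round(v))))
        msg <- c(msg, "counts must be non-negative integers")
    if ("lognorm" %in% anames) {
        ln <- SummarizedExperiment::assay(object, "lognorm")
        if (!identical(dim(ln), dim(cts)))
            msg <- c(msg, "lognorm and counts must share dimensions")
        else {
            z_ct <- .asDenseNoCheck(cts) == 0
            z_ln <- .asDenseNoCheck(ln) == 0
            if (!identical(z_ct, z_ln))
                msg <- c(msg, "lognorm must be 0 exactly where counts are 0")
        }
    }
    cd <- SummarizedExperiment::colData(object)
    if (!"n_genes_detected" %in% colnames(cd))
        msg <- c(msg, "colData column 'n_genes_detected' is required")
    else {
        ngd <- Matrix::colSums(cts > 0)
        if (!isTRUE(all.equal(unname(as.numeric(cd$n_genes_detected)),
                              unname(as.numeric(ngd)))))
            msg <- c(msg, "n_genes_detected must equal per-cell nonzero counts")
    }
    if (length(msg)) msg else TRUE
}
setValidity("ExoExperiment", .validExoExperiment)

#' Construct an ExoExperiment from a count matrix
#'
#' @param counts gene x cell matrix (dense or \pkg{Matrix} sparse) of
#'   non-negative integer counts with unique rownames (gene symbols) and
#'   colnames (cell ids).
#' @param cellData optional data.frame / DataFrame of per-cell metadata,
#'   rows aligned to the columns of \code{counts}. A \code{n_genes_detected}
#'   column is (re)computed from \code{counts}.
#' @param geneData optional per-gene metadata table keyed by gene symbol.
#' @return A validated \linkS4class{ExoExperiment} with the \code{counts}
#'   assay populated and no \code{lognorm} assay (see
#'   \code{\link{logNormalize}}).
#' @examples
#' m <- matrix(c(4L, 0L, 0L, 0L, 0L, 1L), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' ee <- ExoExperiment(m)
#' colData(ee)$n_genes_detected
#' @export
ExoExperiment <- function(counts, cellData = NULL, geneData = NULL) {
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have rownames (genes) and colnames (cells)")
    if (is.null(cellData)) {
        cellData <- S4Vectors::DataFrame(row.names = colnames(counts))
    } else {
        cellData <- S4Vectors::DataFrame(cellData,
                                         row.names = colnames(counts))
    }
    cellData$n_genes_detected <- as.integer(Matrix::colSums(counts > 0))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), colData = cellData)
    if (!is.null(geneData))
        SummarizedExperiment::rowData(sce) <- S4Vectors::DataFrame(geneData)
    methods::new("ExoExperiment", sce)
}

#' Signed, weighted TF-to-target regulon
#'
#' Edge list of transcription-factor regulons: each edge links a TF to one
#' target gene with a mode of regulation (+1 activation, -1 repression) and
#' a positive confidence weight. (tf, target) pairs are unique.
#'
#' @slot edges data.frame with columns \code{tf}, \code{target},
#'   \code{mode} (integer in \{-1, +1\}) and \code{weight} (finite, > 0).
#' @name Regulon-class
#' @exportClass Regulon
setClass("Regulon", representation(edges = "data.frame"))

setValidity("Regulon", function(object) {
    e <- object@edges
    req <- c("tf", "target", "mode", "weight")
    if (!all(req %in% colnames(e)))
        return(paste("edges must have columns", paste(req, collapse = ", ")))
    msg <- character(0)
    if (anyDuplicated(e[, c("tf", "target")]))
        msg <- c(msg, "(tf, target) pairs must be unique")
    if (!all(e$mode %in% c(-1L, 1L)))
        msg <- c(msg, "mode must be -1 or +1")
    if (!all(is.finite(e$weight)) || any(e$weight <= 0))
        msg <- c(msg, "weights must be finite and > 0")
    if (length(msg)) msg else TRUE
})

#' @param edges data.frame with columns tf, target, mode, weight.
#' @rdname Regulon-class
#' @export
Regulon <- function(edges) {
    edges$tf <- as.character(edges$tf)
    edges$target <- as.character(edges$target)
    edges$mode <- as.integer(edges$mode)
    edges$weight <- as.numeric(edges$weight)
    methods::new("Regulon", edges = edges)
}

#' Named gene-set collection
#'
#' Container for named marker panels, gene modules or NMF signature gene
#' lists. Sets are non-empty character vectors of gene symbols with unique
#' collection names.
#'
#' @slot sets named list of character vectors of gene symbols.
#' @slot kind one of \code{"axis_panel"}, \code{"gene_module"},
#'   \code{"nmf_signature"}.
#' @name GeneSetList-class
#' @exportClass GeneSetList
setClass("GeneSetList",
         representation(sets = "list", kind = "character"))

setValidity("GeneSetList", function(object) {
    msg <- character(0)
    if (length(object@sets)) {
        if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
            msg <- c(msg, "set names must be present and unique")
        if (any(lengths(object@sets) == 0))
            msg <- c(msg, "every set must be non-empty")
    }
    if (length(object@kind) != 1 ||
        !object@kind %in% c("axis_panel", "gene_module", "nmf_signature"))
        msg <- c(msg, "kind must be axis_panel, gene_module or nmf_signature")
    if (length(msg)) msg else TRUE
})

#' @param sets named list of character vectors.
#' @param kind collection kind.
#' @rdname GeneSetList-class
#' @export
GeneSetList <- function(sets, kind = c("axis_panel", "gene_module",
                                       "nmf_signature")) {
    kind <- match.arg(kind)
    methods::new("GeneSetList", sets = lapply(sets, as.character),
                 kind = kind)
}

#' Per-cell TF activity matrix
#'
#' Cell x TF matrix of regulon-based activity scores, z-scaled per TF across
#' cells (mean 0, SD 1 up to numerical tolerance; degenerate all-zero TFs are
#' flagged). \code{residualized} records whether technical covariates have
#' been regressed out, and \code{covariatesUsed} which ones.
#'
#' @slot values numeric matrix, cells in rows, TFs in columns.
#' @slot residualized logical scalar.
#' @slot covariatesUsed character vector of covariate names.
#' @slot degenerate character vector of TFs whose scores collapsed to zero.
#' @name ActivityMatrix-class
#' @exportClass ActivityMatrix
setClass("ActivityMatrix",
         representation(values = "matrix", residualized = "logical",
                        covariatesUsed = "character",
                        degenerate = "character"))

setValidity("ActivityMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    msg <- character(0)
    ok <- setdiff(colnames(v), object@degenerate)
    if (length(ok) && nrow(v) > 1) {
        mu <- colMeans(v[, ok, drop = FALSE])
        sdv <- apply(v[, ok, drop = FALSE], 2, sd)
        if (any(abs(mu) > 1e-6) || any(abs(sdv - 1) > 1e-6))
            msg <- c(msg, "per-TF scores must have mean 0 and SD 1")
    }
    if (length(msg)) msg else TRUE
})

#' Cell x lineage pseudotime set
#'
#' Pseudotime values per cell and lineage (NA where the cell is off-lineage),
#' the root cluster, the root-to-leaf cluster paths, per-lineage metrics,
#' the lineage-lineage pseudotime correlation (redundancy) matrix, and the
#' representative-lineage selection.
#'
#' @slot pseudotime numeric matrix, cells x lineages, NA off-lineage; 0 at
#'   the root-proximal end of each lineage.
#' @slot rootCluster character scalar.
#' @slot lineagePaths named list of cluster-label vectors (root first).
#' @slot metrics data.frame with columns lineage, n_cells, pt_range,
#'   ductal_delta (filled by \code{\link{computeLineageMetrics}}).
#' @slot redundancy numeric lineage x lineage correlation matrix.
#' @slot selectionScores numeric base scores per lineage.
#' @slot selected character vector of selected lineage ids.
#' @name LineageSet-class
#' @exportClass LineageSet
setClass("LineageSet",
         representation(pseudotime = "matrix", rootCluster = "character",
                        lineagePaths = "list", metrics = "data.frame",
                        redundancy = "matrix",
                        selectionScores = "numeric", selected = "character"))

#' Tuned combined embedding
#'
#' Result of interpolating between a structure-space (expression PCA) and an
#' axis-space (marker-axis PCA) representation, with the interpolation weight
#' selected to balance subtype separation against batch/context mixing.
#'
#' @slot alpha selected interpolation weight in [0, 1].
#' @slot combinedPCs cells x dims matrix at the selected alpha.
#' @slot objectiveCurve data.frame with columns alpha, separation, mixing,
#'   objective over the whole grid.
#' @slot grid numeric vector of candidate alphas.
#' @name TunedEmbedding-class
#' @exportClass TunedEmbedding
setClass("TunedEmbedding",
         representation(alpha = "numeric", combinedPCs = "matrix",
                        objectiveCurve = "data.frame", grid = "numeric"))
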