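#' Accessors
#'
#' Accessor generics and methods for the package's S4 classes.
#'
#' @param object an S4 object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("lognorm", function(object) standardGeneric("lognorm"))

#' @rdname accessors
#' @export
setMethod("lognorm", "ExoExperiment", function(object) {
    if (!"lognorm" %in% SummarizedExperiment::assayNames(object))
        stop("lognorm assay not present; run logNormalize() first")
    SummarizedExperiment::assay(object, "lognorm")
})

#' @rdname accessors
#' @export
setGeneric("regulonEdges", function(object) standardGeneric("regulonEdges"))

#' @rdname accessors
#' @export
setMethod("regulonEdges", "Regulon", function(object) object@edges)

#' @rdname accessors
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetList", function(object) object@sets)

#' @rdname accessors
#' @export
setGeneric("setKind", function(object) standardGeneric("setKind"))

#' @rdname accessors
#' @export
setMethod("setKind", "GeneSetList", function(object) object@kind)

#' @rdname accessors
#' @export
setGeneric("activityValues", function(object)
    standardGeneric("activityValues"))

#' @rdname accessors
#' @export
setMethod("activityValues", "ActivityMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("isResidualized", function(object)
    standardGeneric("isResidualized"))

#' @rdname accessors
#' @export
setMethod("isResidualized", "ActivityMatrix",
          function(object) object@residualized)

#' @rdname accessors
#' @export
setGeneric("covariatesUsed", function(object)
    standardGeneric("covariatesUsed"))

#' @rdname accessors
#' @export
setMethod("covariatesUsed", "ActivityMatrix",
          function(object) object@covariatesUsed)

#' @rdname accessors
#' @export
setGeneric("pseudotimes", function(object) standardGeneric("pseudotimes"))

#' @rdname accessors
#' @export
setMethod("pseudotimes", "LineageSet", function(object) object@pseudotime)

#' @rdname accessors
#' @export
setGeneric("rootCluster", function(object) standardGeneric("rootCluster"))

#' @rdname accessors
#' @export
setMethod("rootCluster", "LineageSet", function(object) object@rootCluster)

#' @rdname accessors
#' @export
setGeneric("lineagePaths", function(object) standardGeneric("lineagePaths"))

#' @rdname accessors
#' @export
setMethod("lineagePaths", "LineageSet", function(object) object@lineagePaths)

#' @rdname accessors
#' @export
setGeneric("lineageMetrics", function(object)
    standardGeneric("lineageMetrics"))

#' @rdname accessors
#' @export
setMethod("lineageMetrics", "LineageSet", function(object) object@metrics)

#' @rdname accessors
#' @export
setGeneric("lineageRedundancy", function(object)
    standardGeneric("lineageRedundancy"))

#' @rdname accessors
#' @export
setMethod("lineageRedundancy", "LineageSet",
          function(object) object@redundancy)

#' @rdname accessors
#' @export
setGeneric("selectedLineages", function(object)
    standardGeneric("selectedLineages"))

#' @rdname accessors
#' @export
setMethod("selectedLineages", "LineageSet", function(object) object@selected)

#' @rdname accessors
#' @export
setGeneric("selectedAlpha", function(object)
    standardGeneric("selectedAlpha"))

#' @rdname accessors
#' @export
setMethod("selectedAlpha", "TunedEmbedding", function(object) object@alpha)

#' @rdname accessors
#' @export
setGeneric("combinedPCs", function(object) standardGeneric("combinedPCs"))

#' @rdname accessors
#' @export
setMethod("combinedPCs", "TunedEmbedding",
          function(object) object@combinedPCs)

#' @rdname accessors
#' @export
setGeneric("objectiveCurve", function(object)
    standardGeneric("objectiveCurve"))

#' @rdname accessors
#' @export
setMethod("objectiveCurve", "TunedEmbedding",
          function(object) object@objectiveCurve)

setMethod("show", "Regulon", function(object) {
    e <- object@edges
    cat("Regulon with", nrow(e), "edges,", length(unique(e$tf)), "TF(s)\n")
    for (tf in head(unique(e$tf), 5)) {
        sub <- e[e$tf == tf, ]
        cat(sprintf("  %s: %d targets (%d activating, %d repressing)\n",
                    tf, nrow(sub), sum(sub$mode == 1), sum(sub$mode == -1)))
    }
    if (length(unique(e$tf)) > 5) cat("  ...\n")
})

setMethod("show", "GeneSetList", function(object) {
    cat("GeneSetList of kind '", object@kind, "' with ",
        length(object@sets), " sets\n", sep = "")
    nm <- head(names(object@sets), 6)
    for (n in nm)
        cat(sprintf("  %s: %d genes\n", n, length(object@sets[[n]])))
    if (length(object@sets) > 6) cat("  ...\n")
})

setMethod("show", "ActivityMatrix", function(object) {
    cat("ActivityMatrix:", nrow(object@values), "cells x",
        ncol(object@values), "TF(s);",
        if (object@residualized) "residualized" else "raw", "\n")
    if (length(object@covariatesUsed))
        cat("  covariates:", paste(object@covariatesUsed, collapse = ", "),
            "\n")
})

setMethod("show", "LineageSet", function(object) {
    cat("LineageSet:", ncol(object@pseudotime), "lineage(s), root cluster '",
        object@rootCluster, "'\n", sep = "")
    if (length(object@selected))
        cat("  selected:", paste(object@selected, collapse = ", "), "\n")
})

setMethod("show", "TunedEmbedding", function(object) {
    cat("TunedEmbedding: alpha =", object@alpha, "over grid of",
        length(object@grid), "values;", nrow(object@combinedPCs),
        "cells x", ncol(object@combinedPCs), "dims\n")
})
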