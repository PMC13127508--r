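#' Score NMF signatures and derive classical/basal fractions
#'
#' Each signature score is the mean log-normalized expression of the
#' signature genes present in the matrix (intersected with the expressed
#' gene universe). The classical fraction is (Sig1 + Sig6) and the basal
#' fraction (Sig2 + Sig10), each normalized by the total over all four
#' signatures; cells with zero total signal get missing fractions and
#' family \code{Unassigned}.
#'
#' @param x an \linkS4class{ExoExperiment} with lognorm.
#' @param sigs a \linkS4class{GeneSetList} containing Sig1, Sig2, Sig6,
#'   Sig10; a signature with no present genes is an error naming it.
#' @return data.frame with columns \code{cell_id}, \code{Sig1},
#'   \code{Sig2}, \code{Sig6}, \code{Sig10}, \code{p_classical},
#'   \code{p_basal}, \code{family}.
#' @export
scoreSignatures <- function(x, sigs) {
    sets <- geneSets(sigs)
    need <- c("Sig1", "Sig2", "Sig6", "Sig10")
    if (!all(need %in% names(sets)))
        stop("signature collection must contain Sig1, Sig2, Sig6, Sig10")
    ln <- .denseLognorm(x)
    sc <- vapply(need, function(s) {
        present <- intersect(sets[[s]], rownames(ln))
        if (!length(present))
            stop("signature '", s, "' has no genes present in the matrix")
        colMeans(ln[present, , drop = FALSE])
    }, numeric(ncol(ln)))
    total <- rowSums(sc)
    pc <- ifelse(total > 0, (sc[, "Sig1"] + sc[, "Sig6"]) / total,
                 NA_real_)
    pb <- ifelse(total > 0, (sc[, "Sig2"] + sc[, "Sig10"]) / total,
                 NA_real_)
    data.frame(cell_id = colnames(ln), sc, p_classical = pc, p_basal = pb,
               family = classifyFamily(pc, pb), stringsAsFactors = FALSE,
               row.names = NULL)
}

#' Three-family tumor-cell classification
#'
#' Applies the explicit thresholds in order, first match wins:
#' Classical if \code{p_classical >= 0.60} and \code{p_basal <= 0.30};
#' Basal if \code{p_basal >= 0.60} and \code{p_classical <= 0.30};
#' Hybrid if both fractions are at least 0.30; otherwise (or with missing
#' fractions) Unassigned. The rule order makes the measure-zero boundary
#' set deterministic.
#'
#' @param pClassical,pBasal fractions in [0, 1] (vectorized; NAs allowed).
#' @return character vector of \code{Classical} / \code{Hybrid} /
#'   \code{Basal} / \code{Unassigned}.
#' @examples
#' classifyFamily(c(0.8333, 0.5, 0.25, 0.7), c(0.1667, 0.5, 0.75, 0.3))
#' @export
classifyFamily <- function(pClassical, pBasal) {
    n <- max(length(pClassical), length(pBasal))
    pClassical <- rep_len(pClassical, n)
    pBasal <- rep_len(pBasal, n)
    out <- rep("Unassigned", n)
    ok <- !is.na(pClassical) & !is.na(pBasal)
    if (any(ok & (pClassical < 0 | pClassical > 1 | pBasal < 0 |
                  pBasal > 1)))
        stop("fractions must lie in [0, 1]")
    cl <- ok & pClassical >= 0.60 & pBasal <= 0.30
    ba <- ok & !cl & pBasal >= 0.60 & pClassical <= 0.30
    hy <- ok & !cl & !ba & pClassical >= 0.30 & pBasal >= 0.30
    out[cl] <- "Classical"
    out[ba] <- "Basal"
    out[hy] <- "Hybrid"
    out
}
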