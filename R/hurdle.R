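#' Fit a two-part hurdle model for one gene
#'
#' Detection (expression > 0) is modeled by logistic regression on activity
#' plus covariates; expression magnitude by linear regression on the same
#' design restricted to detected cells. Categorical covariates expand to
#' fixed-effect indicator columns (first level reference). The activity
#' coefficient, its two-sided p-value and signed z are extracted from each
#' component and combined by \code{\link{combineEvidence}}.
#'
#' Status values: \code{ok}; \code{too_few_positive} when fewer than
#' \code{minPos} cells express the gene (no statistics);
#' \code{degenerate_detection} when detection is all-0 or all-1 (detection
#' component missing, continuous still fit when possible);
#' \code{fit_error} when the activity column is dropped by collinearity or
#' a fit fails to converge.
#'
#' @param expr per-cell lognorm expression vector.
#' @param activity per-cell activity vector.
#' @param covariates data.frame of covariates (may have zero columns).
#' @param minPos minimum expressing cells (default 25).
#' @param weights (w_det, w_cont) evidence weights for the combined z.
#' @param clip absolute z clip bound.
#' @return one-row data.frame (see \code{\link{fitHurdle}} for columns).
#' @export
fitHurdleGene <- function(expr, activity, covariates = NULL, minPos = 25L,
                          weights = c(1, 1), clip = 10) {
    n <- length(expr)
    stopifnot(length(activity) == n)
    det <- as.integer(expr > 0)
    nPos <- sum(det)
    out <- data.frame(n_pos = nPos, logOR_det = NA_real_, OR_det = NA_real_,
                      p_det = NA_real_, z_det = NA_real_,
                      beta_cont = NA_real_, p_cont = NA_real_,
                      z_cont = NA_real_, z_combined = NA_real_,
                      p_combined = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    if (nPos < minPos) {
        out$status <- "too_few_positive"
        return(out)
    }
    dat <- data.frame(activity = activity)
    if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
        dat <- cbind(dat, as.data.frame(covariates))
    degen <- nPos == 0 || nPos == n
    if (!degen) {
        fitD <- tryCatch(
            glm(det ~ ., data = cbind(det = det, dat), family = binomial()),
            error = function(e) NULL, warning = function(w) {
                suppressWarnings(glm(det ~ ., data = cbind(det = det, dat),
                                     family = binomial()))
            })
        if (is.null(fitD) || !fitD$converged ||
            is.na(coef(fitD)["activity"])) {
            out$status <- "fit_error"
        } else {
            cf <- summary(fitD)$coefficients
            if (any(is.na(coef(fitD))))
                warning("collinear covariate column(s) dropped in ",
                        "detection fit")
            out$logOR_det <- cf["activity", 1]
            out$OR_det <- exp(out$logOR_det)
            out$p_det <- max(cf["activity", 4], .Machine$double.xmin)
            out$z_det <- sign(out$logOR_det) *
                qnorm(1 - min(out$p_det, 1) / 2)
        }
    } else {
        out$status <- "degenerate_detection"
    }
    # continuous component among detected cells
    pos <- det == 1
    datPos <- dat[pos, , drop = FALSE]
    nonconst <- vapply(datPos, function(col) length(unique(col)) > 1,
                       logical(1))
    nonconst["activity"] <- TRUE
    fitC <- tryCatch(
        lm(y ~ ., data = cbind(y = expr[pos],
                               datPos[, nonconst, drop = FALSE])),
        error = function(e) NULL)
    if (!is.null(fitC) && !is.na(coef(fitC)["activity"]) &&
        nrow(datPos) > length(coef(fitC))) {
        cf <- summary(fitC)$coefficients
        if ("activity" %in% rownames(cf) && !is.na(cf["activity", 2]) &&
            cf["activity", 2] > 0) {
            out$beta_cont <- cf["activity", 1]
            out$p_cont <- max(cf["activity", 4], .Machine$double.xmin)
            out$z_cont <- sign(out$beta_cont) *
                qnorm(1 - min(out$p_cont, 1) / 2)
        }
    } else if (out$status == "ok" && is.na(out$p_det)) {
        out$status <- "fit_error"
    }
    comb <- combineEvidence(out$p_det, sign(out$logOR_det), out$p_cont,
                            sign(out$beta_cont), weights = weights,
                            clip = clip)
    out$z_combined <- comb$z_combined
    out$p_combined <- comb$p_combined
    out
}

#' Fit hurdle models across all genes of an experiment
#'
#' Applies \code{\link{fitHurdleGene}} to each gene of the lognorm matrix
#' and appends Benjamini-Hochberg FDRs for the detection, continuous and
#' combined p-values.
#'
#' @param x an \linkS4class{ExoExperiment} with lognorm.
#' @param activity per-cell activity vector (e.g. residualized TF activity).
#' @param covariates data.frame of per-cell covariates.
#' @param minPos minimum expressing cells per gene (default 25).
#' @param weights (w_det, w_cont): equal weights for the exocrine pipeline,
#'   \code{c(2, 1)} for the tumor pipeline.
#' @param clip absolute z clip bound (default 10).
#' @param genes optional subset of gene symbols to fit.
#' @return data.frame with one row per gene: \code{gene}, \code{n_pos},
#'   \code{logOR_det}, \code{OR_det}, \code{p_det}, \code{z_det},
#'   \code{beta_cont}, \code{p_cont}, \code{z_cont}, \code{z_combined},
#'   \code{p_combined}, \code{FDR_det}, \code{FDR_cont}, \code{FDR_comb},
#'   \code{status}.
#' @export
fitHurdle <- function(x, activity, covariates = NULL, minPos = 25L,
                      weights = c(1, 1), clip = 10, genes = NULL) {
    ln <- .denseLognorm(x)
    if (is.null(genes)) genes <- rownames(ln)
    res <- do.call(rbind, lapply(genes, function(g) {
        r <- suppressWarnings(
            fitHurdleGene(ln[g, ], activity, covariates, minPos, weights,
                          clip))
        cbind(gene = g, r, stringsAsFactors = FALSE)
    }))
    res$FDR_det <- bhFDR(res$p_det)
    res$FDR_cont <- bhFDR(res$p_cont)
    res$FDR_comb <- bhFDR(res$p_combined)
    rownames(res) <- NULL
    res
}

#' Combine detection and continuous evidence
#'
#' Converts each two-sided p-value to a signed z,
#' \eqn{z_i = s_i \Phi^{-1}(1 - p_i/2)}, clips to \code{+/- clip}, and
#' combines Stouffer-style with weight-norm denominator
#' \eqn{(w_d z_d + w_c z_c)/\sqrt{w_d^2 + w_c^2}}. The overall p-value is
#' Fisher's method on the two p-values (chi-squared survival with 4 df).
#' A missing component propagates: single-component input returns that
#' component's z and p; both missing returns NA with \code{both_missing}.
#'
#' @param pDet,pCont two-sided p-values in (0, 1] (NA when missing).
#' @param signDet,signCont coefficient signs in \{-1, +1\}.
#' @param weights positive weights (w_det, w_cont).
#' @param clip positive clip bound (default 10).
#' @return list with \code{z_combined}, \code{p_combined},
#'   \code{both_missing}.
#' @examples
#' combineEvidence(0.0455, 1, 0.0455, 1)            # z ~ 2.83
#' combineEvidence(0.5, 1, 0.5, 1)$p_combined        # 0.5966
#' @export
combineEvidence <- function(pDet, signDet, pCont, signCont,
                            weights = c(1, 1), clip = 10) {
    stopifnot(length(weights) == 2, all(weights > 0), clip > 0)
    zOf <- function(p, s) {
        if (is.na(p) || is.na(s)) return(NA_real_)
        stopifnot(p > 0, p <= 1)
        z <- s * qnorm(1 - p / 2)
        max(min(z, clip), -clip)
    }
    zd <- zOf(pDet, signDet)
    zc <- zOf(pCont, signCont)
    if (is.na(zd) && is.na(zc))
        return(list(z_combined = NA_real_, p_combined = NA_real_,
                    both_missing = TRUE))
    if (is.na(zd))
        return(list(z_combined = zc, p_combined = pCont,
                    both_missing = FALSE))
    if (is.na(zc))
        return(list(z_combined = zd, p_combined = pDet,
                    both_missing = FALSE))
    zComb <- (weights[1] * zd + weights[2] * zc) / sqrt(sum(weights^2))
    X <- -2 * (log(pDet) + log(pCont))
    list(z_combined = zComb,
         p_combined = pchisq(X, df = 4, lower.tail = FALSE),
         both_missing = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement,
#' order-preserving with the input; missing entries pass through as NA and
#' do not count toward the number of tests.
#'
#' @param p numeric vector of p-values in (0, 1] (NAs allowed).
#' @return adjusted vector, same order and length.
#' @export
bhFDR <- function(p) {
    ok <- !is.na(p)
    if (any(p[ok] <= 0 | p[ok] > 1))
        stop("p-values must lie in (0, 1]")
    out <- rep(NA_real_, length(p))
    out[ok] <- p.adjust(p[ok], method = "BH")
    out
}

#' Export a preranked GSEA RNK file
#'
#' Recomputes clipped signed combined z-scores from the hurdle results at
#' the given weights, sorts descending, and writes a two-column
#' tab-separated file (gene symbol, z) with no header. Rows with neither
#' component available are dropped.
#'
#' @param results data.frame from \code{\link{fitHurdle}}.
#' @param path output path.
#' @param weights (w_det, w_cont) weights.
#' @param clip positive clip bound.
#' @return Invisibly, the data.frame written (gene, z).
#' @export
exportRankFile <- function(results, path, weights = c(1, 1), clip = 10) {
    if (anyDuplicated(results$gene))
        stop("duplicate gene symbols in results")
    z <- vapply(seq_len(nrow(results)), function(i) {
        combineEvidence(results$p_det[i], sign(results$logOR_det[i]),
                        results$p_cont[i], sign(results$beta_cont[i]),
                        weights = weights, clip = clip)$z_combined
    }, numeric(1))
    keep <- !is.na(z)
    rnk <- data.frame(gene = results$gene[keep], z = z[keep],
                      stringsAsFactors = FALSE)
    rnk <- rnk[order(-rnk$z), ]
    write.table(rnk, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(rnk)
}

#' Read an RNK file back
#'
#' @param path RNK file path.
#' @return data.frame with columns \code{gene}, \code{z}.
#' @export
readRankFile <- function(path) {
    read.delim(path, header = FALSE, col.names = c("gene", "z"),
               stringsAsFactors = FALSE)
}
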