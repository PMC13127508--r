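#' Gene-module to activity association models
#'
#' For each module (column of \code{scores}) and each requested stratum,
#' fits ordinary least squares of the module score on residualized activity
#' plus covariates (donor, context, detected genes, percent mitochondrial,
#' percent ribosomal, contamination) and reports the activity coefficient,
#' its standard error and two-sided p-value. The global fit uses all cells;
#' stratified fits subset to one subtype each. Benjamini-Hochberg FDR is
#' computed jointly across the whole module x stratum table.
#'
#' @param scores cells x modules numeric matrix.
#' @param activity per-cell activity vector.
#' @param meta per-cell metadata with columns \code{donor}, \code{context},
#'   \code{n_genes_detected}, \code{pct_mito}, \code{pct_ribo},
#'   \code{contamination} and, when stratifying, \code{subtype}.
#' @param strata \code{NULL} for the global fit only, or a character vector
#'   of subtype labels to also fit within (use
#'   \code{unique(meta$subtype)} for all).
#' @return data.frame with columns \code{module}, \code{stratum},
#'   \code{coefficient}, \code{se}, \code{p}, \code{fdr}, \code{n_cells},
#'   \code{status}. Strata with too few cells for the design yield a
#'   status-flagged row of NAs rather than an error.
#' @export
fitModuleAssociations <- function(scores, activity, meta, strata = NULL) {
    meta <- as.data.frame(meta)
    stopifnot(nrow(meta) == length(activity),
              nrow(scores) == length(activity))
    need <- c("donor", "context", "n_genes_detected", "pct_mito",
              "pct_ribo", "contamination")
    miss <- setdiff(need, colnames(meta))
    if (length(miss)) stop("missing metadata column(s): ",
                           paste(miss, collapse = ", "))
    if (any(!complete.cases(meta[, need])))
        stop("covariates must be complete")
    layers <- c(list(global = rep(TRUE, length(activity))),
                setNames(lapply(strata, function(s) meta$subtype == s),
                         strata))
    rows <- list()
    for (st in names(layers)) {
        idx <- layers[[st]] & !is.na(layers[[st]])
        for (mod in colnames(scores)) {
            rows[[length(rows) + 1L]] <-
                .fitOneModule(scores[idx, mod], activity[idx],
                              meta[idx, , drop = FALSE], mod, st)
        }
    }
    out <- do.call(rbind, rows)
    out$fdr <- bhFDR(out$p)
    out <- out[, c("module", "stratum", "coefficient", "se", "p", "fdr",
                   "n_cells", "status")]
    rownames(out) <- NULL
    out
}

.fitOneModule <- function(y, act, meta, mod, stratum) {
    dat <- data.frame(y = y, activity = act)
    for (cn in c("donor", "context"))
        if (length(unique(meta[[cn]])) > 1)
            dat[[cn]] <- factor(meta[[cn]])
    for (cn in c("n_genes_detected", "pct_mito", "pct_ribo",
                 "contamination"))
        dat[[cn]] <- as.numeric(meta[[cn]])
    bad <- data.frame(module = mod, stratum = stratum,
                      coefficient = NA_real_, se = NA_real_, p = NA_real_,
                      n_cells = nrow(dat), status = "too_few_cells",
                      stringsAsFactors = FALSE)
    nCoefMax <- 2 + sum(vapply(dat, is.factor, logical(1)) *
                        (vapply(dat, nlevels, integer(1)) - 1)) + 4
    if (nrow(dat) <= nCoefMax) return(bad)
    fit <- tryCatch(lm(y ~ ., data = dat), error = function(e) NULL)
    if (is.null(fit) || is.na(coef(fit)["activity"])) return(bad)
    cf <- summary(fit)$coefficients
    data.frame(module = mod, stratum = stratum,
               coefficient = cf["activity", 1], se = cf["activity", 2],
               p = max(cf["activity", 4], .Machine$double.xmin),
               n_cells = nrow(dat), status = "ok",
               stringsAsFactors = FALSE)
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles by
#' \eqn{y_i = \Phi^{-1}((r_i - c)/(n - 2c + 1))} with mid-ranked ties and
#' Blom offset \eqn{c = 3/8} by default.
#'
#' @param x finite numeric vector of length >= 2.
#' @param offset rank offset (default 3/8).
#' @return transformed numeric vector, same order.
#' @examples
#' intTransform(c(5, 1, 9))  # 0, -0.8694, 0.8694
#' @export
intTransform <- function(x, offset = 3 / 8) {
    if (length(x) < 2) stop("need at least 2 observations")
    if (!all(is.finite(x))) stop("x must be finite")
    r <- rank(x, ties.method = "average")
    qnorm((r - offset) / (length(x) - 2 * offset + 1))
}

#' Additive genotype-dose association with clone random intercepts
#'
#' Fits \code{expression_int ~ genotype_dose + (1 | clone)} by restricted
#' maximum likelihood (\pkg{lme4}) with Satterthwaite p-values
#' (\pkg{lmerTest}) and returns the dose coefficient and its p-value. When
#' the clone variance estimate is zero (singular fit) the estimate
#' coincides with ordinary least squares; if mixed-model fitting fails
#' altogether the OLS fit is the documented fallback.
#'
#' @param data data.frame with columns \code{clone},
#'   \code{genotype_dose} (integer in 0..2) and \code{expression_int}.
#' @return list with \code{beta}, \code{se}, \code{p}, \code{singular}.
#' @export
fitGenotypeAssociation <- function(data) {
    stopifnot(all(c("clone", "genotype_dose", "expression_int") %in%
                  colnames(data)))
    if (!all(data$genotype_dose %in% 0:2))
        stop("genotype_dose must be in {0, 1, 2}")
    if (length(unique(data$genotype_dose)) < 2)
        stop("at least 2 distinct dose levels are required")
    if (length(unique(data$clone)) < 2)
        stop("at least 2 clones are required")
    fit <- tryCatch(
        suppressMessages(lmerTest::lmer(
            expression_int ~ genotype_dose + (1 | clone), data = data,
            REML = TRUE)),
        error = function(e) NULL)
    if (!is.null(fit)) {
        cf <- coef(summary(fit))
        return(list(beta = cf["genotype_dose", "Estimate"],
                    se = cf["genotype_dose", "Std. Error"],
                    p = cf["genotype_dose", "Pr(>|t|)"],
                    singular = lme4::isSingular(fit)))
    }
    ols <- lm(expression_int ~ genotype_dose, data = data)
    cf <- summary(ols)$coefficients
    list(beta = cf["genotype_dose", 1], se = cf["genotype_dose", 2],
         p = cf["genotype_dose", 4], singular = TRUE)
}
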