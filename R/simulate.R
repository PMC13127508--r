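#' Configuration for the exocrine snRNA-seq simulator
#'
#' Assembles (and validates) the configuration list consumed by
#' \code{\link{simulateExocrine}}. Defaults describe a desk-scale
#' multi-donor, three-context (neonatal / adult / chronic pancreatitis)
#' exocrine pancreas dataset with seven marker-driven subtypes, a sparse TF
#' transcript whose latent activity drives signed regulon targets, donor
#' batch effects, and an acinar-to-ductal stage structure.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes in the universe (including markers and
#'   regulon targets).
#' @param contexts context labels.
#' @param donors_per_context donors simulated within each context.
#' @param subtype_proportions named fractions over the seven exocrine
#'   subtypes; must sum to 1.
#' @param markers_per_subtype marker genes planted per subtype.
#' @param marker_boost additive log-mean boost of a marker gene in cells
#'   of its own subtype (discrete identity component).
#' @param marker_graded_boost additional marker boost weighted by a
#'   Gaussian kernel of the distance between a cell's stage position and
#'   the marker subtype's stage position; encodes the gradual
#'   acinar-to-ductal expression continuum (stage-adjacent subtypes share
#'   partial marker expression) without eroding subtype identity.
#' @param marker_stage_bandwidth bandwidth (stage-position units) of that
#'   kernel.
#' @param tf_activity_sd SD of the latent per-cell TF activity.
#' @param regulon_size number of TF target genes (>= 5).
#' @param regulon_frac_repressed fraction of targets with mode -1.
#' @param regulon_effect per-unit-activity shift in target-gene log-mean
#'   (signed by mode).
#' @param dropout_logit_slope slope of an optional extra detection-dropout
#'   layer on the log-mean scale; 0 (default) disables it, leaving dropout
#'   to negative-binomial sampling alone.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param batch_effect_sd SD of per-donor, per-gene log-mean shifts.
#' @param lib_size_sd SD of the per-cell log-normal library-size factor.
#' @param lineage_spec named numeric vector of stage positions per subtype
#'   along the acinar-to-ductal axis; pseudotime_true is the stage position
#'   plus Gaussian jitter.
#' @param confounder_coefs optional named numeric vector (names among
#'   \code{pct_mito}, \code{pct_ribo}, \code{contamination},
#'   \code{cngeneson}) added to the latent activity *before* it drives the
#'   regulon, planting a technical confounder for residualization tests.
#' @param seed integer seed; all randomness flows from it.
#' @return A validated list of class \code{exocrine_sim_config}.
#' @export
exocrineSimConfig <- function(
    n_cells = 2000L,
    n_genes = 2000L,
    contexts = c("neonatal", "adult", "CP"),
    donors_per_context = 2L,
    subtype_proportions = c(
        "Acinar" = 0.30, "Acinar_REG+" = 0.10, "Acinar-stress" = 0.10,
        "Ductal" = 0.20, "Ductal-CFTRhi" = 0.10, "Ductal-MUC5B" = 0.10,
        "Ductal-injury" = 0.10),
    markers_per_subtype = 20L,
    marker_boost = 1.5,
    marker_graded_boost = 0.8,
    marker_stage_bandwidth = 0.12,
    tf_activity_sd = 1,
    regulon_size = 100L,
    regulon_frac_repressed = 0.25,
    regulon_effect = 0.5,
    dropout_logit_slope = 0,
    nb_dispersion = 0.4,
    batch_effect_sd = 0.2,
    lib_size_sd = 0.5,
    lineage_spec = c(
        "Acinar" = 0, "Acinar_REG+" = 0.16, "Acinar-stress" = 0.32,
        "Ductal" = 0.48, "Ductal-MUC5B" = 0.64, "Ductal-injury" = 0.80,
        "Ductal-CFTRhi" = 0.96),
    confounder_coefs = NULL,
    seed = 1L) {
    cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                contexts = contexts,
                donors_per_context = as.integer(donors_per_context),
                subtype_proportions = subtype_proportions,
                markers_per_subtype = as.integer(markers_per_subtype),
                marker_boost = marker_boost,
                marker_graded_boost = marker_graded_boost,
                marker_stage_bandwidth = marker_stage_bandwidth,
                tf_activity_sd = tf_activity_sd,
                regulon_size = as.integer(regulon_size),
                regulon_frac_repressed = regulon_frac_repressed,
                regulon_effect = regulon_effect,
                dropout_logit_slope = dropout_logit_slope,
                nb_dispersion = nb_dispersion,
                batch_effect_sd = batch_effect_sd,
                lib_size_sd = lib_size_sd,
                lineage_spec = lineage_spec,
                confounder_coefs = confounder_coefs,
                seed = as.integer(seed))
    if (abs(sum(cfg$subtype_proportions) - 1) > 1e-9)
        stop("subtype_proportions must sum to 1")
    if (cfg$n_cells < 1 || cfg$n_genes < 1 || cfg$donors_per_context < 1)
        stop("entity counts must be >= 1")
    if (cfg$regulon_size < 5)
        stop("regulon_size must be >= 5 (smaller regulons are skipped by ",
             "activity inference)")
    if (cfg$nb_dispersion <= 0 || cfg$tf_activity_sd <= 0)
        stop("dispersion and tf_activity_sd must be positive")
    if (!all(names(cfg$subtype_proportions) %in% names(cfg$lineage_spec)))
        stop("lineage_spec must cover every subtype")
    class(cfg) <- "exocrine_sim_config"
    cfg
}

#' Read an exocrine simulator configuration from YAML
#'
#' Fields present in the YAML override the defaults of
#' \code{\link{exocrineSimConfig}}.
#'
#' @param path YAML file.
#' @return A validated configuration list.
#' @export
readExocrineSimConfig <- function(path) {
    y <- yaml::read_yaml(path)
    known <- names(formals(exocrineSimConfig))
    bad <- setdiff(names(y), known)
    if (length(bad))
        stop("unknown config field(s): ", paste(bad, collapse = ", "))
    for (f in c("subtype_proportions", "lineage_spec", "confounder_coefs"))
        if (!is.null(y[[f]])) y[[f]] <- unlist(y[[f]])
    do.call(exocrineSimConfig, y)
}

#' Generate a random regulon
#'
#' Samples \code{nTargets} target genes without replacement from a gene
#' universe; \code{round(fracRepressed * nTargets)} of them get mode -1, the
#' rest +1; all weights are 1.
#'
#' @param tf TF symbol.
#' @param nTargets number of targets (>= 5).
#' @param fracRepressed fraction of repressed (mode -1) targets.
#' @param universe character vector of candidate target symbols.
#' @param seed integer seed.
#' @return A \linkS4class{Regulon}.
#' @export
generateRegulon <- function(tf, nTargets, fracRepressed, universe,
                            seed = 1L) {
    if (nTargets < 5)
        stop("nTargets must be >= 5")
    if (nTargets > length(universe))
        stop("nTargets exceeds the gene universe")
    .withSeed(seed, {
        targets <- sample(universe, nTargets)
        nRep <- round(fracRepressed * nTargets)
        modes <- rep(1L, nTargets)
        if (nRep > 0)
            modes[sample(nTargets, nRep)] <- -1L
        Regulon(data.frame(tf = tf, target = targets, mode = modes,
                           weight = 1, stringsAsFactors = FALSE))
    })
}

#' Simulate an exocrine pancreas snRNA-seq dataset with planted truth
#'
#' Draws counts from a negative-binomial model whose gene/cell log-means are
#' baseline + subtype marker boost + regulon_effect x activity x mode (for
#' regulon targets) + donor batch shift + log library-size factor. The TF's
#' own transcript is forced sparse (detected in well under 10 percent of
#' cells) while its latent activity varies continuously; per-cell technical
#' covariates (pct_mito, pct_ribo, contamination) are drawn with mild
#' correlation to library size; pseudotime_true follows the configured
#' acinar-to-ductal stage positions. A fixed seed gives bit-identical
#' output.
#'
#' @param cfg an \code{\link{exocrineSimConfig}}.
#' @return A list with elements \code{experiment}
#'   (\linkS4class{ExoExperiment} with counts and lognorm), \code{truth}
#'   (list of per-cell and per-gene truth tables), \code{regulon}
#'   (\linkS4class{Regulon}) and \code{panels} (marker-panel
#'   \linkS4class{GeneSetList}, one axis per subtype).
#' @export
simulateExocrine <- function(cfg = exocrineSimConfig()) {
    stopifnot(inherits(cfg, "exocrine_sim_config"))
    .withSeed(cfg$seed, .simulateExocrineImpl(cfg))
}

.simulateExocrineImpl <- function(cfg) {
    subtypes <- names(cfg$subtype_proportions)
    nS <- length(subtypes)
    tf <- "PDX1"
    nMark <- nS * cfg$markers_per_subtype
    if (cfg$n_genes < nMark + cfg$regulon_size + 50)
        stop("n_genes too small for the requested markers and regulon")
    genes <- sprintf("G%05d", seq_len(cfg$n_genes))
    genes[1] <- tf
    markerIdx <- 1 + seq_len(nMark)
    markerOf <- rep(subtypes, each = cfg$markers_per_subtype)
    panels <- split(genes[markerIdx], markerOf)[subtypes]
    names(panels) <- paste0("axis_", gsub("[^A-Za-z0-9]+", "_", subtypes))
    background <- genes[-c(1, markerIdx)]

    regulon <- generateRegulon(tf, cfg$regulon_size,
                               cfg$regulon_frac_repressed, background,
                               seed = sample.int(2^31 - 1, 1))
    edges <- regulonEdges(regulon)

    nC <- cfg$n_cells
    cells <- sprintf("cell%05d", seq_len(nC))
    context <- sample(cfg$contexts, nC, replace = TRUE)
    donor <- paste0(context, "_d",
                    sample.int(cfg$donors_per_context, nC, replace = TRUE))
    subtype <- sample(subtypes, nC, replace = TRUE,
                      prob = cfg$subtype_proportions)
    activityLatent <- rnorm(nC, 0, cfg$tf_activity_sd)
    pt <- pmax(cfg$lineage_spec[subtype] + rnorm(nC, 0, 0.05), 0)
    libFactor <- rlnorm(nC, 0, cfg$lib_size_sd)

    baseline <- rnorm(cfg$n_genes, log(0.3), 0.8)
    names(baseline) <- genes
    baseline[tf] <- log(0.02)  # sparse TF transcript, independent of activity

    # pre-draw technical covariates so an optional planted confounder can
    # feed into the activity that drives the regulon
    zLibPre <- .zscale(log(libFactor))
    pctMito <- 100 * plogis(rnorm(nC, -3.2, 0.4) + 0.15 * zLibPre)
    pctRibo <- 100 * plogis(rnorm(nC, -1.6, 0.4) + 0.15 * zLibPre)
    contamination <- plogis(rnorm(nC, -2.0, 0.6))

    activity <- activityLatent
    if (!is.null(cfg$confounder_coefs)) {
        covs <- list(pct_mito = pctMito, pct_ribo = pctRibo,
                     contamination = contamination)
        for (nm in names(cfg$confounder_coefs)) {
            if (!nm %in% names(covs))
                stop("unknown confounder covariate: ", nm)
            activity <- activity +
                cfg$confounder_coefs[[nm]] * .zscale(covs[[nm]])
        }
    }

    logMu <- matrix(baseline, nrow = cfg$n_genes, ncol = nC,
                    dimnames = list(genes, cells))
    # markers carry a discrete subtype-identity boost plus a graded
    # stage-continuum component, so subtypes stay separable while
    # stage-adjacent states share partial marker expression (the
    # acinar-to-ductal continuum visible in expression space)
    for (s in subtypes) {
        gi <- genes[markerIdx][markerOf == s]
        w <- cfg$marker_boost * (subtype == s) +
            cfg$marker_graded_boost *
            exp(-0.5 * ((pt - cfg$lineage_spec[s]) /
                        cfg$marker_stage_bandwidth)^2)
        logMu[gi, ] <- logMu[gi, ] +
            matrix(w, nrow = length(gi), ncol = nC, byrow = TRUE)
    }
    tIdx <- match(edges$target, genes)
    logMu[tIdx, ] <- logMu[tIdx, ] +
        cfg$regulon_effect * outer(edges$mode, activity)
    donors <- unique(donor)
    batch <- matrix(rnorm(length(donors) * cfg$n_genes, 0,
                          cfg$batch_effect_sd),
                    nrow = cfg$n_genes,
                    dimnames = list(genes, donors))
    logMu <- logMu + batch[, donor]
    logMu <- sweep(logMu, 2, log(libFactor), "+")

    mu <- exp(logMu)
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / cfg$nb_dispersion),
                     nrow = cfg$n_genes, dimnames = dimnames(mu))
    if (cfg$dropout_logit_slope > 0) {
        keep <- matrix(
            rbinom(length(mu), 1,
                   plogis(cfg$dropout_logit_slope * (logMu - log(0.5)))),
            nrow = cfg$n_genes)
        counts <- counts * keep
    }
    zero <- colSums(counts) == 0
    if (any(zero)) counts[1, zero] <- 1L  # guard: keep every cell normalizable
    storage.mode(counts) <- "integer"

    meta <- data.frame(donor = donor, context = context, sample = donor,
                       cluster = subtype, pct_mito = pctMito,
                       pct_ribo = pctRibo, contamination = contamination,
                       subtype = NA_character_, row.names = cells,
                       stringsAsFactors = FALSE)
    ee <- ExoExperiment(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), cellData = meta)
    ee <- logNormalize(ee)

    geneTruth <- data.frame(
        gene = genes,
        marker_of = NA_character_,
        is_target = genes %in% edges$target,
        mode = 0L,
        lfc_per_activity = 0,
        stringsAsFactors = FALSE)
    geneTruth$marker_of[markerIdx] <- markerOf
    geneTruth$mode[tIdx] <- edges$mode
    geneTruth$lfc_per_activity[tIdx] <- cfg$regulon_effect * edges$mode

    truth <- list(
        cells = data.frame(cell_id = cells, activity_true = activity,
                           activity_latent = activityLatent,
                           subtype_true = subtype, pseudotime_true = pt,
                           stringsAsFactors = FALSE),
        genes = geneTruth,
        module_effects = setNames(numeric(0), character(0)))
    list(experiment = ee, truth = truth, regulon = regulon,
         panels = GeneSetList(panels, "axis_panel"))
}

#' Default disjoint tumor NMF signature gene sets
#'
#' Builds four disjoint signature gene sets named Sig1, Sig2, Sig6 and Sig10
#' (Sig1 + Sig6 form the classical signal, Sig2 + Sig10 the basal signal)
#' over a synthetic gene universe, for use with
#' \code{\link{simulateTumor}}.
#'
#' @param genesPerSig genes per signature.
#' @return A \linkS4class{GeneSetList} of kind \code{nmf_signature}.
#' @export
defaultTumorSignatures <- function(genesPerSig = 25L) {
    ids <- sprintf("T%05d", seq_len(4L * genesPerSig))
    sets <- split(ids, rep(c("Sig1", "Sig6", "Sig2", "Sig10"),
                           each = genesPerSig))
    GeneSetList(sets[c("Sig1", "Sig2", "Sig6", "Sig10")], "nmf_signature")
}

#' Simulate a tumor scRNA-seq dataset along the Classical-Basal continuum
#'
#' Each cell draws a latent classical fraction from \code{continuumMix};
#' classical-signature (Sig1, Sig6) gene means scale with that fraction and
#' basal-signature (Sig2, Sig10) gene means with its complement, calibrated
#' so the mean log-normalized signature scores recover the latent fractions.
#' True families are the explicit thresholds applied to the latent
#' fractions. A latent TF activity increasing with the classical fraction
#' drives a signed regulon over background genes, and 15 samples (default)
#' carry sample-level log-mean shifts.
#'
#' @param nCells number of cells.
#' @param nSamples number of tumor samples.
#' @param signatureSets \linkS4class{GeneSetList} with exactly the four
#'   disjoint signatures Sig1, Sig2, Sig6, Sig10; default
#'   \code{\link{defaultTumorSignatures}()}.
#' @param continuumMix distribution of the latent classical fraction:
#'   \code{list(type = "uniform")}, \code{list(type = "beta", a =, b =)} or
#'   \code{list(type = "point", value =)}.
#' @param sigEffect signature effect strength (log-scale gain per unit
#'   latent loading).
#' @param nBackground background (non-signature) genes.
#' @param nbSize negative-binomial size (inverse dispersion).
#' @param regulonSize,regulonEffect planted TF regulon over background genes
#'   (activity higher in classical cells).
#' @param sampleEffectSd SD of per-sample, per-gene log-mean shifts.
#' @param seed integer seed.
#' @return A list with \code{experiment}, \code{truth} (per-cell
#'   \code{p_classical_true}, \code{p_basal_true}, \code{family_true},
#'   \code{activity_true}), \code{regulon} and \code{signatures}.
#' @export
simulateTumor <- function(nCells = 3000L, nSamples = 15L,
                          signatureSets = defaultTumorSignatures(),
                          continuumMix = list(type = "uniform"),
                          sigEffect = 2.5, nBackground = 1500L,
                          nbSize = 10, regulonSize = 50L,
                          regulonEffect = 0.5, sampleEffectSd = 0.1,
                          seed = 1L) {
    sets <- geneSets(signatureSets)
    need <- c("Sig1", "Sig2", "Sig6", "Sig10")
    if (!setequal(names(sets), need))
        stop("signatureSets must contain exactly Sig1, Sig2, Sig6, Sig10")
    if (any(duplicated(unlist(sets))))
        stop("signature gene lists must be disjoint")
    .withSeed(seed, .simulateTumorImpl(nCells, nSamples, sets, continuumMix,
                                       sigEffect, nBackground, nbSize,
                                       regulonSize, regulonEffect,
                                       sampleEffectSd))
}

# Mean of log1p(c * N) for N ~ NB(mu, size), truncated far in the tail.
.lognormMeanNB <- function(mu, c, size) {
    vapply(mu, function(m) {
        if (m <= 0) return(0)
        nMax <- max(stats::qnbinom(1 - 1e-10, mu = m, size = size), 20)
        n <- 0:nMax
        sum(stats::dnbinom(n, mu = m, size = size) * log1p(c * n))
    }, numeric(1))
}

# Invert target = E[log1p(c N)] over mu by monotone grid interpolation.
.invertLognormMean <- function(target, c, size) {
    muGrid <- c(0, exp(seq(log(1e-4), log(200), length.out = 400)))
    eGrid <- .lognormMeanNB(muGrid, c, size)
    if (max(target) > max(eGrid))
        stop("signature effect too large for the calibration grid")
    out <- stats::approx(eGrid, muGrid, xout = pmax(as.vector(target), 0),
                         rule = 2)$y
    matrix(out, nrow = nrow(target), dimnames = dimnames(target))
}

.drawContinuum <- function(n, mix) {
    switch(mix$type,
           uniform = runif(n),
           beta = rbeta(n, mix$a, mix$b),
           point = rep(mix$value, n),
           stop("unknown continuumMix type: ", mix$type))
}

.simulateTumorImpl <- function(nCells, nSamples, sets, continuumMix,
                               sigEffect, nBackground, nbSize,
                               regulonSize, regulonEffect, sampleEffectSd) {
    sigGenes <- unlist(sets, use.names = FALSE)
    background <- sprintf("B%05d", seq_len(nBackground))
    tf <- "PDX1"
    background[1] <- tf
    genes <- c(sigGenes, background)
    cells <- sprintf("tcell%05d", seq_len(nCells))

    pc <- .drawContinuum(nCells, continuumMix)
    family <- classifyFamily(pc, 1 - pc)
    activity <- 2 * (pc - 0.5) + rnorm(nCells, 0, 0.5)
    sampleId <- paste0("S", sample.int(nSamples, nCells, replace = TRUE))

    regulon <- generateRegulon(tf, regulonSize, 0.25, background[-1],
                               seed = sample.int(2^31 - 1, 1))
    edges <- regulonEdges(regulon)

    baseBg <- rnorm(nBackground, log(1), 0.7)
    names(baseBg) <- background
    baseBg[tf] <- log(0.02)
    libFactor <- rlnorm(nCells, 0, 0.1)
    # expected library total: background dominates (~ nBackground * E[mu])
    expTotal <- nBackground * exp(log(1) + 0.7^2 / 2)
    lnFactor <- 1e4 / expTotal  # lognorm ~ log1p(lnFactor * count)

    loading <- matrix(NA_real_, nrow = length(sigGenes), ncol = nCells,
                      dimnames = list(sigGenes, cells))
    for (s in names(sets)) {
        l <- if (s %in% c("Sig1", "Sig6")) pc else 1 - pc
        loading[sets[[s]], ] <- matrix(l, nrow = length(sets[[s]]),
                                       ncol = nCells, byrow = TRUE)
    }
    # calibrate so the expected lognorm of a signature gene equals
    # sigEffect * latent loading exactly (inverts E[log1p(c N)] for the
    # negative binomial numerically; removes the concavity bias that would
    # otherwise push estimated fractions outward)
    muSig <- .invertLognormMean(sigEffect * loading, lnFactor, nbSize)
    muSig <- sweep(muSig, 2, libFactor, "*")

    logMuBg <- matrix(baseBg, nrow = nBackground, ncol = nCells,
                      dimnames = list(background, cells))
    tIdx <- match(edges$target, background)
    logMuBg[tIdx, ] <- logMuBg[tIdx, ] +
        regulonEffect * outer(edges$mode, activity)
    sampShift <- matrix(rnorm(nSamples * nBackground, 0, sampleEffectSd),
                        nrow = nBackground,
                        dimnames = list(background,
                                        paste0("S", seq_len(nSamples))))
    logMuBg <- logMuBg + sampShift[, sampleId]
    logMuBg <- sweep(logMuBg, 2, log(libFactor), "+")

    mu <- rbind(muSig, exp(logMuBg))[genes, , drop = FALSE]
    counts <- matrix(rnbinom(length(mu), mu = mu, size = nbSize),
                     nrow = length(genes), dimnames = list(genes, cells))
    zero <- colSums(counts) == 0
    if (any(zero)) counts[1, zero] <- 1L
    storage.mode(counts) <- "integer"

    zLib <- .zscale(log(colSums(counts)))
    meta <- data.frame(
        donor = sampleId, context = "tumor", sample = sampleId,
        cluster = NA_character_,
        pct_mito = 100 * plogis(rnorm(nCells, -2.4, 0.5) + 0.1 * zLib),
        pct_ribo = 100 * plogis(rnorm(nCells, -2.2, 0.5) + 0.1 * zLib),
        contamination = plogis(rnorm(nCells, -2.0, 0.6)),
        subtype = NA_character_, row.names = cells,
        stringsAsFactors = FALSE)
    ee <- ExoExperiment(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), cellData = meta)
    ee <- logNormalize(ee)

    truth <- list(cells = data.frame(
        cell_id = cells, p_classical_true = pc, p_basal_true = 1 - pc,
        family_true = family, activity_true = activity, sample = sampleId,
        stringsAsFactors = FALSE))
    list(experiment = ee, truth = truth, regulon = regulon,
         signatures = GeneSetList(sets, "nmf_signature"))
}

#' Simulate a single hurdle-model gene with exact planted effects
#'
#' Generates one gene's detection/expression data under the two-part hurdle
#' model itself: detection is Bernoulli with logit = logit(baseRate) +
#' logOR x activity, and expression among detected cells is Gaussian with
#' mean contMean + betaCont x activity. Used for calibration and
#' parameter-recovery checks where the planted coefficients must be exact on
#' the model's own scale.
#'
#' @param nCells number of cells.
#' @param logOR planted detection log-odds ratio per unit activity.
#' @param betaCont planted continuous slope per unit activity.
#' @param baseRate detection probability at activity 0.
#' @param contMean,contSd mean/SD of expression among detected cells.
#' @param activity optional activity vector (default standard normal).
#' @param seed integer seed.
#' @return data.frame with columns \code{activity}, \code{expr} (0 for
#'   undetected cells) and \code{det}.
#' @export
simulateHurdleGene <- function(nCells, logOR = 0, betaCont = 0,
                               baseRate = 0.5, contMean = 5, contSd = 1,
                               activity = NULL, seed = 1L) {
    .withSeed(seed, {
        if (is.null(activity)) activity <- rnorm(nCells)
        det <- rbinom(nCells, 1, plogis(qlogis(baseRate) + logOR * activity))
        expr <- ifelse(det == 1,
                       pmax(contMean + betaCont * activity +
                            rnorm(nCells, 0, contSd), 0.01),
                       0)
        data.frame(activity = activity, expr = expr, det = det)
    })
}

#' Simulate per-cell module scores with a planted activity coefficient
#'
#' @param activity per-cell activity vector.
#' @param coefficient planted linear coefficient.
#' @param noiseSd Gaussian noise SD.
#' @param seed integer seed.
#' @return numeric vector of scores.
#' @export
simulateModuleScores <- function(activity, coefficient, noiseSd = 1,
                                 seed = 1L) {
    .withSeed(seed,
              coefficient * activity + rnorm(length(activity), 0, noiseSd))
}

#' Simulate clone genotype-dose expression data
#'
#' Emulates CRISPR-edited clone RT-qPCR measurements: each clone has a
#' genotype dose in \{0, 1, 2\} (count of the risk allele), a random clone
#' intercept, and replicate measurements with residual noise, on the
#' analysis (inverse-normal-transformed) scale.
#'
#' @param nClones number of clones.
#' @param nReps replicates per clone.
#' @param doseEffect planted additive dose effect.
#' @param cloneSd SD of clone random intercepts.
#' @param residSd residual SD.
#' @param seed integer seed.
#' @return data.frame with columns \code{clone}, \code{genotype_dose},
#'   \code{expression_int}.
#' @export
simulateCloneExpression <- function(nClones = 12L, nReps = 3L,
                                    doseEffect = -0.8, cloneSd = 0.2,
                                    residSd = 0.3, seed = 1L) {
    .withSeed(seed, {
        dose <- rep_len(c(0L, 1L, 2L), nClones)[sample.int(nClones)]
        intercepts <- rnorm(nClones, 0, cloneSd)
        clone <- rep(paste0("clone", seq_len(nClones)), each = nReps)
        d <- rep(dose, each = nReps)
        y <- doseEffect * d + rep(intercepts, each = nReps) +
            rnorm(nClones * nReps, 0, residSd)
        data.frame(clone = clone, genotype_dose = d, expression_int = y,
                   stringsAsFactors = FALSE)
    })
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the MTX triplet, per-cell metadata TSV, truth TSV, marker-panel
#' GMT and regulon TSV for a \code{\link{simulateExocrine}} or
#' \code{\link{simulateTumor}} result.
#'
#' @param sim simulator output list.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
writeSimulatedDataset <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeCountsMtx(sim$experiment, dir)
    cd <- as.data.frame(SummarizedExperiment::colData(sim$experiment))
    cd <- cbind(cell_id = rownames(cd), cd)
    write.table(cd, file.path(dir, "cell_meta.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$truth$cells, file.path(dir, "truth_cells.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sim$truth$genes))
        write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sim$regulon))
        writeRegulon(sim$regulon, file.path(dir, "regulon.tsv"))
    gs <- if (!is.null(sim$panels)) sim$panels else sim$signatures
    if (!is.null(gs)) writeGeneSets(gs, file.path(dir, "gene_sets.gmt"))
    invisible(dir)
}
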