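#' Pipeline configuration
#'
#' Builds the configuration for \code{\link{runPipeline}}. With
#' \code{inputs = NULL} the workflow starts from the package's seeded
#' synthetic generators; otherwise \code{inputs} names the on-disk files
#' (MTX triplet, cell metadata TSV, regulon TSV, gene-set GMT) and is
#' validated up front so a missing file fails before any stage runs.
#'
#' @param workflow \code{"exocrine"} or \code{"tumor"}.
#' @param seed integer seed recorded in provenance and used by every
#'   stochastic stage.
#' @param sim simulator configuration: an \code{\link{exocrineSimConfig}}
#'   for the exocrine workflow, or a named list of
#'   \code{\link{simulateTumor}} arguments for the tumor workflow.
#' @param inputs optional named list of input files: \code{matrix},
#'   \code{genes}, \code{barcodes}, \code{cell_meta}, \code{regulon},
#'   \code{gene_sets}.
#' @param qc_preset QC preset name (defaults to the workflow's).
#' @param hurdle_weights detection/continuous evidence weights (exocrine
#'   default equal; tumor default 2:1).
#' @param n_hvg,n_pcs embedding parameters.
#' @param alpha_grid embedding tuning grid.
#' @param min_pos hurdle minimum expressing cells.
#' @param clip rank-export z clip bound.
#' @return list of class \code{pipeline_config}.
#' @export
pipelineConfig <- function(workflow = c("exocrine", "tumor"), seed = 1L,
                           sim = NULL, inputs = NULL, qc_preset = NULL,
                           hurdle_weights = NULL, n_hvg = 1000L,
                           n_pcs = 20L, alpha_grid = seq(0, 1, 0.1),
                           min_pos = 25L, clip = 10) {
    workflow <- match.arg(workflow)
    if (is.null(qc_preset)) qc_preset <- workflow
    if (is.null(hurdle_weights))
        hurdle_weights <- if (workflow == "tumor") c(2, 1) else c(1, 1)
    if (is.null(sim)) {
        sim <- if (workflow == "exocrine")
            exocrineSimConfig(n_cells = 800L, n_genes = 600L,
                              seed = seed)
        else list(nCells = 800L, nBackground = 1200L, seed = seed)
    }
    if (!is.null(inputs)) {
        missing <- !vapply(inputs, file.exists, logical(1))
        if (any(missing))
            stop("missing input file(s): ",
                 paste(unlist(inputs[missing]), collapse = ", "))
    }
    cfg <- list(workflow = workflow, seed = as.integer(seed), sim = sim,
                inputs = inputs, qc_preset = qc_preset,
                hurdle_weights = hurdle_weights, n_hvg = as.integer(n_hvg),
                n_pcs = as.integer(n_pcs), alpha_grid = alpha_grid,
                min_pos = as.integer(min_pos), clip = clip)
    class(cfg) <- "pipeline_config"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; fields mirror \code{\link{pipelineConfig}}, with
#'   \code{sim} interpreted as \code{\link{exocrineSimConfig}} fields for
#'   the exocrine workflow.
#' @return list of class \code{pipeline_config}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$sim) && identical(y$workflow, "exocrine")) {
        for (f in c("subtype_proportions", "lineage_spec"))
            if (!is.null(y$sim[[f]])) y$sim[[f]] <- unlist(y$sim[[f]])
        y$sim <- do.call(exocrineSimConfig, y$sim)
    }
    if (!is.null(y$hurdle_weights)) y$hurdle_weights <-
        as.numeric(unlist(y$hurdle_weights))
    if (!is.null(y$alpha_grid)) y$alpha_grid <-
        as.numeric(unlist(y$alpha_grid))
    do.call(pipelineConfig, y)
}

# stage output helper: TSV + provenance JSON with input hashes; only
# basenames are recorded so identical reruns in different directories are
# byte-identical.
.writeStage <- function(outDir, stage, tables, params, seed,
                        inputFiles = character(0)) {
    paths <- character(0)
    for (nm in names(tables)) {
        p <- file.path(outDir, paste0(nm, ".tsv"))
        write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        paths <- c(paths, p)
    }
    hashes <- if (length(inputFiles)) {
        h <- tools::md5sum(inputFiles)
        setNames(unname(h), basename(inputFiles))
    } else NULL
    prov <- list(stage = stage, seed = seed, params = params,
                 outputs = basename(paths), input_md5 = hashes)
    jsonlite::write_json(prov, file.path(outDir,
                                         paste0(stage, ".provenance.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(paths)
}

.loadOrSimulateExocrine <- function(cfg) {
    if (is.null(cfg$inputs)) return(simulateExocrine(cfg$sim))
    ee <- readCountsMtx(cfg$inputs$matrix, cfg$inputs$genes,
                        cfg$inputs$barcodes)
    ee <- readCellMeta(ee, cfg$inputs$cell_meta)
    ee <- logNormalize(ee)
    list(experiment = ee, truth = NULL,
         regulon = readRegulon(cfg$inputs$regulon),
         panels = readGeneSets(cfg$inputs$gene_sets, "axis_panel"))
}

#' Run an end-to-end workflow
#'
#' Orchestrates the stages of the two named workflows, writing each stage's
#' TSV outputs plus a JSON provenance record (stage parameters, seed, input
#' hashes) into \code{outDir}. Reruns with an identical configuration are
#' byte-identical. A stage failure aborts with the stage name; outputs of
#' completed stages persist.
#'
#' The exocrine workflow runs: QC filtering, exocrine cluster selection,
#' axis scoring and subtype assignment, TF activity inference and
#' residualization, combined-embedding tuning, hurdle association models
#' (equal weights), gene-module associations (global and
#' subtype-stratified), trajectory/lineage analysis, and preranked GSEA
#' export. The tumor workflow runs: QC (tumor preset), NMF-signature
#' scoring and three-family classification, activity inference, hurdle
#' models (2:1 weights), and rank export.
#'
#' @param cfg a \code{\link{pipelineConfig}} (or path to its YAML form).
#' @param outDir output directory, created if missing.
#' @return Invisibly, \code{outDir}.
#' @export
runPipeline <- function(cfg, outDir) {
    if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
    stopifnot(inherits(cfg, "pipeline_config"))
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    runner <- if (cfg$workflow == "exocrine") .runExocrine else .runTumor
    runner(cfg, outDir)
    invisible(outDir)
}

#' @rdname runPipeline
#' @param seed,... forwarded to \code{\link{pipelineConfig}}.
#' @export
runExocrineWorkflow <- function(outDir, seed = 1L, ...) {
    runPipeline(pipelineConfig("exocrine", seed = seed, ...), outDir)
}

#' @rdname runPipeline
#' @export
runTumorWorkflow <- function(outDir, seed = 1L, ...) {
    runPipeline(pipelineConfig("tumor", seed = seed, ...), outDir)
}

.stageFail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
}

.tryStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) .stageFail(stage, e))
}

.runExocrine <- function(cfg, outDir) {
    sim <- .tryStage("simulate", .loadOrSimulateExocrine(cfg))
    ee <- sim$experiment

    qc <- .tryStage("qc", applyQCFilter(ee, qcThresholds(cfg$qc_preset)))
    .writeStage(outDir, "qc", list(qc_report = qc$report),
                list(preset = cfg$qc_preset), cfg$seed)
    ee <- qc$kept

    panels <- geneSets(sim$panels)
    acinarIdx <- grep("Acinar", names(panels), ignore.case = TRUE)
    ductalIdx <- grep("Ductal", names(panels), ignore.case = TRUE)
    ee <- .tryStage("select_exocrine", selectExocrine(
        ee, unlist(panels[acinarIdx], use.names = FALSE),
        unlist(panels[ductalIdx], use.names = FALSE),
        seed = cfg$seed))

    axisScores <- .tryStage("score_axes",
                            scoreGeneSets(ee, sim$panels, seed = cfg$seed))
    labels <- sub("^axis_", "", colnames(axisScores))
    assign <- .tryStage("score_axes", assignAxisSubtype(
        axisScores, setNames(labels, colnames(axisScores))))
    SummarizedExperiment::colData(ee)$subtype <- assign$subtype
    .writeStage(outDir, "score_axes",
                list(axis_scores = data.frame(cell_id = rownames(axisScores),
                                              axisScores,
                                              check.names = FALSE),
                     subtype_assignment = assign),
                list(n_bins = 24, n_ctrl = 100), cfg$seed)

    spaces <- .tryStage("embed", computePCSpaces(
        ee, axisScores, nHvg = cfg$n_hvg, nPcs = cfg$n_pcs))
    act <- .tryStage("activity", inferActivity(ee, sim$regulon))
    actR <- .tryStage("activity", residualizeActivity(
        act, SummarizedExperiment::colData(ee),
        spaces$structure_pcs[, 1]))
    .writeStage(outDir, "activity",
                list(activity = data.frame(
                         cell_id = rownames(activityValues(act)),
                         activityValues(act), check.names = FALSE),
                     activity_residualized = data.frame(
                         cell_id = rownames(activityValues(actR)),
                         activityValues(actR), check.names = FALSE)),
                list(min_regulon = 5,
                     covariates = covariatesUsed(actR)), cfg$seed)

    cd <- SummarizedExperiment::colData(ee)
    emb <- .tryStage("embed", suppressWarnings(tuneCombinedEmbedding(
        spaces$structure_pcs, spaces$axis_pcs, cd$subtype,
        as.character(cd$context), cfg$alpha_grid)))
    .writeStage(outDir, "embed",
                list(embedding_curve = objectiveCurve(emb)),
                list(alpha = selectedAlpha(emb), n_hvg = cfg$n_hvg,
                     n_pcs = cfg$n_pcs), cfg$seed)

    tfName <- colnames(activityValues(actR))[1]
    covs <- data.frame(subtype = factor(cd$subtype),
                       donor = factor(cd$donor),
                       context = factor(cd$context),
                       cngeneson = as.numeric(cd$n_genes_detected))
    covs <- covs[, vapply(covs, function(v) length(unique(v)) > 1,
                          logical(1)), drop = FALSE]
    hr <- .tryStage("hurdle", fitHurdle(
        ee, activityValues(actR)[, tfName], covs, minPos = cfg$min_pos,
        weights = cfg$hurdle_weights, clip = cfg$clip))
    .writeStage(outDir, "hurdle", list(hurdle_results = hr),
                list(weights = cfg$hurdle_weights, min_pos = cfg$min_pos),
                cfg$seed)

    ma <- .tryStage("modules", fitModuleAssociations(
        axisScores, activityValues(actR)[, tfName], cd,
        strata = sort(unique(cd$subtype))))
    .writeStage(outDir, "modules", list(module_associations = ma),
                list(strata = "all subtypes"), cfg$seed)

    ls <- .tryStage("trajectory", inferPseudotime(
        combinedPCs(emb), as.character(cd$cluster), cd$subtype))
    ls <- .tryStage("trajectory", computeLineageMetrics(ls, cd$subtype))
    nEligible <- sum(complete.cases(lineageMetrics(ls)))
    ls <- .tryStage("trajectory", suppressWarnings(
        selectRepresentativeLineages(ls, k = min(3L, max(nEligible, 1L)))))
    prof <- .tryStage("trajectory", activityCompositionProfile(
        ls, activityValues(actR)[, tfName], cd$subtype))
    .writeStage(outDir, "trajectory",
                list(lineage_metrics = lineageMetrics(ls),
                     lineage_selection = data.frame(
                         lineage = names(ls@selectionScores),
                         base_score = unname(ls@selectionScores),
                         selected = names(ls@selectionScores) %in%
                             selectedLineages(ls)),
                     lineage_profiles = prof),
                list(root = rootCluster(ls), k = 3), cfg$seed)

    .tryStage("rank_export", exportRankFile(
        hr, file.path(outDir, "ranks.rnk"), weights = cfg$hurdle_weights,
        clip = cfg$clip))
    invisible(outDir)
}

.runTumor <- function(cfg, outDir) {
    sim <- .tryStage("simulate", do.call(simulateTumor, cfg$sim))
    ee <- sim$experiment

    qc <- .tryStage("qc", applyQCFilter(ee, qcThresholds(cfg$qc_preset)))
    .writeStage(outDir, "qc", list(qc_report = qc$report),
                list(preset = cfg$qc_preset), cfg$seed)
    ee <- qc$kept

    fam <- .tryStage("tumor_classify", scoreSignatures(ee, sim$signatures))
    SummarizedExperiment::colData(ee)$subtype <- fam$family
    .writeStage(outDir, "tumor_classify", list(family_calls = fam),
                list(thresholds = "classical>=0.6&basal<=0.3; ordered"),
                cfg$seed)

    act <- .tryStage("activity", inferActivity(ee, sim$regulon))
    .writeStage(outDir, "activity",
                list(activity = data.frame(
                         cell_id = rownames(activityValues(act)),
                         activityValues(act), check.names = FALSE)),
                list(min_regulon = 5), cfg$seed)

    ln <- .tryStage("hurdle", {
        cd <- SummarizedExperiment::colData(ee)
        lnm <- .denseLognorm(ee)
        v <- apply(lnm, 1, var)
        hvg <- names(sort(v, decreasing = TRUE))[
            seq_len(min(cfg$n_hvg, nrow(ee)))]
        pcs <- prcomp(t(lnm[hvg, ]), center = TRUE,
                      rank. = min(cfg$n_pcs, length(hvg)))$x
        cluster <- clusterCellsKmeans(pcs, k = 6L, seed = cfg$seed)
        covs <- data.frame(cluster = factor(cluster),
                           sample = factor(cd$sample),
                           cngeneson = as.numeric(cd$n_genes_detected))
        tfName <- colnames(activityValues(act))[1]
        fitHurdle(ee, activityValues(act)[, tfName], covs,
                  minPos = cfg$min_pos, weights = cfg$hurdle_weights,
                  clip = cfg$clip)
    })
    .writeStage(outDir, "hurdle", list(hurdle_results = ln),
                list(weights = cfg$hurdle_weights, min_pos = cfg$min_pos),
                cfg$seed)

    .tryStage("rank_export", exportRankFile(
        ln, file.path(outDir, "ranks.rnk"), weights = cfg$hurdle_weights,
        clip = cfg$clip))
    invisible(outDir)
}
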