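test_that("exocrine simulation is deterministic under a fixed seed", {
    cfg <- exocrineSimConfig(n_cells = 150L, n_genes = 400L, seed = 5L)
    s1 <- simulateExocrine(cfg)
    s2 <- simulateExocrine(cfg)
    expect_identical(
        as.matrix(SummarizedExperiment::assay(s1$experiment, "counts")),
        as.matrix(SummarizedExperiment::assay(s2$experiment, "counts")))
    expect_identical(s1$truth$cells, s2$truth$cells)
    expect_identical(regulonEdges(s1$regulon), regulonEdges(s2$regulon))
})

test_that("simulated experiments satisfy the container invariants", {
    sim <- simulateExocrine(exocrineSimConfig(n_cells = 200L,
                                              n_genes = 400L, seed = 2L))
    expect_true(methods::validObject(sim$experiment))
    expect_identical(sim$truth$cells$cell_id, colnames(sim$experiment))
    cd <- SummarizedExperiment::colData(sim$experiment)
    expect_true(all(cd$pct_mito >= 0 & cd$pct_mito <= 100))
    expect_true(all(cd$contamination >= 0 & cd$contamination <= 1))
    expect_true(all(sim$truth$cells$pseudotime_true >= 0))
})

test_that("TF transcript is sparse while planted activity is continuous", {
    sim <- simulateExocrine(exocrineSimConfig(n_cells = 600L,
                                              n_genes = 400L, seed = 3L))
    det <- mean(
        as.matrix(SummarizedExperiment::assay(sim$experiment,
                                              "counts"))["PDX1", ] > 0)
    expect_lt(det, 0.10)
    expect_gt(length(unique(sim$truth$cells$activity_true)), 500)
})

test_that("marker genes are higher in their own subtype in expectation", {
    sim <- simulateExocrine(exocrineSimConfig(
        n_cells = 3500L, n_genes = 400L, seed = 4L))
    ln <- as.matrix(lognorm(sim$experiment))
    st <- sim$truth$cells$subtype_true
    gt <- sim$truth$genes
    for (s in unique(gt$marker_of[!is.na(gt$marker_of)])) {
        markers <- gt$gene[!is.na(gt$marker_of) & gt$marker_of == s]
        own <- mean(ln[markers, st == s])
        other <- max(vapply(setdiff(unique(st), s), function(o) {
            mean(ln[markers, st == o])
        }, numeric(1)))
        expect_gt(own, other + 0.1)  # one-sided margin
    }
})

test_that("null regulon effect gives near-zero activity correlation", {
    sim <- simulateExocrine(exocrineSimConfig(
        n_cells = 2000L, n_genes = 500L, regulon_effect = 0,
        seed = 6L))
    ln <- as.matrix(lognorm(sim$experiment))
    tg <- regulonEdges(sim$regulon)$target
    r <- cor(colMeans(ln[tg, ]), sim$truth$cells$activity_true)
    expect_lt(abs(r), 0.1)
})

test_that("planted regulon effect drives target expression", {
    sim <- simulateExocrine(exocrineSimConfig(
        n_cells = 1000L, n_genes = 500L, regulon_effect = 0.5,
        regulon_size = 100L, regulon_frac_repressed = 0, seed = 7L))
    ln <- as.matrix(lognorm(sim$experiment))
    tg <- regulonEdges(sim$regulon)$target
    r <- cor(colMeans(ln[tg, ]), sim$truth$cells$activity_true)
    expect_gt(r, 0.5)
})

test_that("generateRegulon honors size, repression fraction, seed", {
    u <- sprintf("g%03d", 1:50)
    r <- generateRegulon("TF1", 10, 0, u, seed = 1)
    expect_equal(nrow(regulonEdges(r)), 10L)
    expect_true(all(regulonEdges(r)$mode == 1L))

    r2 <- generateRegulon("TF1", 10, 0.5, u, seed = 1)
    expect_equal(sum(regulonEdges(r2)$mode == -1L), 5L)

    r3 <- generateRegulon("TF1", 10, 0.5, u, seed = 1)
    expect_identical(regulonEdges(r2), regulonEdges(r3))

    expect_error(generateRegulon("TF1", 4, 0, u), ">= 5")
    expect_error(generateRegulon("TF1", 60, 0, u), "universe")
})

test_that("degenerate tumor continua land on single families", {
    s1 <- simulateTumor(nCells = 50L, continuumMix = list(type = "point",
                                                          value = 1),
                        seed = 1L)
    expect_true(all(s1$truth$cells$family_true == "Classical"))
    s2 <- simulateTumor(nCells = 50L, continuumMix = list(type = "point",
                                                          value = 0.5),
                        seed = 1L)
    expect_true(all(s2$truth$cells$family_true == "Hybrid"))
})

test_that("uniform continuum matches the threshold partition", {
    # brute-force integration of the family partition of Uniform(0, 1):
    # Classical <=> pc >= 0.7, Basal <=> pc <= 0.3, Hybrid otherwise
    grid <- seq(0.0005, 0.9995, by = 0.001)
    fam <- classifyFamily(grid, 1 - grid)
    expected <- table(fam) / length(grid)
    sim <- simulateTumor(nCells = 3000L,
                         continuumMix = list(type = "uniform"), seed = 9L)
    got <- table(sim$truth$cells$family_true) / 3000
    for (f in names(expected))
        expect_lt(abs(got[[f]] - expected[[f]]), 0.03)
})

test_that("tumor simulation rejects malformed signature collections", {
    sets <- geneSets(defaultTumorSignatures())
    sets$Sig2[1] <- sets$Sig1[1]  # overlap
    bad <- GeneSetList(sets, "nmf_signature")
    expect_error(simulateTumor(nCells = 10L, signatureSets = bad),
                 "disjoint")
})

test_that("hurdle-gene and clone generators are seeded and on-contract", {
    d <- simulateHurdleGene(500, logOR = 1, betaCont = 0.5, seed = 3)
    expect_identical(
        d, simulateHurdleGene(500, logOR = 1, betaCont = 0.5, seed = 3))
    expect_true(all(d$expr[d$det == 0] == 0))
    expect_true(all(d$expr[d$det == 1] > 0))

    cl <- simulateCloneExpression(nClones = 12, nReps = 3, seed = 2)
    expect_equal(nrow(cl), 36L)
    expect_true(all(cl$genotype_dose %in% 0:2))
    expect_equal(length(unique(cl$clone)), 12L)
})

test_that("simulated datasets round trip through the writers", {
    sim <- simulateExocrine(exocrineSimConfig(n_cells = 60L,
                                              n_genes = 320L, seed = 8L))
    dir <- withr::local_tempdir()
    writeSimulatedDataset(sim, dir)
    back <- readCountsMtx(file.path(dir, "matrix.mtx"),
                          file.path(dir, "genes.tsv"),
                          file.path(dir, "barcodes.tsv"))
    expect_equal(
        as.matrix(SummarizedExperiment::assay(back, "counts")),
        as.matrix(SummarizedExperiment::assay(sim$experiment, "counts")))
    reg <- readRegulon(file.path(dir, "regulon.tsv"))
    expect_equal(regulonEdges(reg), regulonEdges(sim$regulon))
    panels <- readGeneSets(file.path(dir, "gene_sets.gmt"), "axis_panel")
    expect_equal(geneSets(panels), geneSets(sim$panels))
})

test_that("YAML simulator configs mirror the constructor", {
    dir <- withr::local_tempdir()
    p <- file.path(dir, "cfg.yaml")
    writeLines(c("n_cells: 100", "n_genes: 350", "seed: 42"), p)
    cfg <- readExocrineSimConfig(p)
    expect_equal(cfg$n_cells, 100L)
    expect_equal(cfg$seed, 42L)
    writeLines("nonsense_field: 1", p)
    expect_error(readExocrineSimConfig(p), "unknown config field")
})
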