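test_that("MTX triplet is read with orientation detection and counted", {
    dir <- withr::local_tempdir()
    m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(4, 1),
                              dims = c(3, 2))
    Matrix::writeMM(m, file.path(dir, "matrix.mtx"))  # genes x cells
    writeLines(c("KRT19", "MUC1", "EPCAM"), file.path(dir, "genes.tsv"))
    writeLines(c("AAAC", "GGGT"), file.path(dir, "barcodes.tsv"))
    ee <- readCountsMtx(file.path(dir, "matrix.mtx"),
                        file.path(dir, "genes.tsv"),
                        file.path(dir, "barcodes.tsv"))
    expect_s4_class(ee, "ExoExperiment")
    cts <- as.matrix(SummarizedExperiment::assay(ee, "counts"))
    expect_identical(dim(cts), c(3L, 2L))
    expect_equal(cts["KRT19", "AAAC"], 4)
    expect_equal(cts["EPCAM", "GGGT"], 1)
    expect_equal(
        unname(SummarizedExperiment::colData(ee)$n_genes_detected),
        c(1L, 1L))

    # same matrix stored transposed (cells x genes) reads identically
    Matrix::writeMM(Matrix::t(m), file.path(dir, "matrix_t.mtx"))
    ee2 <- readCountsMtx(file.path(dir, "matrix_t.mtx"),
                         file.path(dir, "genes.tsv"),
                         file.path(dir, "barcodes.tsv"))
    expect_equal(as.matrix(SummarizedExperiment::assay(ee2, "counts")), cts)
})

test_that("empty coordinate list gives an all-zero matrix", {
    dir <- withr::local_tempdir()
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                              x = numeric(0), dims = c(2, 2))
    Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
    writeLines(c("g1", "g2"), file.path(dir, "genes.tsv"))
    writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
    ee <- readCountsMtx(file.path(dir, "matrix.mtx"),
                        file.path(dir, "genes.tsv"),
                        file.path(dir, "barcodes.tsv"))
    expect_true(all(SummarizedExperiment::assay(ee, "counts") == 0))
    expect_equal(
        unname(SummarizedExperiment::colData(ee)$n_genes_detected),
        c(0L, 0L))
})

test_that("dimension mismatches and bad entries are format errors", {
    dir <- withr::local_tempdir()
    m <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(3, 2))
    Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
    writeLines(c("g1", "g2"), file.path(dir, "genes.tsv"))
    writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
    expect_error(readCountsMtx(file.path(dir, "matrix.mtx"),
                               file.path(dir, "genes.tsv"),
                               file.path(dir, "barcodes.tsv")),
                 "match neither")
    m2 <- Matrix::sparseMatrix(i = 1, j = 1, x = 1.5, dims = c(2, 2))
    Matrix::writeMM(m2, file.path(dir, "matrix2.mtx"))
    expect_error(readCountsMtx(file.path(dir, "matrix2.mtx"),
                               file.path(dir, "genes.tsv"),
                               file.path(dir, "barcodes.tsv")),
                 "non-integer")
})

test_that("MTX write-then-read round trips on random instances", {
    dir <- withr::local_tempdir()
    for (seed in 1:5) {
        ee <- ExoExperiment(Matrix::Matrix(randomCounts(12, 7, seed),
                                           sparse = TRUE))
        writeCountsMtx(ee, dir, prefix = paste0("s", seed, "_"))
        back <- readCountsMtx(
            file.path(dir, paste0("s", seed, "_matrix.mtx")),
            file.path(dir, paste0("s", seed, "_genes.tsv")),
            file.path(dir, paste0("s", seed, "_barcodes.tsv")))
        expect_equal(
            as.matrix(SummarizedExperiment::assay(back, "counts")),
            as.matrix(SummarizedExperiment::assay(ee, "counts")))
    }
})

test_that("log normalization matches its closed form and contracts", {
    m <- matrix(c(1L, 1L), nrow = 2,
                dimnames = list(c("g1", "g2"), "c1"))
    ee <- logNormalize(ExoExperiment(m))
    ln <- as.matrix(lognorm(ee))
    expect_equal(unname(ln[, 1]), rep(log(1 + 5000), 2),
                 tolerance = 1e-10)

    # zero counts map to exactly zero
    ee2 <- logNormalize(tinyExperiment())
    ln2 <- as.matrix(lognorm(ee2))
    cts <- as.matrix(SummarizedExperiment::assay(ee2, "counts"))
    expect_true(all((ln2 == 0) == (cts == 0)))

    # doubling a cell's counts leaves its lognorm unchanged
    m3 <- randomCounts(10, 3, seed = 2) + 1L
    ee3 <- logNormalize(ExoExperiment(m3))
    m4 <- m3
    m4[, 2] <- 2L * m4[, 2]
    ee4 <- logNormalize(ExoExperiment(m4))
    expect_equal(as.matrix(lognorm(ee3))[, 2], as.matrix(lognorm(ee4))[, 2])

    # monotone within a cell
    v <- as.matrix(lognorm(ee3))[, 1]
    expect_true(all(diff(v[order(m3[, 1])]) >= 0))

    # zero-total cell names the cell
    m5 <- m3
    m5[, 3] <- 0L
    expect_error(logNormalize(ExoExperiment(m5)), "c003")
})

test_that("GMT parsing handles sets, duplicates, and errors", {
    dir <- withr::local_tempdir()
    p <- file.path(dir, "sets.gmt")
    writeLines(c("ductal_core\tna\tKRT19\tMUC1\tEPCAM",
                 "acinar\tna\tPRSS1\tCPA1"), p)
    gs <- readGeneSets(p, "axis_panel")
    expect_equal(geneSets(gs)$ductal_core, c("KRT19", "MUC1", "EPCAM"))
    expect_equal(setKind(gs), "axis_panel")

    writeLines("dup\tna\tA\tB\tA", p)
    expect_warning(gs2 <- readGeneSets(p, "gene_module"), "duplicate")
    expect_equal(geneSets(gs2)$dup, c("A", "B"))

    writeLines("empty\tna", p)
    expect_error(readGeneSets(p, "gene_module"), "empty")

    # round trip
    gs3 <- GeneSetList(list(a = c("X", "Y"), b = "Z"), "nmf_signature")
    writeGeneSets(gs3, p)
    expect_equal(geneSets(readGeneSets(p, "nmf_signature")), geneSets(gs3))
})

test_that("regulon TSV parsing enforces the edge contract", {
    dir <- withr::local_tempdir()
    p <- file.path(dir, "reg.tsv")
    writeLines(c("tf\ttarget\tmode\tweight", "PDX1\tINS\t1\t1.0"), p)
    r <- readRegulon(p)
    expect_equal(nrow(regulonEdges(r)), 1L)
    expect_equal(regulonEdges(r)$mode, 1L)

    writeLines(c("tf\ttarget\tmode\tweight",
                 "PDX1\tINS\t1\t1.0", "PDX1\tINS\t-1\t0.5"), p)
    expect_warning(r2 <- readRegulon(p), "duplicated")
    expect_equal(nrow(regulonEdges(r2)), 1L)
    expect_equal(regulonEdges(r2)$mode, 1L)  # first row retained

    writeLines(c("tf\ttarget\tmode\tweight", "PDX1\tINS\t2\t1.0"), p)
    expect_error(readRegulon(p), "mode")

    # round trip
    r3 <- Regulon(data.frame(tf = "PDX1", target = c("A", "B"),
                             mode = c(1L, -1L), weight = c(1, 2)))
    writeRegulon(r3, p)
    expect_equal(regulonEdges(readRegulon(p)), regulonEdges(r3))
})

test_that("ExoExperiment validity rejects inconsistent objects", {
    m <- randomCounts(5, 4)
    expect_error(ExoExperiment(matrix(1L, 2, 2)), "rownames")
    ee <- logNormalize(ExoExperiment(m + 1L))
    bad <- ee
    SummarizedExperiment::assay(bad, "lognorm")[1, 1] <- 0
    expect_error(methods::validObject(bad), "lognorm must be 0")
    bad2 <- ee
    SummarizedExperiment::colData(bad2)$n_genes_detected <- 0L
    expect_error(methods::validObject(bad2), "n_genes_detected")
})
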