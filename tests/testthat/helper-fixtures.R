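# Small in-code fixtures shared across test files.

# Tiny dense ExoExperiment with known counts.
tinyExperiment <- function(counts = NULL) {
    if (is.null(counts)) {
        counts <- matrix(c(4L, 0L, 0L,
                           0L, 0L, 1L), nrow = 3,
                         dimnames = list(paste0("g", 1:3), c("c1", "c2")))
    }
    ExoExperiment(counts)
}

# Random small count matrix with unique labels.
randomCounts <- function(nGenes, nCells, seed = 1) {
    set.seed(seed)
    m <- matrix(rpois(nGenes * nCells, 2), nrow = nGenes,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                sprintf("c%03d", seq_len(nCells))))
    storage.mode(m) <- "integer"
    m
}

# ExoExperiment with full metadata for QC tests.
metaExperiment <- function(nGenes = 50, nCells = 20, seed = 1,
                           pct_mito = 1, pct_ribo = 1,
                           contamination = 0.01, sample = "s1") {
    m <- randomCounts(nGenes, nCells, seed)
    m[m == 0] <- 1L  # ensure all cells normalizable
    meta <- data.frame(donor = "d1", context = "adult",
                       sample = rep_len(sample, nCells),
                       cluster = "k1",
                       pct_mito = rep_len(pct_mito, nCells),
                       pct_ribo = rep_len(pct_ribo, nCells),
                       contamination = rep_len(contamination, nCells))
    ExoExperiment(m, cellData = meta)
}

# Independent brute-force bin-controlled module score used as the oracle
# for moduleScore(): straightforward loop implementation with the same
# binning and sampling contract.
bruteModuleScore <- function(lnorm, genes, nBins, nCtrl, seed) {
    avg <- apply(lnorm, 1, mean)
    bin <- as.integer(cut(rank(avg, ties.method = "first"),
                          breaks = min(nBins, nrow(lnorm))))
    names(bin) <- rownames(lnorm)
    set.seed(seed)
    ctrl <- c()
    for (g in genes) {
        members <- rownames(lnorm)[bin == bin[g]]
        pool <- members[!(members %in% genes)]
        if (length(pool) == 0) pool <- members
        ctrl <- c(ctrl, sample(pool, nCtrl, replace = TRUE))
    }
    modMean <- numeric(ncol(lnorm))
    for (j in seq_len(ncol(lnorm)))
        modMean[j] <- mean(lnorm[genes, j])
    ctrlMean <- numeric(ncol(lnorm))
    for (j in seq_len(ncol(lnorm)))
        ctrlMean[j] <- mean(lnorm[ctrl, j])
    modMean - ctrlMean
}
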