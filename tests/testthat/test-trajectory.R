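# Construct a LineageSet directly for metric/selection tests.
makeLineageSet <- function(pt, paths = NULL, root = "A") {
    if (is.null(paths))
        paths <- setNames(rep(list(c("A", "B")), ncol(pt)), colnames(pt))
    methods::new("LineageSet", pseudotime = pt, rootCluster = root,
                 lineagePaths = paths, metrics = data.frame(),
                 redundancy = matrix(numeric(0), 0, 0),
                 selectionScores = numeric(0), selected = character(0))
}

test_that("two clusters force a single rooted lineage", {
    set.seed(70)
    pcs <- rbind(matrix(rnorm(100, 0, 0.2), ncol = 2),
                 matrix(rnorm(100, 5, 0.2), ncol = 2))
    rownames(pcs) <- paste0("c", 1:100)
    cl <- rep(c("A", "B"), each = 50)
    st <- rep(c("Acinar", "Ductal"), each = 50)
    ls <- inferPseudotime(pcs, cl, st)
    expect_equal(rootCluster(ls), "A")
    expect_equal(length(lineagePaths(ls)), 1L)
    expect_equal(lineagePaths(ls)[[1]], c("A", "B"))
    pt <- pseudotimes(ls)[, 1]
    expect_gte(min(pt), 0)
    expect_lt(mean(pt[cl == "A"]), mean(pt[cl == "B"]))
})

test_that("collinear clusters give one monotone two-segment lineage", {
    set.seed(71)
    x <- c(rnorm(40, 0, 0.1), rnorm(40, 4, 0.1), rnorm(40, 8, 0.1))
    pcs <- cbind(x, rnorm(120, 0, 0.1))
    rownames(pcs) <- paste0("c", 1:120)
    cl <- rep(c("A", "B", "C"), each = 40)
    st <- rep(c("Acinar", "Acinar-stress", "Ductal"), each = 40)
    ls <- inferPseudotime(pcs, cl, st)
    expect_equal(length(lineagePaths(ls)), 1L)
    expect_equal(lineagePaths(ls)[[1]], c("A", "B", "C"))
    pt <- pseudotimes(ls)[, 1]
    expect_gt(cor(pt, x, method = "spearman"), 0.99)
})

test_that("coincident centroids are a degenerate-geometry error", {
    pcs <- matrix(rep(c(0, 0), 40), ncol = 2, byrow = TRUE)
    rownames(pcs) <- paste0("c", 1:40)
    expect_error(inferPseudotime(pcs, rep(c("A", "B"), 20),
                                 rep("Acinar", 40)), "degenerate")
    expect_error(inferPseudotime(pcs[1:5, ], rep("A", 5),
                                 rep("Acinar", 5)), "2 clusters")
})

test_that("planted acinar-to-ductal lineage is recovered", {
    sim <- simulateExocrine(exocrineSimConfig(n_cells = 1200L,
                                              n_genes = 500L, seed = 72L))
    ee <- sim$experiment
    sc <- scoreGeneSets(ee, sim$panels, seed = 1)
    sp <- computePCSpaces(ee, sc, nHvg = 400, nPcs = 15)
    cl <- as.character(SummarizedExperiment::colData(ee)$cluster)
    emb <- suppressWarnings(tuneCombinedEmbedding(
        sp$structure_pcs, sp$axis_pcs, cl,
        as.character(SummarizedExperiment::colData(ee)$context)))
    ls <- inferPseudotime(combinedPCs(emb), cl, cl)
    pt <- pseudotimes(ls)
    best <- which.max(colSums(!is.na(pt)))
    on <- !is.na(pt[, best])
    rho <- cor(pt[on, best], sim$truth$cells$pseudotime_true[on],
               method = "spearman")
    expect_gte(rho, 0.7)
})

test_that("lineage metrics compute fractions, ranges and redundancy", {
    # 50 cells along one lineage: bottom quintile 10 percent ductal-like,
    # top quintile 90 percent -> ductal_delta 0.8
    pt <- cbind(L1 = seq(0, 1, length.out = 50),
                L2 = seq(0, 1, length.out = 50))
    rownames(pt) <- paste0("c", 1:50)
    st <- rep("Acinar", 50)
    st[1:10] <- c("Ductal", rep("Acinar", 9))
    st[41:50] <- c(rep("Ductal", 9), "Acinar")
    ls <- makeLineageSet(pt)
    ls <- computeLineageMetrics(ls, st, ductalLike = "Ductal", q = 0.2)
    met <- lineageMetrics(ls)
    expect_equal(met$ductal_delta, c(0.8, 0.8))
    expect_equal(met$n_cells, c(50L, 50L))
    expect_equal(met$pt_range, c(1, 1))
    expect_equal(lineageRedundancy(ls)["L1", "L2"], 1)  # identical copies

    # all same subtype -> zero delta
    ls2 <- computeLineageMetrics(makeLineageSet(pt), rep("Acinar", 50),
                                 ductalLike = "Ductal")
    expect_equal(lineageMetrics(ls2)$ductal_delta, c(0, 0))

    # lineage with < 2 cells -> missing metrics
    pt3 <- cbind(L1 = c(0.5, rep(NA, 49)), L2 = seq(0, 1, length.out = 50))
    rownames(pt3) <- paste0("c", 1:50)
    ls3 <- computeLineageMetrics(makeLineageSet(pt3), st)
    expect_true(is.na(lineageMetrics(ls3)$pt_range[1]))
})

test_that("duplicated lineages are never both selected", {
    # four lineages over the same cells with equal base metrics: L1 and an
    # exact copy (redundancy 1) plus two rotations of the same ordering
    # with modest |correlation|; the penalty must exclude one copy
    base <- seq(0, 1, length.out = 60)
    rot <- function(k) base[c((k + 1):60, 1:k)]
    pt <- cbind(L1 = base, L1copy = base, L2 = rot(30), L3 = rot(15))
    rownames(pt) <- paste0("c", 1:60)
    ls <- makeLineageSet(pt, paths = setNames(rep(list(c("A", "B")), 4),
                                              colnames(pt)))
    ls <- computeLineageMetrics(ls, rep("Acinar", 60))
    R <- lineageRedundancy(ls)
    expect_equal(R["L1", "L1copy"], 1)
    expect_lt(abs(R["L1", "L2"]), 0.9)
    ls <- selectRepresentativeLineages(ls, k = 3, lambdaPenalty = 1)
    sel <- selectedLineages(ls)
    expect_length(sel, 3L)
    expect_false(all(c("L1", "L1copy") %in% sel))
    expect_true(all(c("L2", "L3") %in% sel))
    # brute force: among all size-3 subsets, every subset avoiding the
    # duplicate pair dominates any subset containing it under the
    # penalized objective (base - lambda * max |redundancy| within subset)
    subsetScore <- function(s) {
        sum(vapply(seq_along(s), function(i) {
            others <- s[-i]
            0 - 1 * max(abs(R[s[i], others]))
        }, numeric(1)))
    }
    subs <- combn(colnames(pt), 3, simplify = FALSE)
    withDup <- vapply(subs, function(s)
        all(c("L1", "L1copy") %in% s), logical(1))
    expect_lt(max(vapply(subs[withDup], subsetScore, numeric(1))),
              max(vapply(subs[!withDup], subsetScore, numeric(1))))
})

test_that("selection limits behave: no penalty, full k, scarcity", {
    pt <- cbind(L1 = seq(0, 1, length.out = 30),
                L2 = seq(0, 2, length.out = 30),
                L3 = c(seq(0, 0.5, length.out = 15), rep(NA, 15)))
    rownames(pt) <- paste0("c", 1:30)
    st <- rep(c("Acinar", "Ductal"), each = 15)
    ls <- computeLineageMetrics(
        makeLineageSet(pt, setNames(rep(list(c("A", "B")), 3),
                                    colnames(pt))), st)
    # lambda = 0 -> top-k by base score
    l0 <- selectRepresentativeLineages(ls, k = 2, lambdaPenalty = 0)
    base <- sort(l0@selectionScores, decreasing = TRUE)
    expect_setequal(selectedLineages(l0), names(base)[1:2])
    # k = all lineages -> everything selected
    lAll <- selectRepresentativeLineages(ls, k = 3)
    expect_setequal(selectedLineages(lAll), colnames(pt))
    # fewer eligible than k -> warning and all eligible
    pt2 <- pt
    pt2[, 3] <- NA
    ls2 <- computeLineageMetrics(
        makeLineageSet(pt2, setNames(rep(list(c("A", "B")), 3),
                                     colnames(pt2))), st)
    expect_warning(l2 <- selectRepresentativeLineages(ls2, k = 3),
                   "eligible")
    expect_setequal(selectedLineages(l2), c("L1", "L2"))
})

test_that("large penalties forbid highly redundant pairs", {
    base <- seq(0, 1, length.out = 40)
    pt <- cbind(L1 = base, L1copy = base,
                L2 = base[c(21:40, 1:20)])  # |cor| with L1 well below 1
    rownames(pt) <- paste0("c", 1:40)
    st <- rep(c("Acinar", "Ductal"), each = 20)
    ls <- computeLineageMetrics(
        makeLineageSet(pt, setNames(rep(list(c("A", "B")), 3),
                                    colnames(pt))), st)
    l <- selectRepresentativeLineages(ls, k = 2, lambdaPenalty = 1e6)
    expect_false(all(c("L1", "L1copy") %in% selectedLineages(l)))
})

test_that("pseudotime is invariant to rigid transformations", {
    set.seed(74)
    pcs <- rbind(matrix(rnorm(80, 0, 0.3), ncol = 2),
                 matrix(rnorm(80, c(4, 1), 0.3), ncol = 2))
    rownames(pcs) <- paste0("c", 1:80)
    cl <- rep(c("A", "B"), each = 40)
    theta <- 0.7
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    p1 <- pseudotimes(inferPseudotime(pcs, cl, rep("Acinar", 80)))
    p2 <- pseudotimes(inferPseudotime(sweep(pcs %*% R, 2, c(3, -1), "+"),
                                      cl, rep("Acinar", 80)))
    expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("profiles bin, normalize and smooth along pseudotime", {
    set.seed(75)
    n <- 200
    pt <- cbind(L1 = runif(n))
    rownames(pt) <- paste0("c", 1:n)
    st <- sample(c("Acinar", "Ductal"), n, TRUE)
    ls <- makeLineageSet(pt)
    ls@selected <- "L1"
    # constant activity -> constant smoothed curve
    prof <- activityCompositionProfile(ls, rep(2, n), st, nBins = 10)
    expect_true(all(abs(prof$activity_smooth - 2) < 1e-12, na.rm = TRUE))
    fr <- prof[, grep("^frac_", colnames(prof))]
    sums <- rowSums(fr)
    expect_true(all(abs(sums[prof$n_cells > 0] - 1) < 1e-9))

    # planted U shape: smoothed minimum falls in the middle third
    act <- 4 * (pt[, 1] - 0.5)^2
    profU <- activityCompositionProfile(ls, act, st, nBins = 15,
                                        smoothWindow = 3)
    mid <- profU$bin_mid[which.min(profU$activity_smooth)]
    expect_gt(mid, 1 / 3)
    expect_lt(mid, 2 / 3)
})
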