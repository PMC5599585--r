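test_that("differential matrix subtracts the control median, cell by cell", {
    m <- rbind(a = c(5, 1, 2, 3), b = c(0, 2, 2, 2))
    ms <- makeME(m, group = c("tumor", rep("control", 3)))
    chg <- differentialMatrix(ms)
    expect_equal(unname(assay(chg, "meth")["a", ]), c(3, -1, 0, 1))
    expect_equal(unname(assay(chg, "meth")["b", ]), c(-2, 0, 0, 0))
    # brute-force oracle on the small fixture
    ms2 <- smallMatrix()
    chg2 <- assay(differentialMatrix(ms2), "meth")
    raw <- assay(ms2, "meth")
    g <- sampleGroups(ms2)
    set.seed(1)
    for (s in sample(rownames(raw), 20)) {
        ref <- median(raw[s, g == "control"])
        expect_equal(chg2[s, ], raw[s, ] - ref)
    }
    # a tumor equal to the reference gives an all-zero column
    expect_error(differentialMatrix(makeME(m, group = rep("tumor", 4))),
                 "control")
})

test_that("MVP kernel density estimates approach the closed-form normal density", {
    set.seed(2)
    x <- matrix(rnorm(10000 * 2), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
    prof <- mvpProfiles(x, nGrid = 512)
    grid <- mvpGrid(prof)
    inner <- grid >= -3 & grid <= 3
    expect_lt(max(abs(mvpDensity(prof)[inner, 1] - dnorm(grid[inner]))), 0.02)
    # every profile integrates to 1 on its grid
    ints <- apply(mvpDensity(prof), 2, trapzOracle, x = grid)
    expect_equal(ints, setNames(c(1, 1), c("a", "b")), tolerance = 1e-6)
})

test_that("symmetric inputs give symmetric profiles; degenerate inputs warn", {
    v <- c(seq(0.1, 3, length.out = 300))
    x <- matrix(c(-v, v), ncol = 1, dimnames = list(NULL, "s"))
    prof <- mvpProfiles(x, nGrid = 301)
    d <- mvpDensity(prof)[, 1]
    expect_lt(max(abs(d - rev(d))), 1e-6)
    expect_warning(mvpProfiles(cbind(s = rep(1, 50), t = rnorm(50))),
                   "degenerate")
})

test_that("the L1 area distance is a metric bounded by 2", {
    grid <- seq(0, 10, length.out = 512)
    tri <- function(lo, hi) {
        y <- pmax(0, 1 - abs(grid - (lo + hi) / 2) / ((hi - lo) / 2))
        y / trapzOracle(y, grid)
    }
    p <- new("MVProfileSet", grid = grid,
             density = cbind(a = tri(0, 2), b = tri(8, 10), c = tri(1, 3)),
             group = rep("tumor", 3), bw = rep(1, 3))
    D <- mvpDistance(p)
    expect_equal(unname(diag(D)), c(0, 0, 0))
    # disjoint supports attain the total-variation bound
    expect_equal(D["a", "b"], 2, tolerance = 1e-9)
    expect_equal(D, t(D), tolerance = 1e-12)
    # metric axioms on random triples
    set.seed(3)
    rp <- randomProfiles(30)
    Dr <- mvpDistance(rp)
    expect_equal(Dr, t(Dr), tolerance = 1e-12)
    worst <- 0
    for (rep in 1:100) {
        ijk <- sample(30, 3)
        viol <- Dr[ijk[1], ijk[3]] -
            (Dr[ijk[1], ijk[2]] + Dr[ijk[2], ijk[3]])
        worst <- max(worst, viol)
    }
    expect_lt(worst, 1e-9)
    # mismatched grids are rejected
    p2 <- new("MVProfileSet", grid = grid + 1,
              density = p@density, group = p@group, bw = p@bw)
    expect_error(mvpDistance(p, p2), "grids")
})

test_that("distance between shifted normals grows monotonically with the shift", {
    grid <- seq(-6, 9, length.out = 1024)
    base <- dnorm(grid); base <- base / trapzOracle(base, grid)
    deltas <- seq(0.1, 2, by = 0.2)
    dens <- sapply(deltas, function(d) {
        y <- dnorm(grid, mean = d); y / trapzOracle(y, grid)
    })
    colnames(dens) <- paste0("d", deltas)
    p <- new("MVProfileSet", grid = grid,
             density = cbind(base = base, dens),
             group = rep("tumor", ncol(dens) + 1),
             bw = rep(1, ncol(dens) + 1))
    D <- mvpDistance(p)
    expect_true(all(diff(D["base", -1]) > 0))
})

test_that("MVS is the distance to the renormalized control-median profile", {
    sim <- smallSim()
    chg <- differentialMatrix(smallMatrix())
    prof <- mvpProfiles(chg)
    mvs <- mvsScores(prof)
    # definitional consistency, recomputed by hand
    ctrl <- mvpDensity(prof)[, sampleGroups(prof) == "control"]
    ref <- apply(ctrl, 1, median)
    ref <- ref / trapzOracle(ref, mvpGrid(prof))
    s1 <- names(mvs$scores)[1]
    byHand <- trapzOracle(abs(mvpDensity(prof)[, s1] - ref), mvpGrid(prof))
    expect_equal(unname(mvs$scores[1]), byHand, tolerance = 1e-12)
    # tracks the planted disruption gradient
    tr <- sim$truth
    expect_gt(cor(mvs$scores, tr$disruption[names(mvs$scores)],
                  method = "spearman"), 0.8)
    # leave-one-out control MVS sits below tumor MVS
    all <- mvsScores(prof, which = "all")$scores
    g <- sampleGroups(prof)
    expect_lt(median(all[names(g)[g == "control"]]),
              median(all[names(g)[g == "tumor"]]))
})

test_that("a profile equal to the control reference scores zero", {
    grid <- seq(-3, 3, length.out = 128)
    y <- dnorm(grid); y <- y / trapzOracle(y, grid)
    p <- new("MVProfileSet", grid = grid,
             density = cbind(t = y, c1 = y, c2 = y),
             group = c("tumor", "control", "control"), bw = rep(1, 3))
    expect_equal(unname(mvsScores(p)$scores), 0, tolerance = 1e-12)
})

test_that("MAD ranking orders by spread with deterministic tie-breaks", {
    m <- rbind(flat = rep(1, 5), wide = c(-2, -1, 0, 1, 2),
               tie_b = c(0, 0, 1, 1, 2), tie_a = c(5, 5, 6, 6, 7))
    colnames(m) <- paste0("T", 1:5)
    r <- madRankSequences(m)
    expect_equal(r$mad[r$sequence_id == "wide"], 1)   # unscaled MAD
    expect_identical(r$sequence_id[4], "flat")        # zero spread ranks last
    # equal MADs (all three spread rows have unscaled MAD 1) resolve by id
    expect_identical(r$sequence_id[1:3], c("tie_a", "tie_b", "wide"))
    # planted disruption-prone sequences concentrate at the top
    sim <- smallSim()
    chg <- differentialMatrix(smallMatrix())
    rk <- madRankSequences(chg)
    prone <- sim$truth$disruptionProneIds
    topFrac <- mean(rk$sequence_id[1:300] %in% prone)
    baseFrac <- mean(rk$sequence_id %in% prone)
    expect_gt(topFrac, 1.5 * baseFrac)
})

test_that("consensus clustering is deterministic, reduces to a single run, and isolates planted groups", {
    chg <- differentialMatrix(smallMatrix())
    # single full-sample resample equals one hierarchical run, entries in {0,1}
    one <- consensusCluster(chg, subsetSizes = 300, k = 3, nResamples = 1,
                            sampleFraction = 1, seed = 9)[["300"]]
    cm <- consensusMatrix(one)
    expect_true(all(cm %in% c(0, 1)))
    same <- outer(clusterAssignment(one), clusterAssignment(one), `==`)
    expect_identical(cm == 1, same)
    # fixed seed reproduces the result exactly
    a <- consensusCluster(chg, subsetSizes = 300, k = 3, nResamples = 50, seed = 5)
    b <- consensusCluster(chg, subsetSizes = 300, k = 3, nResamples = 50, seed = 5)
    expect_identical(consensusMatrix(a[["300"]]), consensusMatrix(b[["300"]]))
    # the planted high-disruption samples form a high-consensus block
    tr <- smallSim()$truth
    hi <- names(tr$disruption)[tr$disruption >= 3]
    full <- consensusCluster(chg, subsetSizes = 500, k = 3,
                             nResamples = 300, seed = 6)[["500"]]
    cmf <- consensusMatrix(full)
    within <- cmf[hi, hi][upper.tri(cmf[hi, hi])]
    between <- cmf[hi, setdiff(rownames(cmf), hi)]
    expect_gt(mean(within), 0.9)
    expect_lt(mean(between), 0.5)
    expect_true(all(clusterAssignment(full)[hi] == clusterAssignment(full)[hi][1]))
    # guard rails
    expect_error(consensusCluster(chg, subsetSizes = 1e6), "exceeds")
    expect_error(consensusCluster(chg, subsetSizes = 300, k = 10,
                                  sampleFraction = 0.2), "fewer samples")
})

test_that("permuting sample order permutes a deterministic consensus matrix", {
    chg <- differentialMatrix(smallMatrix())
    g <- sampleGroups(chg)
    tum <- names(g)[g == "tumor"]
    one <- consensusCluster(chg, subsetSizes = 200, k = 2, nResamples = 1,
                            sampleFraction = 1)[["200"]]
    perm <- sample(ncol(chg))
    one2 <- consensusCluster(chg[, perm], subsetSizes = 200, k = 2,
                             nResamples = 1, sampleFraction = 1)[["200"]]
    cm1 <- consensusMatrix(one)
    cm2 <- consensusMatrix(one2)[rownames(cm1), colnames(cm1)]
    expect_identical(cm1, cm2)
})

test_that("the most disrupted cluster's short-survival test matches the exact oracle", {
    ids <- sprintf("T%02d", 1:37)
    assign <- setNames(rep(c(1L, 2L), c(6, 31)), ids)
    mvs <- setNames(c(rep(2, 6), rep(0.5, 31)), ids)
    # 5/6 short-LSS in the flagged cluster vs 10/31 outside
    clin <- data.frame(
        sample_id = ids, group = "tumor",
        lss_days = c(rep(100, 5), 400, rep(100, 10), rep(400, 21)),
        lss_event = TRUE, stringsAsFactors = FALSE)
    rep <- flagDisruptedGroup(assign, mvs, clin, lssCutoff = 180)
    expect_identical(rep$cluster, 1L)
    expect_equal(rep$p, fisherOracle(5, 1, 10, 21), tolerance = 1e-12)
    expect_gt(rep$odds_ratio, 1)
    # censored before the cutoff is excluded as unknown
    clin2 <- clin
    clin2$lss_event[7] <- FALSE   # censored at day 100: unknown status
    rep2 <- flagDisruptedGroup(assign, mvs, clin2)
    expect_equal(sum(rep2$table), 36)
    # degenerate inputs
    expect_error(flagDisruptedGroup(setNames(rep(1L, 37), ids), mvs, clin),
                 "two clusters")
    clin3 <- clin; clin3$lss_event <- FALSE
    expect_error(flagDisruptedGroup(assign, mvs, clin3), "no deaths")
})
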