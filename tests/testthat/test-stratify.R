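test_that("noiseless latent structure is selected exactly at |r| = 1", {
    set.seed(1)
    n <- 12
    v <- scale(rnorm(n))[, 1]                      # latent direction
    w <- scale(residuals(lm(rnorm(n) ~ v)))[, 1]   # orthogonal direction
    m <- rbind(t(sapply(3:10, function(a) a * v)),       # latent-aligned rows
               t(sapply(seq(0.1, 0.5, length.out = 5), function(a) a * w)))
    rownames(m) <- c(sprintf("lat%02d", 1:8), sprintf("oth%02d", 1:5))
    ms <- makeME(m, group = rep("tumor", n))
    sel <- pcaSelectSequences(ms, corrThreshold = 0.85, nComponents = 1)
    expect_setequal(sel$selected, sprintf("lat%02d", 1:8))
    expect_true(all(abs(sel$correlations[sprintf("lat%02d", 1:8), 1]) > 0.999))
})

test_that("selection is invariant to sample order and errors beyond the rank", {
    ms <- smallMatrix()
    sel1 <- pcaSelectSequences(ms)
    perm <- sample(ncol(ms))
    sel2 <- pcaSelectSequences(ms[, perm])
    expect_setequal(sel1$selected, sel2$selected)
    tiny <- makeME(matrix(rnorm(40), 10), group = rep("tumor", 4))
    expect_error(pcaSelectSequences(tiny, nComponents = 5), "rank")
})

test_that("explained-variance fractions are valid and match an eigendecomposition oracle", {
    set.seed(2)
    m <- matrix(rnorm(20 * 10), 20)
    ms <- makeME(m, group = rep("tumor", 10))
    sel <- pcaSelectSequences(ms, nComponents = 2)
    ve <- sel$varExplained
    expect_true(all(ve >= 0 & ve <= 1))
    expect_true(all(diff(ve) <= 1e-12))
    expect_lte(sum(ve), 1 + 1e-9)
    ev <- eigen(cov(t(m)), symmetric = TRUE)$values
    ev <- ev[ev > 1e-12]
    expect_equal(ve[seq_along(ev)], ev / sum(ev), tolerance = 1e-8)
})

test_that("Ward clustering separates blobs, respects duplicates, and ignores row order", {
    set.seed(3)
    blob <- cbind(matrix(rnorm(50 * 5, 0, 0.3), 50), matrix(rnorm(50 * 5, 4, 0.3), 50))
    colnames(blob) <- paste0("S", 1:10)
    ms <- makeME(blob, group = rep("tumor", 10))
    cl <- wardCluster(ms, k = 2)
    expect_identical(unname(clusterAssignment(cl)[1:5]), rep(1L, 5))
    expect_identical(unname(clusterAssignment(cl)[6:10]), rep(2L, 5))
    # duplicated samples co-assign with their originals
    dup <- blob[, c(1:10, 1, 6)]
    colnames(dup) <- c(paste0("S", 1:10), "dupA", "dupB")
    msd <- makeME(dup, group = rep("tumor", 12))
    cld <- clusterAssignment(wardCluster(msd, k = 2))
    expect_identical(cld[["dupA"]], cld[["S1"]])
    expect_identical(cld[["dupB"]], cld[["S6"]])
    # sequence order is irrelevant
    perm <- sample(nrow(blob))
    clp <- wardCluster(makeME(blob[perm, ], group = rep("tumor", 10)), k = 2)
    expect_identical(clusterAssignment(clp), clusterAssignment(cl))
    expect_error(wardCluster(ms, k = 11), "exceeds")
})

test_that("planted subtypes are recovered from PCA-selected sequences", {
    skip_if_not_installed("mclust")
    ms <- smallMatrix()
    tr <- smallSim()$truth
    sel <- pcaSelectSequences(ms)
    expect_gt(length(sel$selected), 10)
    cl <- wardCluster(ms, k = 3, sequenceIds = sel$selected)
    ari <- mclust::adjustedRandIndex(clusterAssignment(cl),
                                     tr$subgroup[names(clusterAssignment(cl))])
    expect_gt(ari, 0.9)
})

test_that("a clean high-signal fixture concentrates selection on the planted signatures", {
    sim <- simulateMethylArray(simConfig(
        nCpgSequences = 1500, nCdsSequences = 50, signatureEffect = 3,
        eventRateProne = 0.1, eventRateBase = 0.02, noiseSd = 0.15,
        dyeBiasAmplitude = 0, disruptionLevels = rep(1, 37), seed = 12))
    ms <- filterLowMethylation(aggregateToSequences(sim$probes, sim$annotation))
    sel <- pcaSelectSequences(ms)
    sig <- intersect(unlist(sim$truth$signatureMap), rownames(ms))
    jac <- length(intersect(sel$selected, sig)) /
        length(union(sel$selected, sig))
    expect_gt(jac, 0.5)
})

test_that("cluster-clinical association screens factors correctly", {
    cl <- smallSim()$clinical
    assign <- setNames(rep(1:3, length.out = 37),
                       cl$sample_id[cl$group == "tumor"])
    res <- clusterClinicalAssociation(assign, cl)
    expect_true(all(c("stage", "age") %in% res$factor))
    expect_true(all(res$p >= 0 & res$p <= 1))
    # factor equal to the cluster labels: minimal attainable p
    cl2 <- cl
    cl2$mirror <- as.character(assign[cl2$sample_id])
    res2 <- clusterClinicalAssociation(assign, cl2, factors = "mirror")
    expect_lt(res2$p, 1e-10)
    # single-level factor skipped with a warning
    cl2$flat <- "x"
    expect_warning(clusterClinicalAssociation(assign, cl2,
                                              factors = c("mirror", "flat")),
                   "single-level")
    expect_error(clusterClinicalAssociation(setNames(rep(1, 37), names(assign)),
                                            cl), "two clusters")
})

test_that("clinical factors independent of clusters give uniform p-values", {
    set.seed(5)
    ids <- sprintf("T%02d", 1:37)
    ps <- replicate(60, {
        cl <- data.frame(sample_id = ids, group = "tumor",
                         f = sample(c("x", "y"), 37, TRUE),
                         stringsAsFactors = FALSE)
        assign <- setNames(sample(rep(1:3, length.out = 37)), ids)
        clusterClinicalAssociation(assign, cl, factors = "f")$p
    })
    expect_gt(mean(ps), 0.35)
    expect_gt(mean(ps > 0.5), 0.3)
})

test_that("Kaplan-Meier medians and the log-rank statistic match small-sample oracles", {
    cl <- data.frame(sample_id = paste0("S", 1:6), group = "tumor",
                     lss_days = c(1, 2, 3, 4, 5, 6),
                     lss_event = TRUE, stringsAsFactors = FALSE)
    assign <- setNames(rep(1:2, each = 3), cl$sample_id)
    km <- kmLogrank(assign, cl, "LSS", groups = c(1, 2))
    expect_equal(unname(km$medians), c(2, 5))
    # the observed statistic is the most extreme over all label permutations
    perm <- logrankPermutationChisq(cl$lss_days, cl$lss_event, 3)
    expect_equal(km$chisq, max(perm), tolerance = 1e-9)
    expect_equal(mean(perm >= km$chisq - 1e-9), 2 / 20)   # permutation p
    # identical groups: statistic ~ 0, p ~ 1
    cl2 <- cl; cl2$lss_days <- rep(c(10, 20, 30), 2)
    assign2 <- setNames(rep(1:2, 3), cl$sample_id)
    km2 <- kmLogrank(assign2, cl2, "LSS", groups = c(1, 2))
    expect_lt(km2$chisq, 1e-9)
    expect_gt(km2$p, 0.99)
    # KM with no censoring equals the empirical survival function
    fit <- km$fit
    s1 <- summary(fit)$surv[summary(fit)$strata == "grp=1"]
    expect_equal(s1, c(2, 1, 0) / 3)
    # missing endpoint columns and too few events are rejected
    expect_error(kmLogrank(assign, cl[, 1:2], "LSS"), "lacks")
    cl3 <- cl; cl3$lss_event <- c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
    expect_error(kmLogrank(assign, cl3, "LSS", groups = c(1, 2)), ">= 2 events")
})
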