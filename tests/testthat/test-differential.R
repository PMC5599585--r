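test_that("fully separated groups attain the minimal exact two-sided rank-sum p", {
    set.seed(1)
    m <- rbind(sep = c(rnorm(37, 5, 0.1), rnorm(7, 0, 0.1)),
               null = rnorm(44),
               const = rep(1, 44))
    ms <- makeME(m, group = rep(c("tumor", "control"), c(37, 7)))
    dmr <- mwwDmrTest(ms)
    expect_equal(dmr$p[1], 2 / choose(44, 7), tolerance = 1e-12)
    expect_identical(dmr$direction[1], "hyper")
    # constant sequence: flagged, p = 1
    expect_true(dmr$constant[3])
    expect_identical(dmr$p[3], 1)
    # Bonferroni bookkeeping
    expect_equal(dmr$p_bonf, pmin(1, dmr$p * 3))
})

test_that("the rank test is invariant to strictly monotone transforms", {
    set.seed(2)
    m <- matrix(rnorm(20 * 14, 0, 1), 20)
    ms1 <- makeME(m, group = rep(c("tumor", "control"), c(9, 5)))
    ms2 <- makeME(exp(m), group = rep(c("tumor", "control"), c(9, 5)))
    d1 <- mwwDmrTest(ms1); d2 <- mwwDmrTest(ms2)
    expect_equal(d1$statistic, d2$statistic)
    expect_equal(d1$p, d2$p)
})

test_that("null sequences give calibrated raw p-values and no Bonferroni calls", {
    set.seed(3)
    m <- matrix(rnorm(4000 * 44), 4000)
    ms <- makeME(m, group = rep(c("tumor", "control"), c(37, 7)))
    dmr <- mwwDmrTest(ms)
    expect_lte(sum(dmr$significant), 1)
    # the p-value is discrete: its sub-0.05 mass is the exact-law expectation
    law <- mwwNullPValues(37, 7)
    expect_lt(abs(mean(dmr$p < 0.05) - sum(law$prob[law$p < 0.05])), 0.012)
    # empirical p distribution matches the exact discrete null law
    brk <- c(0, head(law$p, -1) + diff(law$p) / 2, 1 + 1e-9)
    obs <- table(cut(dmr$p, brk))
    gof <- suppressWarnings(chisq.test(as.vector(obs), p = law$prob))
    expect_gt(gof$p.value, 0.01)
})

test_that("Bonferroni adjustment is monotone, dominated below by raw p, and capped", {
    set.seed(4)
    p <- runif(50)
    pb <- bonferroni(p)
    expect_true(all(pb >= p))
    expect_true(all(pb <= 1))
    expect_true(all(diff(pb[order(p)]) >= 0))
})

test_that("variance-ratio F tests match var.test and behave under scaling and the null", {
    set.seed(5)
    m <- matrix(rnorm(300 * 37), 300,
                dimnames = list(sprintf("s%03d", 1:300), sprintf("T%02d", 1:37)))
    m[1:150, 1:20] <- m[1:150, 1:20] * 3   # first group 3x sd at half the rows
    ms <- makeME(m, group = rep("tumor", 37))
    grp <- setNames(factor(rep(c("A", "B"), c(20, 17))), colnames(m))
    ft <- variabilityFtest(ms, grp)
    # agreement with var.test on sampled rows
    for (i in sample(300, 8)) {
        vt <- var.test(m[i, 1:20], m[i, 21:37])
        expect_equal(ft$statistic[i], unname(vt$statistic), tolerance = 1e-12)
        expect_equal(ft$p[i], vt$p.value, tolerance = 1e-12)
    }
    # scaled rows: variance ratio near 9, detected with high power
    expect_equal(median(ft$statistic[1:150]), 9, tolerance = 0.35 * 9)
    expect_gt(mean(ft$significant[1:150]), 0.5)
    expect_true(all(ft$more_variable[ft$significant & seq_len(300) <= 150] == "A"))
    # null rows essentially never significant
    expect_lte(sum(ft$significant[151:300]), 1)
    # degenerate rows flagged
    m2 <- rbind(m, flat = rep(c(1, 2), c(20, 17)))
    ms2 <- makeME(m2, group = rep("tumor", 37))
    ft2 <- variabilityFtest(ms2, grp)
    expect_true(ft2$degenerate[301])
    expect_true(is.na(ft2$p[301]))
    expect_error(variabilityFtest(ms, setNames(factor(rep(c("A", "B"), c(1, 36))),
                                               colnames(m))), ">= 2")
})

test_that("clinical factor groupings follow the study's pairings", {
    cl <- smallSim()$clinical
    g <- clinicalFactorGroups(cl, "stage")
    expect_setequal(levels(g), c("III-IV", "V"))
    expect_identical(unname(g[cl$sample_id[which(cl$stage == "V")[1]]]),
                     factor("V", levels = levels(g)))
    g2 <- clinicalFactorGroups(cl, "relapse_any")
    expect_setequal(levels(g2), c("no", "yes"))
    g3 <- clinicalFactorGroups(cl, "relapse_timing")
    expect_setequal(levels(g3), c("after_or_none", "before_end"))
    expect_error(clinicalFactorGroups(cl, "coat_color"), "unknown")
})

test_that("the multivariate model recovers planted covariate effects and matches lm", {
    sim <- smallSim()
    cl <- sim$clinical
    tum <- cl[cl$group == "tumor", ]
    set.seed(6)
    n <- nrow(tum)
    m <- t(replicate(400, 0.3 * tum$age + rnorm(n, 0, 1)))
    m <- rbind(m, t(replicate(400, rnorm(n))))   # pure-noise block
    colnames(m) <- tum$sample_id
    rownames(m) <- sprintf("s%04d", seq_len(nrow(m)))
    ms <- MethylExperiment(m, group = rep("tumor", n))
    fit <- multivariateLm(ms, cl, c("age", "weight"))
    expect_lt(abs(mean(fit$coefficients[1:400, "age"]) - 0.3), 0.02)
    # agreement with lm() on sampled sequences
    for (i in sample(800, 5)) {
        lmFit <- lm(m[i, ] ~ age + weight, data = tum)
        expect_equal(unname(fit$coefficients[i, ]), unname(coef(lmFit)),
                     tolerance = 1e-10)
        fs <- summary(lmFit)$fstatistic
        expect_equal(fit$table$p[i],
                     unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
                     tolerance = 1e-10)
    }
    # pure-noise block: essentially nothing significant after Bonferroni
    expect_lte(sum(fit$table$significant[401:800]), 1)
    # rejected inputs
    expect_error(multivariateLm(ms, cl, character(0)), "non-empty")
    cl2 <- cl; cl2$age2 <- cl2$age
    expect_error(multivariateLm(ms, cl2, c("age", "age2")), "age2")
})

test_that("location enrichment flags planted promoter excess and degenerate directions", {
    set.seed(7)
    n <- 800
    ids <- sprintf("s%04d", 1:n)
    isProm <- runif(n) < 0.25
    locs <- lapply(isProm, function(p) if (p) c("promoter", "exon") else "exon")
    gr <- GenomicRanges::GRanges(rep("chr1", n),
                                 IRanges::IRanges(seq_len(n) * 1000, width = 90))
    names(gr) <- ids
    gr$sequence_class <- "CpG"
    gr$locations <- IRanges::CharacterList(locs)
    gr$gene_symbol <- NA_character_
    # significant-hyper set drawn 3x enriched from promoter sequences
    w <- ifelse(isProm, 3, 1)
    sig <- sample(n, 120, prob = w)
    dmr <- data.frame(sequence_id = ids, significant = seq_len(n) %in% sig,
                      direction = "hyper", stringsAsFactors = FALSE)
    enr <- locationEnrichment(dmr, gr, "hyper")
    prom <- enr[enr$location == "promoter", ]
    expect_gt(prom$odds_ratio, 1)
    expect_true(prom$significant)
    # Fisher p agrees with the brute-force hypergeometric oracle
    expect_equal(prom$p, fisherOracle(prom$in_cat_sig, prom$in_cat_other,
                                      prom$out_cat_sig, prom$out_cat_other),
                 tolerance = 1e-12)
    # empty direction: all p = 1
    dmr0 <- dmr; dmr0$significant <- FALSE
    enr0 <- locationEnrichment(dmr0, gr, "hyper")
    expect_true(all(enr0$p == 1))
})

test_that("beta-category Fisher testing handles the extreme and degenerate tables", {
    # all tumors methylated, all controls unmethylated (37 vs 7)
    m <- rbind(ext = c(rep(2, 37), rep(-2, 7)),
               same = rep(2, 44))
    ms <- makeME(m, group = rep(c("tumor", "control"), c(37, 7)))
    out <- betaCategoryFisher(ms)
    # minlike two-sided p at the hypergeometric extreme: only the observed
    # table is as unlikely as itself
    expect_equal(out$p[1], 1 / choose(44, 7), tolerance = 1e-12)
    expect_equal(out$p[1], fisherOracle(37, 0, 0, 7), tolerance = 1e-12)
    expect_identical(out$direction[1], "hyper")
    # all samples in one category: p = 1
    expect_identical(out$p[2], 1)
})

test_that("beta-category calls agree with rank-test directions at strongly planted DMRs", {
    ms <- smallMatrix()
    dmr <- mwwDmrTest(ms)
    bf <- betaCategoryFisher(ms, alpha = 0.01)
    tr <- smallSim()$truth
    planted <- intersect(c(tr$hyperIds, tr$hypoIds), rownames(ms))
    both <- planted[planted %in% dmr$sequence_id[dmr$significant] &
                    planted %in% bf$sequence_id[bf$significant]]
    expect_gt(length(both), 20)
    agree <- mean(dmr$direction[match(both, dmr$sequence_id)] ==
                  bf$direction[match(both, bf$sequence_id)])
    expect_gt(agree, 0.95)
})
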