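## Independent oracles used to check the implementations.

# brute-force two-sided Fisher p for a 2x2 table (minlike convention):
# enumerate the whole hypergeometric support and sum probabilities <= observed
fisherOracle <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    x <- max(0, r1 + c1 - n):min(r1, c1)
    pr <- exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
    pObs <- pr[x == a]
    sum(pr[pr <= pObs * (1 + 1e-7)])
}

# trapezoidal integral (independent of the package's internal helper)
trapzOracle <- function(y, x) {
    idx <- seq_len(length(x) - 1)
    sum((x[idx + 1] - x[idx]) * (y[idx + 1] + y[idx]) / 2)
}

# random MVProfileSet on a shared grid (smoothed positive curves)
randomProfiles <- function(nProfiles, grid = seq(-4, 4, length.out = 256)) {
    dens <- sapply(seq_len(nProfiles), function(i) {
        y <- stats::filter(abs(rnorm(length(grid))), rep(1, 25), sides = 2)
        y[is.na(y)] <- 0.1
        y <- as.numeric(y) + 0.01
        y / trapzOracle(y, grid)
    })
    new("MVProfileSet", grid = grid, density = dens,
        group = rep("tumor", nProfiles), bw = rep(1, nProfiles))
}

# log-rank chisq over all label permutations (small n): returns the
# permutation distribution of the statistic
logrankPermutationChisq <- function(time, event, n1) {
    n <- length(time)
    combs <- utils::combn(n, n1)
    apply(combs, 2, function(idx) {
        g <- factor(ifelse(seq_len(n) %in% idx, "a", "b"))
        survival::survdiff(survival::Surv(time, event) ~ g)$chisq
    })
}
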