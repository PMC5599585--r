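## Shared fixtures, memoised so expensive simulations run once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
    if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
    .fixtures[[key]]
}

# small default-design simulation used across module tests
smallSim <- function() memo("smallSim", simulateMethylArray(simConfig(seed = 42)))

# its preprocessed, filtered methylation matrix
smallMatrix <- function() memo("smallMatrix", {
    sim <- smallSim()
    pb <- loessDyeCorrect(sim$probes)
    pb <- quantileNormalize(qcFilterArrays(pb)$probes)
    filterLowMethylation(aggregateToSequences(pb, sim$annotation))
})

# full-design simulation + preprocessing: the study-scale fixture shared by
# the acceptance checks (built once; a few minutes of compute)
studyFixture <- function() memo("studyFixture", {
    sim <- simulateMethylArray(studyDesignConfig(seed = 7))
    pb <- loessDyeCorrect(sim$probes)
    pb <- quantileNormalize(qcFilterArrays(pb)$probes)
    ms <- filterLowMethylation(aggregateToSequences(pb, sim$annotation))
    list(sim = sim, matrix = ms, dmr = mwwDmrTest(ms))
})

# a bare MethylExperiment from a matrix, with sample names
makeME <- function(m, group, ...) {
    if (is.null(rownames(m))) rownames(m) <- sprintf("s%05d", seq_len(nrow(m)))
    if (is.null(colnames(m)))
        colnames(m) <- paste0(ifelse(group == "tumor", "T", "C"),
                              seq_along(group))
    MethylExperiment(m, group = group, ...)
}
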