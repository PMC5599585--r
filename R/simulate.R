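#' Simulation configuration for a two-color CpG methylation-array experiment
#'
#' Builds a validated configuration emulating a tumor-versus-control
#' methylation-enrichment array study: ~90 bp-tiled probes over CpG regions
#' and CDS targets, planted hyper-/hypo-methylated sequences, planted tumor
#' subtypes with signature sequences, a per-sample methylation-disruption
#' gradient, intensity-dependent dye bias, and censored Weibull survival
#' endpoints whose hazard depends on the subtype.
#'
#' Defaults reproduce the study design this package targets: 37 tumors vs 7
#' control lymph nodes; planted DMR fractions 0.034 / 0.006 so that the
#' full-design configuration (36,807 CpG regions + 672 CDS, see
#' [studyDesignConfig()]) plants 1,011 hyper- and 183 hypo-methylated
#' sequences; 3 epigenetic subtypes of which one is aggressive (hazard x3);
#' and a disruption gradient with 6 strongly disrupted tumors.
#'
#' @param nTumors,nControls sample counts per group.
#' @param nCpgSequences,nCdsSequences number of CpG-region and CDS target
#'   sequences on the array.
#' @param probesPerSequence mean probes tiling each sequence (Poisson with
#'   minimum 1).
#' @param fracHyper,fracHypo fractions of the designed sequence set planted
#'   as tumor-hypermethylated / hypomethylated; must sum to < 1.
#' @param effectSize mean tumor shift at planted DMRs, log2-ratio units.
#' @param noiseSd per-probe technical noise sd (log2-ratio units).
#' @param dyeBiasAmplitude magnitude of the smooth intensity-dependent dye
#'   bias added per array (0 disables).
#' @param nSubgroups number of planted tumor subtypes.
#' @param signatureSize sequences per subtype signature; `NULL` (default)
#'   uses 4% of the sequence set per subtype, the scale real methylation
#'   subtypes show.
#' @param signatureEffect log2-ratio shift of a subtype's signature sequences
#'   in its member samples; half of each signature is shifted up
#'   (hypermethylated in the subtype), half down.
#' @param disruptionLevels per-tumor multiplier on the magnitude of discrete
#'   aberrant-methylation events (the disruption gradient). `NULL` uses the
#'   default gradient: `nHighDisruption` tumors at `highDisruptionLevel`, the
#'   rest spread evenly over \[0.5, 1.8\].
#' @param nHighDisruption,highDisruptionLevel size and level of the planted
#'   strongly disrupted group (used when `disruptionLevels` is `NULL`).
#' @param disruptionProneFrac fraction of sequences that are disruption-prone
#'   (recurrently aberrant across tumors).
#' @param eventRateProne,eventRateBase per-sample probability of an aberrant
#'   methylation event at a disruption-prone / ordinary sequence.
#' @param eventSd sd of an event's log2-ratio magnitude at disruption level 1
#'   (scaled by the sample's disruption level).
#' @param disruptionCoherence in \[0, 1\]: how strongly events at a
#'   disruption-prone sequence share one direction and magnitude across
#'   samples (recurrent targeting, e.g. of Polycomb loci); 0 = fully
#'   idiosyncratic.
#' @param hyperEventBias probability that a prone sequence's shared event
#'   direction is hypermethylation.
#' @param bioNoiseSd sd of the small per-sequence biological noise present in
#'   every sample.
#' @param controlDisruption disruption level of control samples.
#' @param survival list with `scale` (days), `shape` (Weibull),
#'   `hazardMultipliers` (length `nSubgroups`; `NULL` makes the first
#'   subtype aggressive at hazard x3 and the rest baseline) and
#'   `censorMax` (days; independent uniform censoring on \[0, censorMax\],
#'   light by default as follow-up in such cohorts is near-complete).
#' @param seed integer; fully determines the output.
#' @return A list of class `SimulationConfig`.
#' @seealso [simulateMethylArray()], [studyDesignConfig()]
#' @export
simConfig <- function(nTumors = 37L, nControls = 7L,
                      nCpgSequences = 2000L, nCdsSequences = 60L,
                      probesPerSequence = 3,
                      fracHyper = 0.034, fracHypo = 0.006,
                      effectSize = 3.0, noiseSd = 0.3,
                      dyeBiasAmplitude = 0.3,
                      nSubgroups = 3L, signatureSize = NULL,
                      signatureEffect = 2.0,
                      disruptionLevels = NULL,
                      nHighDisruption = 6L, highDisruptionLevel = 3,
                      disruptionProneFrac = 0.3,
                      eventRateProne = 0.6, eventRateBase = 0.02,
                      eventSd = 1.6, bioNoiseSd = 0.15,
                      disruptionCoherence = 0.5, hyperEventBias = 0.7,
                      controlDisruption = 0.5,
                      survival = list(scale = 300, shape = 1.2,
                                      hazardMultipliers = NULL,
                                      censorMax = 8000),
                      seed = 1L) {
    if (is.null(survival$hazardMultipliers))
        survival$hazardMultipliers <-
            if (nSubgroups > 1) c(3, rep(1, nSubgroups - 1)) else 1
    if (is.null(signatureSize))
        signatureSize <- max(2L, round(0.04 * (nCpgSequences + nCdsSequences)))
    counts <- c(nTumors = nTumors, nControls = nControls,
                nCpgSequences = nCpgSequences, nCdsSequences = nCdsSequences,
                nSubgroups = nSubgroups, signatureSize = signatureSize)
    if (any(counts <= 0))
        stop("all counts must be positive: ",
             paste(names(counts)[counts <= 0], collapse = ", "))
    if (fracHyper < 0 || fracHypo < 0 || fracHyper + fracHypo >= 1)
        stop("fracHyper and fracHypo must be non-negative and sum to < 1")
    if (probesPerSequence < 1)
        stop("probesPerSequence must be >= 1")
    if (is.null(disruptionLevels)) {
        nLow <- nTumors - nHighDisruption
        if (nLow < 0) stop("nHighDisruption exceeds nTumors")
        disruptionLevels <- c(rep(highDisruptionLevel, nHighDisruption),
                              if (nLow > 0) seq(0.5, 1.8, length.out = nLow))
    }
    if (length(disruptionLevels) != nTumors)
        stop("disruptionLevels must have one entry per tumor")
    if (any(disruptionLevels < 0)) stop("disruption levels must be >= 0")
    if (disruptionProneFrac < 0 || disruptionProneFrac > 1)
        stop("disruptionProneFrac must lie in [0, 1]")
    if (any(c(eventRateProne, eventRateBase) < 0) ||
        any(c(eventRateProne, eventRateBase) > 1))
        stop("event rates must lie in [0, 1]")
    if (disruptionCoherence < 0 || disruptionCoherence > 1 ||
        hyperEventBias < 0 || hyperEventBias > 1)
        stop("disruptionCoherence and hyperEventBias must lie in [0, 1]")
    if (length(survival$hazardMultipliers) != nSubgroups)
        stop("survival$hazardMultipliers must have length nSubgroups")
    structure(list(
        nTumors = as.integer(nTumors), nControls = as.integer(nControls),
        nCpgSequences = as.integer(nCpgSequences),
        nCdsSequences = as.integer(nCdsSequences),
        probesPerSequence = probesPerSequence,
        fracHyper = fracHyper, fracHypo = fracHypo,
        effectSize = effectSize, noiseSd = noiseSd,
        dyeBiasAmplitude = dyeBiasAmplitude,
        nSubgroups = as.integer(nSubgroups),
        signatureSize = as.integer(signatureSize),
        signatureEffect = signatureEffect,
        disruptionLevels = disruptionLevels,
        disruptionProneFrac = disruptionProneFrac,
        eventRateProne = eventRateProne, eventRateBase = eventRateBase,
        eventSd = eventSd, bioNoiseSd = bioNoiseSd,
        disruptionCoherence = disruptionCoherence,
        hyperEventBias = hyperEventBias,
        controlDisruption = controlDisruption,
        survival = survival, seed = as.integer(seed)
    ), class = "SimulationConfig")
}

#' Full-design configuration
#'
#' The [simConfig()] preset at the full array design: 36,807 CpG regions and
#' 672 CDS, with DMR fractions set so exactly 1,011 hyper- and 183
#' hypo-methylated sequences are planted.
#'
#' @param ... overrides passed to [simConfig()].
#' @export
studyDesignConfig <- function(...) {
    nSeq <- 36807 + 672
    simConfig(nCpgSequences = 36807L, nCdsSequences = 672L,
              fracHyper = 1011 / nSeq, fracHypo = 183 / nSeq, ...)
}

# fraction of sequences in the methylated (high) baseline mode; calibrated so
# the low-methylation filter retains ~80% of CpG regions and ~32% of CDS,
# the proportions of the study's 29,298 / 215 analysis set
.P_HIGH_CPG <- 0.80
.P_HIGH_CDS <- 0.32

.LOCATIONS <- c("promoter", "5'UTR", "upstream", "exon", "intron",
                "3'UTR", "downstream", "intergenic")

#' Simulate a methylation-array experiment with known ground truth
#'
#' Generates probe-level two-color log2 ratios and intensities, per-sequence
#' genomic annotation, a clinical table with censored survival endpoints, and
#' the planted ground truth. The probe signal decomposes as
#' sequence baseline (bimodal low/high mixture) + planted DMR effect +
#' subtype-signature effect + disruption-scaled per-sample deviation +
#' per-probe offset + smooth intensity-dependent dye bias + Gaussian noise.
#'
#' @param config a `SimulationConfig` from [simConfig()].
#' @return A list of class `MethylSimulation` with elements:
#' \describe{
#'   \item{probes}{a [ProbeSet-class] (assays `M`, `A`).}
#'   \item{annotation}{a [GenomicRanges::GRanges] named by sequence id, with
#'     `sequence_class`, multi-label `locations` and `gene_symbol`.}
#'   \item{clinical}{a data.frame of per-sample covariates and censored
#'     TTP/LSS times (controls carry `NA` clinical values).}
#'   \item{truth}{planted ground truth: `hyperIds`, `hypoIds`, `subgroup`
#'     (named integer per tumor), `signatureMap`, `disruption` (named numeric
#'     per tumor), `disruptionProneIds`.}
#' }
#' @examples
#' sim <- simulateMethylArray(simConfig(nCpgSequences = 200, nCdsSequences = 10))
#' sim$probes
#' @importFrom stats rnorm rbinom rpois runif rweibull setNames
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges CharacterList
#' @export
simulateMethylArray <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    nT <- config$nTumors; nC <- config$nControls; nS <- nT + nC
    nCpg <- config$nCpgSequences; nCds <- config$nCdsSequences
    nSeq <- nCpg + nCds

    seqIds <- c(sprintf("CpG_%05d", seq_len(nCpg)),
                sprintf("CDS_%04d", seq_len(nCds)))
    seqClass <- rep(c("CpG", "CDS"), c(nCpg, nCds))
    sampleIds <- c(sprintf("T%02d", seq_len(nT)), sprintf("C%02d", seq_len(nC)))
    group <- rep(c("tumor", "control"), c(nT, nC))

    ## baseline: bimodal low/high methylation mixture
    pHigh <- ifelse(seqClass == "CpG", .P_HIGH_CPG, .P_HIGH_CDS)
    isHigh <- rbinom(nSeq, 1L, pHigh) == 1L
    baseline <- ifelse(isHigh, rnorm(nSeq, 1.0, 0.5), rnorm(nSeq, -2.0, 0.4))

    ## planted DMRs as methylation switches: hypermethylation starts from
    ## the unmethylated mode of CpG regions (CpG-island gain, as in tumors;
    ## the tumor-side enrichment keeps these past the low-methylation
    ## filter), hypomethylation starts from the methylated mode
    nHyper <- round(config$fracHyper * nSeq)
    nHypo <- round(config$fracHypo * nSeq)
    lowCpg <- which(!isHigh & seqClass == "CpG")
    if (length(lowCpg) < nHyper)
        stop("too few unmethylated CpG sequences to plant hyper DMRs")
    hyperIdx <- sample(lowCpg, nHyper)
    high <- which(isHigh)
    if (length(high) < nHypo)
        stop("too few methylated sequences to plant hypo DMRs")
    hypoIdx <- sample(high, nHypo)

    ## planted subtypes with signature sequences (none when a single
    ## subtype is requested: no contrast exists to plant)
    subgroup <- sample(rep_len(seq_len(config$nSubgroups), nT))
    names(subgroup) <- sampleIds[seq_len(nT)]
    if (config$nSubgroups > 1) {
        sigPool <- setdiff(which(isHigh), c(hyperIdx, hypoIdx))
        needed <- config$nSubgroups * config$signatureSize
        if (length(sigPool) < needed)
            stop("too few sequences for subtype signatures")
        sigIdx <- sample(sigPool, needed)
        signatureMap <- split(seqIds[sigIdx],
                              rep(seq_len(config$nSubgroups),
                                  each = config$signatureSize))
        names(signatureMap) <- paste0("subtype", names(signatureMap))
    } else {
        sigIdx <- integer(0)
        signatureMap <- list()
    }

    ## sequence x sample signal
    disruption <- c(config$disruptionLevels,
                    rep(config$controlDisruption, nC))
    S <- matrix(baseline, nSeq, nS)
    S[hyperIdx, seq_len(nT)] <- S[hyperIdx, seq_len(nT)] + config$effectSize
    S[hypoIdx, seq_len(nT)] <- S[hypoIdx, seq_len(nT)] - config$effectSize
    for (g in seq_len(config$nSubgroups * (length(sigIdx) > 0))) {
        memb <- which(subgroup == g)
        idx <- sigIdx[(g - 1L) * config$signatureSize + seq_len(config$signatureSize)]
        half <- length(idx) %/% 2L
        sgn <- rep(c(1, -1), c(half, length(idx) - half))
        S[idx, memb] <- S[idx, memb] + config$signatureEffect * sgn
    }
    ## disruption: discrete aberrant-methylation events, recurrent at a
    ## disruption-prone sequence subset, with magnitude scaled by the
    ## sample's disruption level; plus small ubiquitous biological noise
    pronePool <- setdiff(seq_len(nSeq), c(hyperIdx, hypoIdx, sigIdx))
    nProne <- min(length(pronePool),
                  round(config$disruptionProneFrac * nSeq))
    proneIdx <- sample(pronePool, nProne)
    rate <- rep(config$eventRateBase, nSeq)
    rate[proneIdx] <- config$eventRateProne
    hasEvent <- matrix(runif(nSeq * nS), nSeq, nS) < rate
    ## prone sequences share an event direction/magnitude template
    ## (recurrent targeting); coherence blends template and idiosyncratic part
    template <- numeric(nSeq)
    template[proneIdx] <- abs(rnorm(nProne, 0, config$eventSd)) *
        ifelse(runif(nProne) < config$hyperEventBias, 1, -1)
    rho <- ifelse(seq_len(nSeq) %in% proneIdx, config$disruptionCoherence, 0)
    eventMag <- (template * rho +
                 sqrt(1 - rho^2) * matrix(rnorm(nSeq * nS, 0, config$eventSd),
                                          nSeq, nS)) *
        rep(disruption, each = nSeq)
    S <- S + hasEvent * eventMag +
        matrix(rnorm(nSeq * nS, 0, config$bioNoiseSd), nSeq, nS)

    ## probes: ~Poisson tiling, per-probe offset, dye bias, technical noise
    nProbesPerSeq <- 1L + rpois(nSeq, config$probesPerSequence - 1)
    probeSeq <- rep.int(seq_len(nSeq), nProbesPerSeq)
    nP <- length(probeSeq)
    probeOffset <- rnorm(nP, 0, 0.15)
    Abase <- rnorm(nP, 10, 1.5)
    A <- Abase + matrix(rnorm(nP * nS, 0, 0.2), nP, nS)
    M <- S[probeSeq, ] + probeOffset + matrix(rnorm(nP * nS, 0, config$noiseSd), nP, nS)
    if (config$dyeBiasAmplitude > 0) {
        c1 <- runif(nS, -1, 1) * config$dyeBiasAmplitude
        c2 <- runif(nS, -1, 1) * config$dyeBiasAmplitude
        z <- (A - 10) / 1.5
        M <- M + sweep(z, 2, c1, `*`) + sweep(z^2 - 1, 2, c2, `*`)
    }
    dimnames(M) <- dimnames(A) <-
        list(sprintf("p%06d", seq_len(nP)), sampleIds)

    probes <- ProbeSet(M, A, sequenceId = seqIds[probeSeq], group = group)

    annotation <- .simulateAnnotation(seqIds, seqClass, nProbesPerSeq,
                                      hyperIdx)
    clinical <- .simulateClinical(sampleIds, group, subgroup, config)

    truth <- list(hyperIds = seqIds[hyperIdx], hypoIds = seqIds[hypoIdx],
                  subgroup = subgroup, signatureMap = signatureMap,
                  disruption = setNames(config$disruptionLevels,
                                        sampleIds[seq_len(nT)]),
                  disruptionProneIds = seqIds[proneIdx])
    structure(list(probes = probes, annotation = annotation,
                   clinical = clinical, truth = truth, config = config),
              class = "MethylSimulation")
}

# multi-label genomic-location annotation; planted hypermethylated sequences
# are promoter-biased, mimicking CpG-island promoter gain in tumors
.simulateAnnotation <- function(seqIds, seqClass, nProbesPerSeq, hyperIdx) {
    nSeq <- length(seqIds)
    base <- rbind(
        CpG = c(promoter = 0.40, `5'UTR` = 0.25, upstream = 0.30, exon = 0.25,
                intron = 0.15, `3'UTR` = 0.05, downstream = 0.10,
                intergenic = 0.15),
        CDS = c(promoter = 0.05, `5'UTR` = 0.10, upstream = 0.05, exon = 0.90,
                intron = 0.30, `3'UTR` = 0.10, downstream = 0.05,
                intergenic = 0.02))
    pr <- base[seqClass, , drop = FALSE]
    pr[hyperIdx, "promoter"] <- pmin(0.95, pr[hyperIdx, "promoter"] * 1.8)
    hits <- matrix(runif(nSeq * ncol(pr)) < pr, nSeq)
    locs <- lapply(seq_len(nSeq), function(i) {
        l <- .LOCATIONS[hits[i, ]]
        if (!length(l)) l <- sample(.LOCATIONS, 1L, prob = pr[i, ])
        l
    })
    chrom <- paste0("chr", sample(1:38, nSeq, replace = TRUE))
    start <- sample.int(1e8, nSeq, replace = TRUE)
    width <- pmax(60L, nProbesPerSeq * 90L)
    gr <- GRanges(chrom, IRanges(start = start, width = width))
    names(gr) <- seqIds
    gr$sequence_class <- seqClass
    gr$locations <- CharacterList(locs)
    gr$gene_symbol <- ifelse(runif(nSeq) < 0.7,
                             sprintf("GENE%05d", sample.int(900, nSeq, TRUE)),
                             NA_character_)
    gr
}

.simulateClinical <- function(sampleIds, group, subgroup, config) {
    nT <- config$nTumors; nC <- config$nControls
    sv <- config$survival
    ## covariate frequencies follow the described cohort
    stage <- sample(c("III", "IV", "V"), nT, TRUE, prob = c(3, 16, 20))
    substage <- sample(c("a", "b"), nT, TRUE, prob = c(27, 12))
    extranodal <- sample(c("yes", "no"), nT, TRUE, prob = c(0.3, 0.7))
    treatment <- sample(c("CH", "CH+VAX"), nT, TRUE, prob = c(16, 23))
    steroid <- sample(c("yes", "no"), nT, TRUE, prob = c(15, 24))
    relapse <- sample(c("during", "after", "never"), nT, TRUE,
                      prob = c(20, 14, 5))
    age <- pmin(13, pmax(3, round(rnorm(nT, 7.5, 2.5))))
    weight <- round(pmin(69, pmax(6, exp(rnorm(nT, log(26), 0.4)))), 1)

    h <- sv$hazardMultipliers[subgroup]
    lssT <- rweibull(nT, sv$shape, sv$scale * h^(-1 / sv$shape))
    ttpT <- rweibull(nT, sv$shape, 0.6 * sv$scale * h^(-1 / sv$shape))
    cens <- runif(nT, 0, sv$censorMax)
    lss <- pmax(1, round(pmin(lssT, cens)))
    ttp <- pmax(1, round(pmin(ttpT, cens)))

    tumorDf <- data.frame(
        sample_id = sampleIds[seq_len(nT)], group = "tumor",
        stage = stage, substage = substage, extranodal = extranodal,
        treatment = treatment, steroid = steroid, relapse = relapse,
        age = age, weight = weight,
        ttp_days = ttp, ttp_event = ttpT <= cens,
        lss_days = lss, lss_event = lssT <= cens,
        stringsAsFactors = FALSE)
    ctrlDf <- data.frame(
        sample_id = sampleIds[nT + seq_len(nC)], group = "control",
        stage = NA_character_, substage = NA_character_,
        extranodal = NA_character_, treatment = NA_character_,
        steroid = NA_character_, relapse = NA_character_,
        age = NA_real_, weight = NA_real_,
        ttp_days = NA_real_, ttp_event = NA,
        lss_days = NA_real_, lss_event = NA,
        stringsAsFactors = FALSE)
    rbind(tumorDf, ctrlDf)
}

#' @export
print.MethylSimulation <- function(x, ...) {
    cat("MethylSimulation:", nrow(x$probes), "probes over",
        length(x$annotation), "sequences;",
        sum(x$probes$group == "tumor"), "tumors /",
        sum(x$probes$group == "control"), "controls\n")
    cat("  planted:", length(x$truth$hyperIds), "hyper,",
        length(x$truth$hypoIds), "hypo,",
        length(x$truth$signatureMap), "subtypes\n")
    invisible(x)
}
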