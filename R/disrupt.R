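#' Differential methylation relative to the control median
#'
#' Per sequence, the reference level is the median across control samples;
#' every sample's change is its methylation level minus that reference.
#' Controls also get change values (against the control median), which feed
#' the control reference profiles of [mvsScores()].
#'
#' @param x a [MethylExperiment-class] with a non-empty control group.
#' @return a [MethylExperiment-class] on the `"change"` scale (same samples).
#' @export
differentialMatrix <- function(x) {
    stopifnot(is(x, "MethylExperiment"))
    g <- sampleGroups(x)
    if (!any(g == "control")) stop("no control samples: reference undefined")
    m <- assay(x, "meth")
    ref <- matrixStats::rowMedians(m[, g == "control", drop = FALSE])
    assay(x, "meth") <- m - ref
    metadata(x)$scale <- "change"
    x
}

#' Methylation variability profiles (MVPs)
#'
#' Per sample, a Gaussian kernel density estimate (Silverman's rule,
#' [stats::bw.nrd0]) of the sample's differential-methylation values,
#' evaluated on one shared grid spanning the pooled 0.1-99.9 percentile
#' range, and renormalized to integrate to 1 on the grid (trapezoidal rule).
#' Degenerate samples (all values identical) fall back to a minimum
#' bandwidth with a warning.
#'
#' @param changes a [MethylExperiment-class] on the `"change"` scale (from
#'   [differentialMatrix()]) or a numeric matrix of changes with sample
#'   columns.
#' @param group sample group labels (taken from `changes` when it is a
#'   [MethylExperiment-class]).
#' @param nGrid grid resolution (default 512).
#' @param gridQuantiles pooled quantiles defining the grid span.
#' @param bwFloor minimum kernel bandwidth.
#' @return an [MVProfileSet-class].
#' @export
mvpProfiles <- function(changes, group = NULL, nGrid = 512,
                        gridQuantiles = c(0.001, 0.999), bwFloor = 1e-3) {
    if (is(changes, "MethylExperiment")) {
        if (!identical(metadata(changes)$scale, "change"))
            stop("expected a change-scale matrix from differentialMatrix()")
        group <- unname(sampleGroups(changes))
        m <- assay(changes, "meth")
    } else {
        m <- as.matrix(changes)
        if (is.null(group)) group <- rep("tumor", ncol(m))
    }
    if (nrow(m) < 2) stop("at least 2 change values per sample are required")
    rng <- stats::quantile(m, gridQuantiles, na.rm = TRUE, names = FALSE)
    grid <- seq(rng[1], rng[2], length.out = nGrid)
    dens <- matrix(0, nGrid, ncol(m), dimnames = list(NULL, colnames(m)))
    bws <- numeric(ncol(m))
    for (j in seq_len(ncol(m))) {
        v <- m[, j][is.finite(m[, j])]
        if (stats::sd(v) == 0) {
            warning("degenerate change distribution for sample ",
                    colnames(m)[j], "; bandwidth floored")
            bw <- bwFloor
        } else {
            bw <- stats::bw.nrd0(v)
            if (!is.finite(bw) || bw < bwFloor) bw <- bwFloor
        }
        d <- stats::density(v, bw = bw, from = rng[1], to = rng[2], n = nGrid)
        area <- .trapz(d$y, grid)
        dens[, j] <- d$y / area
        bws[j] <- bw
    }
    new("MVProfileSet", grid = grid, density = dens,
        group = as.character(group), bw = bws)
}

#' L1 area distance between MVP density curves
#'
#' The area bounded by two profiles' density curves: the trapezoidal integral
#' of the absolute difference of the densities over the shared grid. A
#' metric on profiles; 0 iff the curves coincide on the grid, bounded above
#' by 2 (attained for disjoint supports).
#'
#' @param a an [MVProfileSet-class].
#' @param b optional second [MVProfileSet-class] on the same grid; when
#'   missing, distances within `a` are returned.
#' @return matrix of pairwise distances (profiles of `a` x profiles of `b`).
#' @export
mvpDistance <- function(a, b = a) {
    stopifnot(is(a, "MVProfileSet"), is(b, "MVProfileSet"))
    if (length(a@grid) != length(b@grid) ||
        any(abs(a@grid - b@grid) > 1e-9))
        stop("profiles are on different grids")
    da <- a@density; db <- b@density
    w <- c(diff(a@grid) / 2, 0) + c(0, diff(a@grid) / 2)  # trapezoid weights
    out <- matrix(0, ncol(da), ncol(db),
                  dimnames = list(colnames(da), colnames(db)))
    for (i in seq_len(ncol(da)))
        out[i, ] <- colSums(abs(db - da[, i]) * w)
    out
}

#' Methylation variability score (MVS)
#'
#' The per-sample divergence between its MVP and the control reference: the
#' reference curve is the pointwise median of the control profiles,
#' renormalized to integrate to 1, and the MVS is the L1 area distance
#' ([mvpDistance()]) between the sample's density and that reference. Higher
#' MVS means greater methylation disruption.
#'
#' @param profiles an [MVProfileSet-class] containing tumor and control
#'   profiles on one grid.
#' @param which samples to score (default `"tumor"`; `"all"` scores controls
#'   too, e.g. for leave-one-out checks).
#' @return list of class `MVSResult`: `scores` (named numeric), `reference`
#'   (the renormalized reference density), `grid`.
#' @export
mvsScores <- function(profiles, which = c("tumor", "all")) {
    stopifnot(is(profiles, "MVProfileSet"))
    which <- match.arg(which)
    ctrl <- profiles@density[, profiles@group == "control", drop = FALSE]
    if (ncol(ctrl) == 0) stop("no control profiles to build the reference")
    ref <- matrixStats::rowMedians(ctrl)
    ref <- ref / .trapz(ref, profiles@grid)
    refSet <- new("MVProfileSet", grid = profiles@grid,
                  density = matrix(ref, ncol = 1,
                                   dimnames = list(NULL, "reference")),
                  group = "control", bw = NA_real_)
    idx <- if (which == "tumor") profiles@group == "tumor"
           else rep(TRUE, length(profiles@group))
    sub <- new("MVProfileSet", grid = profiles@grid,
               density = profiles@density[, idx, drop = FALSE],
               group = profiles@group[idx], bw = rep(NA_real_, sum(idx)))
    d <- mvpDistance(sub, refSet)
    structure(list(scores = stats::setNames(d[, 1], rownames(d)),
                   reference = ref, grid = profiles@grid),
              class = "MVSResult")
}

#' Rank sequences by median absolute deviation of their changes
#'
#' Per sequence, the MAD (unscaled by default, i.e. constant 1) of the
#' differential-methylation values across tumor samples; sequences are
#' returned sorted by decreasing MAD, ties broken by sequence id.
#'
#' @param changes a change-scale [MethylExperiment-class] or matrix.
#' @param constant MAD scale constant (default 1; use 1.4826 for the
#'   normal-consistent estimator).
#' @return data.frame `sequence_id`, `mad`, sorted decreasing.
#' @export
madRankSequences <- function(changes, constant = 1) {
    if (is(changes, "MethylExperiment")) {
        g <- sampleGroups(changes)
        m <- assay(changes, "meth")[, g == "tumor", drop = FALSE]
    } else m <- as.matrix(changes)
    if (ncol(m) < 2) stop("at least 2 tumor samples are required")
    mads <- matrixStats::rowMads(m, constant = constant)
    ord <- order(-mads, rownames(m))
    data.frame(sequence_id = rownames(m)[ord], mad = mads[ord],
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Consensus clustering of tumors over MAD-ranked sequence subsets
#'
#' For each subset size: restrict the change matrix to the top-MAD
#' sequences, build MVPs on that restriction, take the pairwise L1 area
#' distance, then repeatedly (default 1,000 times) draw a random sample
#' subset, cluster it hierarchically (average linkage on the profile
#' distance) and record co-assignments. The consensus entry for a sample
#' pair is its co-assignment count over its co-draw count. The final
#' assignment clusters 1 - consensus (average linkage).
#'
#' @param changes a change-scale [MethylExperiment-class] (tumors are
#'   clustered).
#' @param subsetSizes top-MAD subset sizes (default c(250, 500, 1000, 2000);
#'   the study scanned 250-20,000). Sizes above the available sequence count
#'   are an error.
#' @param k cluster count (default 3).
#' @param nResamples subsampling iterations (default 1000).
#' @param sampleFraction fraction of samples per draw (default 0.8, without
#'   replacement).
#' @param nGrid MVP grid resolution.
#' @param seed optional integer seed for the resampling.
#' @return named list of [ConsensusResult-class], one per subset size.
#' @export
consensusCluster <- function(changes, subsetSizes = c(250, 500, 1000, 2000),
                             k = 3, nResamples = 1000, sampleFraction = 0.8,
                             nGrid = 512, seed = NULL) {
    stopifnot(is(changes, "MethylExperiment"))
    g <- sampleGroups(changes)
    m <- assay(changes, "meth")[, g == "tumor", drop = FALSE]
    if (any(subsetSizes > nrow(m)))
        stop("subset size exceeds the available ", nrow(m), " sequences")
    n <- ncol(m)
    nDraw <- ceiling(sampleFraction * n)
    if (nDraw < k)
        stop("sampleFraction draws fewer samples than k clusters")
    if (!is.null(seed)) set.seed(seed)
    ranked <- madRankSequences(m)
    out <- lapply(subsetSizes, function(s) {
        ids <- ranked$sequence_id[seq_len(s)]
        prof <- mvpProfiles(m[ids, , drop = FALSE], nGrid = nGrid)
        D <- mvpDistance(prof)
        co <- drawn <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
        for (r in seq_len(nResamples)) {
            idx <- sort(sample.int(n, nDraw))
            hc <- stats::hclust(stats::as.dist(D[idx, idx]), method = "average")
            cl <- stats::cutree(hc, k = k)
            same <- outer(cl, cl, `==`)
            co[idx, idx] <- co[idx, idx] + same
            drawn[idx, idx] <- drawn[idx, idx] + 1
        }
        cons <- ifelse(drawn > 0, co / drawn, 0)
        diag(cons) <- 1
        fhc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
        assign <- stats::cutree(fhc, k = k)
        new("ConsensusResult", consensus = cons,
            assignment = assign, k = as.integer(k),
            subsetSize = as.integer(s), nResamples = as.integer(nResamples),
            sampleFraction = sampleFraction)
    })
    names(out) <- as.character(subsetSizes)
    out
}

#' Flag the most disrupted cluster and test its short-survival association
#'
#' Identifies the cluster with the highest median MVS and tests whether its
#' members are enriched for short lymphoma-specific survival (death before
#' `lssCutoff` days) by Fisher's exact test. Samples censored before the
#' cutoff have unknown short-survival status and are excluded; samples
#' surviving past the cutoff (event or censored) count as not-short.
#'
#' @param result a [ConsensusResult-class] (or named cluster vector).
#' @param mvs an `MVSResult` from [mvsScores()] (or named numeric scores).
#' @param clinical clinical data.frame with `lss_days`/`lss_event`.
#' @param lssCutoff short-survival cutoff in days (default 180).
#' @return list of class `DisruptedGroupReport`: `cluster` (flagged id),
#'   `members`, `medianMVS` (per cluster), `table` (2x2), `odds_ratio`, `p`.
#' @export
flagDisruptedGroup <- function(result, mvs, clinical, lssCutoff = 180) {
    cl <- if (is(result, "ConsensusResult")) clusterAssignment(result)
          else result
    if (length(unique(cl)) < 2)
        stop("at least two clusters are required")
    scores <- if (inherits(mvs, "MVSResult")) mvs$scores else mvs
    scores <- scores[names(cl)]
    medMVS <- tapply(scores, cl, stats::median)
    flagged <- as.integer(names(medMVS)[which.max(medMVS)])
    idx <- match(names(cl), clinical$sample_id)
    time <- clinical$lss_days[idx]
    event <- as.logical(clinical$lss_event[idx])
    if (!any(event, na.rm = TRUE)) stop("no deaths observed")
    short <- ifelse(time < lssCutoff & event, TRUE,
                    ifelse(time >= lssCutoff, FALSE, NA))
    keep <- !is.na(short)
    inCl <- cl[keep] == flagged
    tab <- table(in_cluster = base::factor(inCl, c(TRUE, FALSE)),
                 short_lss = base::factor(short[keep], c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab)
    structure(list(cluster = flagged,
                   members = names(cl)[cl == flagged],
                   medianMVS = medMVS, table = tab,
                   odds_ratio = unname(ft$estimate), p = ft$p.value,
                   lssCutoff = lssCutoff),
              class = "DisruptedGroupReport")
}

#' @export
print.DisruptedGroupReport <- function(x, ...) {
    cat("Most disrupted cluster:", x$cluster, "(",
        length(x$members), "samples )\n")
    cat("  median MVS per cluster:",
        paste(names(x$medianMVS), "=", round(x$medianMVS, 3), collapse = ", "),
        "\n")
    cat("  short LSS (<", x$lssCutoff, "d): Fisher p =", signif(x$p, 3),
        ", OR =", signif(x$odds_ratio, 3), "\n")
    invisible(x)
}
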