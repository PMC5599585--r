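#' Loess dye-bias correction
#'
#' Removes the smooth intensity-dependent (Cy3/Cy5) dye bias from each array:
#' per sample, a loess curve of the log2 ratio (`M`) against mean log2
#' intensity (`A`) is fitted and subtracted, and the residuals are re-centered
#' to the array median so an unbiased array passes through unchanged.
#'
#' @param probes a [ProbeSet-class].
#' @param span loess span (fraction of probes in each local fit).
#' @return the corrected [ProbeSet-class]; `metadata()$dye_corrected` set.
#' @export
loessDyeCorrect <- function(probes, span = 0.3) {
    stopifnot(is(probes, "ProbeSet"))
    if (nrow(probes) < 50)
        stop("at least 50 probes per array are required for the loess smoother")
    M <- assay(probes, "M")
    A <- assay(probes, "A")
    corrected <- M
    for (j in seq_len(ncol(M))) {
        fit <- limma::loessFit(M[, j], A[, j], span = span)
        corrected[, j] <- fit$residuals + stats::median(M[, j])
    }
    assay(probes, "M") <- corrected
    metadata(probes)$dye_corrected <- TRUE
    probes
}

#' Array-level quality control
#'
#' Flags and drops outlier arrays based on the array-wide spread of the log2
#' ratios: an array fails when its median absolute deviation exceeds
#' `madFold` times the median MAD across arrays (or falls below 1/`madFold`
#' of it). `criteria = NULL` disables filtering (identity).
#'
#' @param probes a [ProbeSet-class].
#' @param criteria list with `madFold` (default 3), or `NULL` to disable.
#' @return a list: `probes` (QC-passed [ProbeSet-class]) and `report`
#'   (data.frame of per-array statistics and pass/fail flags).
#' @export
qcFilterArrays <- function(probes, criteria = list(madFold = 3)) {
    stopifnot(is(probes, "ProbeSet"))
    M <- assay(probes, "M")
    arrayMad <- apply(M, 2, stats::mad)
    report <- data.frame(sample_id = colnames(M), mad = arrayMad,
                         passed = TRUE, stringsAsFactors = FALSE)
    if (!is.null(criteria)) {
        ref <- stats::median(arrayMad)
        report$passed <- arrayMad <= criteria$madFold * ref &
            arrayMad >= ref / criteria$madFold
        if (!any(report$passed)) stop("all arrays fail QC")
        if (!all(report$passed))
            message("QC dropped arrays: ",
                    paste(report$sample_id[!report$passed], collapse = ", "))
        probes <- probes[, report$passed]
    }
    list(probes = probes, report = report)
}

#' Between-sample quantile normalization
#'
#' Forces every sample's marginal distribution to the across-sample mean of
#' the sorted value vectors, preserving within-sample rank order (ties get
#' the average of their target quantiles). Backed by
#' [limma::normalizeQuantiles] with `ties = TRUE`.
#'
#' @param x a [ProbeSet-class], [MethylExperiment-class], or numeric matrix.
#' @return the same type, quantile-normalized.
#' @export
quantileNormalize <- function(x) {
    if (is(x, "ProbeSet")) {
        if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
        assay(x, "M") <- .qn(assay(x, "M"))
        metadata(x)$normalized <- TRUE
        return(x)
    }
    if (is(x, "MethylExperiment")) {
        if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
        assay(x, "meth") <- .qn(assay(x, "meth"))
        metadata(x)$normalized <- TRUE
        return(x)
    }
    if (is.matrix(x)) {
        if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
        return(.qn(x))
    }
    stop("unsupported input type")
}

.qn <- function(m) {
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    out
}

#' Aggregate probes to sequence-level methylation
#'
#' The methylation level of each target sequence in each sample is the median
#' of its probes' (normalized) log2 ratios. Sequences with zero probes cannot
#' occur by construction of [ProbeSet-class]; sequences are reported in
#' first-appearance order of the probe table, with class taken from
#' `annotation` when supplied.
#'
#' @param probes a [ProbeSet-class] (normalized).
#' @param annotation optional [GenomicRanges::GRanges] named by sequence id
#'   with a `sequence_class` column.
#' @return a [MethylExperiment-class] (assay `meth`, log2-ratio scale).
#' @importFrom data.table data.table
#' @export
aggregateToSequences <- function(probes, annotation = NULL) {
    stopifnot(is(probes, "ProbeSet"))
    M <- assay(probes, "M")
    sid <- as.character(rowData(probes)$sequence_id)
    dt <- data.table(sid = sid, M)
    agg <- dt[, lapply(.SD, stats::median), by = sid]
    meth <- as.matrix(agg[, -1])
    rownames(meth) <- agg$sid
    colnames(meth) <- colnames(M)
    seqClass <- NULL
    if (!is.null(annotation)) {
        missing <- setdiff(rownames(meth), names(annotation))
        if (length(missing))
            stop("annotation missing for sequences: ",
                 paste(utils::head(missing, 5), collapse = ", "))
        seqClass <- annotation[rownames(meth)]$sequence_class
    }
    me <- MethylExperiment(meth, group = as.character(probes$group),
                           sequenceClass = seqClass, scale = "log2ratio")
    metadata(me)$normalized <- isTRUE(metadata(probes)$normalized)
    me
}

#' Convert log2 ratios to beta values
#'
#' Maps the two-channel log2 ratio m onto the methylation proportion scale by
#' the base-2 logistic, beta = 2^m / (2^m + 1), so m = 0 corresponds to
#' beta = 0.5 (equal channel intensity) and the map is strictly increasing.
#'
#' @param x a [MethylExperiment-class] on the log2-ratio scale, or a numeric
#'   vector/matrix.
#' @return same type on the beta scale (values in (0, 1)).
#' @seealso [logit2()] for the inverse.
#' @export
betaTransform <- function(x) {
    if (is(x, "MethylExperiment")) {
        if (identical(metadata(x)$scale, "beta"))
            stop("matrix is already on the beta scale")
        assay(x, "meth") <- .beta(assay(x, "meth"))
        metadata(x)$scale <- "beta"
        return(x)
    }
    .beta(x)
}

.beta <- function(m) 1 / (1 + 2^(-m))

#' Base-2 logit (inverse of [betaTransform()])
#' @param beta values in (0, 1).
#' @return log2 ratios.
#' @export
logit2 <- function(beta) log2(beta / (1 - beta))

#' Filter sequences with low methylation enrichment
#'
#' A sample counts as "enriched" at a sequence when its beta value is at
#' least `enrichThreshold`; a sequence is retained iff the enriched-sample
#' fraction reaches `minFraction` in the tumor group or in the control group
#' (group-wise OR, so loci unmethylated in tumors but methylated in controls
#' — candidate hypomethylation — are kept).
#'
#' @param x a [MethylExperiment-class] on either scale (log2 ratios are
#'   converted internally for the enrichment call; the returned object keeps
#'   the input scale).
#' @param enrichThreshold beta level defining "enriched" (default 0.5, the
#'   methylated/unmethylated dichotomy).
#' @param minFraction minimum enriched fraction within a group (default 0.25).
#' @return the filtered [MethylExperiment-class]; `metadata()$filter_report`
#'   holds retained/dropped counts per sequence class.
#' @export
filterLowMethylation <- function(x, enrichThreshold = 0.5,
                                 minFraction = 0.25) {
    stopifnot(is(x, "MethylExperiment"))
    g <- .assertGroups(x)
    m <- assay(x, "meth")
    beta <- if (identical(metadata(x)$scale, "beta")) m else .beta(m)
    enriched <- beta >= enrichThreshold
    fracT <- rowMeans(enriched[, g == "tumor", drop = FALSE])
    fracC <- rowMeans(enriched[, g == "control", drop = FALSE])
    keep <- fracT >= minFraction | fracC >= minFraction
    cls <- sequenceClass(x)
    if (is.null(cls)) cls <- rep("unknown", nrow(x))
    report <- as.data.frame.matrix(table(
        class = cls, status = factor(ifelse(keep, "retained", "dropped"),
                                     levels = c("retained", "dropped"))))
    out <- x[keep, ]
    metadata(out)$filtered <- TRUE
    metadata(out)$filter_report <- report
    out
}
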