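#' PCA-guided sequence selection
#'
#' Principal component analysis over the tumor samples (sequences centered;
#' no scaling, so PC-sequence correlations remain scale-free) followed by
#' selection of the sequences whose methylation vector has absolute Pearson
#' correlation above `corrThreshold` with any of the first `nComponents`
#' score vectors.
#'
#' @param x a [MethylExperiment-class]; only tumor samples enter the PCA.
#' @param corrThreshold absolute-correlation cutoff (default 0.85).
#' @param nComponents number of leading components examined (default 2).
#' @return list of class `PCASelection`: `scores` (samples x PCs),
#'   `varExplained` (fraction per PC, all PCs), `correlations` (sequences x
#'   examined PCs), `selectedPerPC` (list), `selected` (union, character).
#' @export
pcaSelectSequences <- function(x, corrThreshold = 0.85, nComponents = 2) {
    stopifnot(is(x, "MethylExperiment"))
    g <- sampleGroups(x)
    m <- assay(x, "meth")[, g == "tumor", drop = FALSE]
    if (ncol(m) < 3) stop("at least 3 tumor samples are required")
    pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
    rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
    if (nComponents > rank)
        stop("nComponents (", nComponents, ") exceeds the matrix rank (",
             rank, ")")
    scores <- pc$x[, seq_len(nComponents), drop = FALSE]
    varExplained <- pc$sdev^2 / sum(pc$sdev^2)
    sds <- matrixStats::rowSds(m)
    corr <- matrix(0, nrow(m), nComponents,
                   dimnames = list(rownames(m), colnames(scores)))
    ok <- sds > 0
    corr[ok, ] <- stats::cor(t(m[ok, , drop = FALSE]), scores)
    selectedPerPC <- lapply(seq_len(nComponents), function(j)
        rownames(m)[abs(corr[, j]) > corrThreshold])
    names(selectedPerPC) <- colnames(scores)
    structure(list(scores = scores, varExplained = varExplained,
                   correlations = corr, selectedPerPC = selectedPerPC,
                   selected = sort(unique(unlist(selectedPerPC))),
                   corrThreshold = corrThreshold),
              class = "PCASelection")
}

#' @export
print.PCASelection <- function(x, ...) {
    cat("PCASelection:", length(x$selected), "sequences at |r| >",
        x$corrThreshold, "\n")
    ve <- round(100 * x$varExplained[seq_len(ncol(x$scores))], 1)
    cat("  variance explained:",
        paste0(colnames(x$scores), " ", ve, "%", collapse = ", "), "\n")
    for (nm in names(x$selectedPerPC))
        cat("  ", nm, ":", length(x$selectedPerPC[[nm]]), "sequences\n")
    invisible(x)
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering of the tumor samples with Euclidean distance and
#' the Ward.D2 criterion, computed on sequence-wise centered-and-scaled
#' methylation levels restricted to the given sequence set. Deterministic
#' given the input; ties are resolved by `stats::hclust`'s fixed merge order.
#'
#' @param x a [MethylExperiment-class]; tumor samples are clustered.
#' @param k number of clusters.
#' @param sequenceIds sequences to cluster on (default: all rows).
#' @param scaleRows center and scale each sequence before clustering
#'   (default TRUE).
#' @return a [ClusterAssignment-class].
#' @export
wardCluster <- function(x, k, sequenceIds = rownames(x), scaleRows = TRUE) {
    stopifnot(is(x, "MethylExperiment"))
    g <- sampleGroups(x)
    missing <- setdiff(sequenceIds, rownames(x))
    if (length(missing))
        stop("unknown sequences: ", paste(utils::head(missing, 5), collapse = ", "))
    m <- assay(x, "meth")[sequenceIds, g == "tumor", drop = FALSE]
    if (k > ncol(m)) stop("k exceeds the number of samples")
    if (scaleRows) {
        sds <- matrixStats::rowSds(m)
        m <- (m - rowMeans(m)) / ifelse(sds > 0, sds, 1)
    }
    hc <- stats::hclust(stats::dist(t(m)), method = "ward.D2")
    cl <- stats::cutree(hc, k = k)
    new("ClusterAssignment", cluster = cl, k = as.integer(k),
        method = "ward.D2", distance = "euclidean",
        sequenceIds = as.character(sequenceIds), tree = hc)
}

#' Association between cluster membership and clinical features
#'
#' Categorical clinical factors are tested against the cluster labels by
#' Fisher's exact test (falling back to the chi-square test when the exact
#' network exceeds its workspace); continuous factors by Kruskal-Wallis.
#' Single-level factors are skipped with a warning. Bonferroni adjustment is
#' across the tested factors.
#'
#' @param assignment a [ClusterAssignment-class] (or named cluster vector).
#' @param clinical clinical data.frame.
#' @param factors clinical columns to test (default: the standard covariates).
#' @return data.frame: `factor`, `test`, `p`, `p_bonf`, `significant`.
#' @export
clusterClinicalAssociation <- function(assignment, clinical,
                                       factors = c("stage", "substage",
                                                   "extranodal", "treatment",
                                                   "steroid", "relapse",
                                                   "age", "weight")) {
    cl <- if (is(assignment, "ClusterAssignment"))
        clusterAssignment(assignment) else assignment
    if (length(unique(cl)) < 2) stop("at least two clusters are required")
    rows <- lapply(factors, function(f) {
        v <- clinical[[f]][match(names(cl), clinical$sample_id)]
        keep <- !is.na(v)
        if (sum(keep) < 3) { warning("factor skipped (too few values): ", f); return(NULL) }
        v <- v[keep]; cli <- cl[keep]
        if (is.numeric(v)) {
            kt <- stats::kruskal.test(v, base::factor(cli))
            return(data.frame(factor = f, test = "kruskal-wallis",
                              p = kt$p.value, stringsAsFactors = FALSE))
        }
        if (length(unique(v)) < 2) {
            warning("single-level factor skipped: ", f)
            return(NULL)
        }
        tab <- table(cluster = cli, value = v)
        p <- tryCatch(stats::fisher.test(tab, workspace = 2e7)$p.value,
                      error = function(e)
                          suppressWarnings(stats::chisq.test(tab)$p.value))
        data.frame(factor = f, test = "fisher", p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no testable clinical factors")
    out$p_bonf <- bonferroni(out$p)
    out$significant <- out$p_bonf < 0.01
    out
}

#' Kaplan-Meier curves and log-rank test between two clusters
#'
#' Kaplan-Meier estimates per group and the two-group log-rank test for a
#' censored survival endpoint (lymphoma-specific survival or time to
#' progression). The median survival is reported as `NA` when a curve never
#' crosses 0.5.
#'
#' @param assignment a [ClusterAssignment-class], [ConsensusResult-class] or
#'   named cluster vector.
#' @param clinical clinical data.frame with `lss_days`/`lss_event` or
#'   `ttp_days`/`ttp_event`.
#' @param endpoint `"LSS"` or `"TTP"`.
#' @param groups length-2 vector of cluster ids to compare (default: all
#'   clusters if exactly two exist).
#' @return list of class `KMLogrank`: `fit` (a [survival::survfit] object),
#'   `medians` (named), `chisq`, `p`, `n`, `events`.
#' @importFrom survival Surv survfit survdiff
#' @export
kmLogrank <- function(assignment, clinical, endpoint = c("LSS", "TTP"),
                      groups = NULL) {
    endpoint <- match.arg(endpoint)
    cl <- if (is(assignment, "ClusterAssignment") ||
              is(assignment, "ConsensusResult"))
        clusterAssignment(assignment) else assignment
    if (is.null(groups)) {
        groups <- sort(unique(cl))
        if (length(groups) != 2)
            stop("specify the pair of clusters to compare")
    }
    if (length(groups) != 2) stop("groups must name exactly two clusters")
    cl <- cl[cl %in% groups]
    cols <- if (endpoint == "LSS") c("lss_days", "lss_event")
            else c("ttp_days", "ttp_event")
    if (!all(cols %in% names(clinical)))
        stop("clinical table lacks the ", endpoint, " columns: ",
             paste(cols, collapse = ", "))
    idx <- match(names(cl), clinical$sample_id)
    time <- clinical[[cols[1]]][idx]
    event <- as.logical(clinical[[cols[2]]][idx])
    keep <- !is.na(time) & !is.na(event)
    time <- time[keep]; event <- event[keep]; cl <- cl[keep]
    grp <- base::factor(cl, levels = groups)
    ev <- tapply(event, grp, sum)
    if (any(is.na(ev)) || any(ev < 2))
        stop("each compared group needs >= 2 events")
    fit <- survfit(Surv(time, event) ~ grp)
    sd <- survdiff(Surv(time, event) ~ grp)
    medians <- summary(fit)$table[, "median"]
    names(medians) <- sub("^grp=", "", names(medians))
    structure(list(fit = fit,
                   medians = medians,
                   chisq = sd$chisq,
                   p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                   n = as.vector(table(grp)), events = as.vector(ev),
                   endpoint = endpoint, groups = groups),
              class = "KMLogrank")
}

#' @export
print.KMLogrank <- function(x, ...) {
    cat("Log-rank (", x$endpoint, "): cluster ", x$groups[1], " vs ",
        x$groups[2], "\n", sep = "")
    cat("  n =", paste(x$n, collapse = " vs "),
        "; events =", paste(x$events, collapse = " vs "), "\n")
    cat("  medians:", paste(names(x$medians), "=",
                            round(x$medians, 1), collapse = ", "), "\n")
    cat("  chisq =", round(x$chisq, 3), ", p =", signif(x$p, 3), "\n")
    invisible(x)
}
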