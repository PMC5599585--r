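#' Differentially methylated sequences by Mann-Whitney-Wilcoxon test
#'
#' Per sequence, a two-sided rank-sum test of tumor versus control
#' methylation levels with Bonferroni control over the tested sequence set.
#' [stats::wilcox.test] supplies the exact null distribution when both group
#' sizes are below 50 and no ties occur (always the case for the 7-control
#' design on continuous data), and the tie- and continuity-corrected normal
#' approximation otherwise. Direction is the sign of
#' (median tumor - median control).
#'
#' @param x a filtered [MethylExperiment-class] with both groups present.
#' @param alpha family-wise significance level (default 0.01).
#' @return data.frame: `sequence_id`, `class`, `statistic` (rank-sum W),
#'   `p`, `p_bonf`, `effect` (median difference), `direction`
#'   (`"hyper"`/`"hypo"`), `significant`, `constant` (flag for sequences
#'   constant across all samples, reported with p = 1).
#' @importFrom matrixStats rowMedians
#' @export
mwwDmrTest <- function(x, alpha = 0.01) {
    stopifnot(is(x, "MethylExperiment"))
    g <- .assertGroups(x)
    if (sum(g == "tumor") < 2 || sum(g == "control") < 2)
        stop("both groups need >= 2 samples")
    m <- assay(x, "meth")
    tIdx <- which(g == "tumor"); cIdx <- which(g == "control")
    constant <- matrixStats::rowVars(m) == 0
    stat <- p <- rep(NA_real_, nrow(m))
    for (i in seq_len(nrow(m))) {
        if (constant[i]) { stat[i] <- NA; p[i] <- 1; next }
        wt <- suppressWarnings(
            stats::wilcox.test(m[i, tIdx], m[i, cIdx]))
        stat[i] <- unname(wt$statistic)
        p[i] <- wt$p.value
    }
    effect <- rowMedians(m[, tIdx, drop = FALSE]) -
        rowMedians(m[, cIdx, drop = FALSE])
    pBonf <- bonferroni(p)
    cls <- sequenceClass(x)
    data.frame(
        sequence_id = rownames(m),
        class = if (is.null(cls)) NA_character_ else unname(cls),
        statistic = stat, p = p, p_bonf = pBonf,
        effect = effect,
        direction = ifelse(effect > 0, "hyper",
                           ifelse(effect < 0, "hypo", NA_character_)),
        significant = pBonf < alpha,
        constant = constant,
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Exact null distribution of the two-sided rank-sum p-value
#'
#' For group sizes `n1`, `n2` without ties, the two-sided exact
#' Mann-Whitney-Wilcoxon p-value takes finitely many values; this returns
#' the attainable p-values and their exact null probabilities (from
#' [stats::dwilcox]), using the same two-sided doubling rule as
#' [stats::wilcox.test]. Useful for calibration checks: with small groups
#' the p-value is markedly discrete, so its uniformity under the null must
#' be judged against this law rather than the continuous uniform.
#'
#' @param n1,n2 group sizes.
#' @return data.frame with `p` (sorted attainable values) and `prob` (their
#'   null probabilities, summing to 1).
#' @export
mwwNullPValues <- function(n1, n2) {
    w <- 0:(n1 * n2)
    prob <- stats::dwilcox(w, n1, n2)
    tail <- ifelse(w > n1 * n2 / 2,
                   stats::pwilcox(w - 1, n1, n2, lower.tail = FALSE),
                   stats::pwilcox(w, n1, n2))
    p <- pmin(1, 2 * tail)
    o <- order(p)
    p <- p[o]; prob <- prob[o]
    # merge atoms equal up to floating-point wobble without losing precision
    grp <- cumsum(c(TRUE, diff(p) > 1e-9 * pmax(p[-1], 1e-300)))
    data.frame(p = unname(tapply(p, grp, `[`, 1)),
               prob = unname(tapply(prob, grp, sum)))
}

#' Binary clinical groupings used for variability testing
#'
#' Encodes a clinical factor as the two-level comparison used by
#' [variabilityFtest()]: stage III-IV vs V, substage a vs b, extranodal
#' yes/no, treatment CH vs CH+VAX, steroid pretreatment yes/no, and relapse
#' encoded both ways (`relapse_any`: ever vs never; `relapse_timing`: before
#' the end of therapy vs after-or-never).
#'
#' @param clinical clinical data.frame (see [simulateMethylArray()]).
#' @param factor one of `"stage"`, `"substage"`, `"extranodal"`,
#'   `"treatment"`, `"steroid"`, `"relapse_any"`, `"relapse_timing"`.
#' @return named factor with two levels over tumor samples (others `NA`).
#' @export
clinicalFactorGroups <- function(clinical, factor) {
    tum <- clinical[clinical$group == "tumor", , drop = FALSE]
    v <- switch(factor,
        stage = ifelse(tum$stage %in% c("III", "IV"), "III-IV", "V"),
        substage = tum$substage,
        extranodal = tum$extranodal,
        treatment = tum$treatment,
        steroid = tum$steroid,
        relapse_any = ifelse(tum$relapse == "never", "no", "yes"),
        relapse_timing = ifelse(tum$relapse == "during",
                                "before_end", "after_or_none"),
        stop("unknown clinical factor: ", factor))
    stats::setNames(base::factor(v), tum$sample_id)
}

#' Differential variability by two-sided F-test
#'
#' Per sequence, a variance-ratio F test between the two levels of a binary
#' grouping of the tumor samples (e.g. a clinical factor from
#' [clinicalFactorGroups()]), with Bonferroni control. Sequences constant
#' within both groups have an undefined variance ratio and are flagged and
#' excluded from the family.
#'
#' @param x a [MethylExperiment-class].
#' @param groups named two-level factor over (a subset of) samples; `NA`
#'   samples are dropped.
#' @param alpha family-wise level (default 0.01).
#' @return data.frame: `sequence_id`, `statistic` (variance ratio, level 1
#'   over level 2), `p`, `p_bonf`, `more_variable` (level name), `significant`,
#'   `degenerate`.
#' @export
variabilityFtest <- function(x, groups, alpha = 0.01) {
    stopifnot(is(x, "MethylExperiment"))
    groups <- groups[!is.na(groups)]
    groups <- droplevels(base::factor(groups))
    if (nlevels(groups) != 2)
        stop("groups must have exactly two levels")
    ids <- intersect(names(groups), colnames(x))
    g1 <- ids[groups[ids] == levels(groups)[1]]
    g2 <- ids[groups[ids] == levels(groups)[2]]
    if (length(g1) < 2 || length(g2) < 2)
        stop("each group needs >= 2 samples")
    m <- assay(x, "meth")
    v1 <- matrixStats::rowVars(m[, g1, drop = FALSE])
    v2 <- matrixStats::rowVars(m[, g2, drop = FALSE])
    degenerate <- v1 == 0 & v2 == 0
    ratio <- ifelse(degenerate, NA_real_, v1 / v2)
    df1 <- length(g1) - 1L; df2 <- length(g2) - 1L
    pf1 <- stats::pf(ratio, df1, df2)
    p <- 2 * pmin(pf1, 1 - pf1)
    p[degenerate] <- NA_real_
    pBonf <- rep(NA_real_, length(p))
    pBonf[!degenerate] <- bonferroni(p[!degenerate])
    data.frame(
        sequence_id = rownames(m),
        statistic = ratio, p = p, p_bonf = pBonf,
        more_variable = ifelse(degenerate, NA_character_,
                               ifelse(ratio > 1, levels(groups)[1],
                                      levels(groups)[2])),
        significant = !degenerate & pBonf < alpha,
        degenerate = degenerate,
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Multivariate linear model of methylation on clinical covariates
#'
#' Ordinary least squares of each sequence's methylation on a shared design
#' matrix built from the given clinical covariates (factors are
#' treatment-coded). One QR decomposition of the design is reused for all
#' sequences; the overall-model F test is Bonferroni-adjusted across
#' sequences.
#'
#' @param x a [MethylExperiment-class] (tumor samples are used).
#' @param clinical clinical data.frame.
#' @param covariates non-empty character vector of clinical column names.
#' @param alpha family-wise level (default 0.01).
#' @return list: `table` (data.frame with `sequence_id`, `f_statistic`, `p`,
#'   `p_bonf`, `significant`), `coefficients` (sequence x term matrix),
#'   `design` (the model matrix).
#' @export
multivariateLm <- function(x, clinical, covariates, alpha = 0.01) {
    stopifnot(is(x, "MethylExperiment"))
    if (length(covariates) == 0)
        stop("covariates must be a non-empty set of clinical column names")
    missing <- setdiff(covariates, names(clinical))
    if (length(missing))
        stop("unknown clinical columns: ", paste(missing, collapse = ", "))
    tum <- clinical[clinical$group == "tumor", , drop = FALSE]
    ids <- intersect(tum$sample_id, colnames(x))
    tum <- tum[match(ids, tum$sample_id), , drop = FALSE]
    X <- stats::model.matrix(~ ., data = tum[, covariates, drop = FALSE])
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
        stop("design matrix is rank deficient; collinear columns: ",
             paste(bad, collapse = ", "))
    }
    n <- nrow(X); pTerms <- ncol(X)
    if (n <= pTerms) stop("more model terms than samples")
    Y <- t(assay(x, "meth")[, ids, drop = FALSE])
    res <- qr.resid(qrX, Y)
    rss1 <- colSums(res^2)
    rss0 <- colSums(scale(Y, center = TRUE, scale = FALSE)^2)
    fstat <- ((rss0 - rss1) / (pTerms - 1)) / (rss1 / (n - pTerms))
    p <- stats::pf(fstat, pTerms - 1, n - pTerms, lower.tail = FALSE)
    pBonf <- bonferroni(p)
    coefs <- t(qr.coef(qrX, Y))
    list(
        table = data.frame(sequence_id = colnames(Y),
                           f_statistic = fstat, p = p, p_bonf = pBonf,
                           significant = pBonf < alpha,
                           stringsAsFactors = FALSE, row.names = NULL),
        coefficients = coefs,
        design = X)
}

#' Genomic-location enrichment of differentially methylated sequences
#'
#' Per location category, a 2x2 Fisher's exact test of membership in the
#' category against significance in the requested direction, over the
#' background of all tested sequences. Multi-label sequences count once in
#' every category they overlap. Bonferroni adjustment is across the tested
#' categories.
#'
#' @param dmr a [mwwDmrTest()] result.
#' @param annotation [GenomicRanges::GRanges] named by sequence id with a
#'   `locations` CharacterList column, covering all tested sequences.
#' @param direction `"hyper"` or `"hypo"`.
#' @param alpha family-wise level (default 0.01).
#' @return data.frame per category: counts, `odds_ratio`, `p`, `p_bonf`,
#'   `significant`.
#' @export
locationEnrichment <- function(dmr, annotation, direction = c("hyper", "hypo"),
                               alpha = 0.01) {
    direction <- match.arg(direction)
    missing <- setdiff(dmr$sequence_id, names(annotation))
    if (length(missing))
        stop("annotation missing for ", length(missing), " tested sequences")
    locs <- annotation[dmr$sequence_id]$locations
    sig <- dmr$significant & !is.na(dmr$direction) & dmr$direction == direction
    ul <- unlist(locs, use.names = FALSE)
    ridx <- rep(seq_along(locs), lengths(locs))
    cats <- sort(unique(ul))
    rows <- lapply(cats, function(cat) {
        inCat <- logical(length(locs))
        inCat[ridx[ul == cat]] <- TRUE
        a <- sum(inCat & sig); b <- sum(inCat & !sig)
        c_ <- sum(!inCat & sig); d <- sum(!inCat & !sig)
        if (a + b == 0) {
            warning("empty location category skipped: ", cat)
            return(NULL)
        }
        ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
        data.frame(location = cat, in_cat_sig = a, in_cat_other = b,
                   out_cat_sig = c_, out_cat_other = d,
                   odds_ratio = unname(ft$estimate), p = ft$p.value,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_bonf <- bonferroni(out$p)
    out$significant <- out$p_bonf < alpha
    out
}

#' Fisher's exact test on dichotomized beta values
#'
#' Each sequence's beta values are classified as methylated (beta >= 0.5) or
#' unmethylated (beta < 0.5); the resulting group x category 2x2 table is
#' tested by Fisher's exact test (two-sided, "minlike" convention of
#' [stats::fisher.test]), Bonferroni-adjusted across sequences. Identical 2x2
#' tables are computed once and reused.
#'
#' @param x a [MethylExperiment-class] on the beta scale (log2 ratios are
#'   converted internally).
#' @param alpha family-wise level (default 0.01).
#' @param threshold beta dichotomization threshold (default 0.5).
#' @return data.frame: per-sequence 2x2 counts, `odds_ratio`, `p`, `p_bonf`,
#'   `direction` (`"hyper"` when tumors are more often methylated),
#'   `significant`.
#' @export
betaCategoryFisher <- function(x, alpha = 0.01, threshold = 0.5) {
    stopifnot(is(x, "MethylExperiment"))
    g <- .assertGroups(x)
    m <- assay(x, "meth")
    beta <- if (identical(metadata(x)$scale, "beta")) m else .beta(m)
    methylated <- beta >= threshold
    nT <- sum(g == "tumor"); nC <- sum(g == "control")
    a <- rowSums(methylated[, g == "tumor", drop = FALSE])
    c_ <- rowSums(methylated[, g == "control", drop = FALSE])
    key <- paste(a, c_)
    uniq <- !duplicated(key)
    pv <- orv <- numeric(sum(uniq))
    names(pv) <- names(orv) <- key[uniq]
    for (k in which(uniq)) {
        tab <- matrix(c(a[k], nT - a[k], c_[k], nC - c_[k]), 2, byrow = TRUE)
        ft <- stats::fisher.test(tab)
        pv[key[k]] <- ft$p.value
        orv[key[k]] <- unname(ft$estimate)
    }
    p <- unname(pv[key]); orr <- unname(orv[key])
    pBonf <- bonferroni(p)
    fracDiff <- a / nT - c_ / nC
    data.frame(
        sequence_id = rownames(m),
        tumor_meth = a, tumor_unmeth = nT - a,
        control_meth = c_, control_unmeth = nC - c_,
        odds_ratio = orr, p = p, p_bonf = pBonf,
        direction = ifelse(fracDiff > 0, "hyper",
                           ifelse(fracDiff < 0, "hypo", NA_character_)),
        significant = pBonf < alpha,
        stringsAsFactors = FALSE, row.names = NULL)
}
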