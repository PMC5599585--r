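## Small numeric helpers shared across modules.

# trapezoidal rule on an ordered grid
.trapz <- function(y, x) {
    n <- length(x)
    sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Bonferroni family-wise adjustment
#'
#' Thin wrapper over [stats::p.adjust] with `method = "bonferroni"`; the
#' number of tests defaults to the number of p-values supplied (the tested
#' set, not the array design size).
#'
#' @param p numeric vector of raw p-values.
#' @param n number of tests in the family.
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, n = length(p)) {
    stats::p.adjust(p, method = "bonferroni", n = n)
}

# deterministic per-stage seed derived from one root seed; stays < 2^31
.stageSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# group index helpers
.tumorIdx <- function(x) which(sampleGroups(x) == "tumor")
.controlIdx <- function(x) which(sampleGroups(x) == "control")

.assertGroups <- function(x) {
    g <- sampleGroups(x)
    if (!any(g == "tumor") || !any(g == "control"))
        stop("both tumor and control samples are required")
    invisible(g)
}
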