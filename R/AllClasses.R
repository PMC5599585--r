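#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData assay<-
NULL

#' Probe-level two-color array container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding probe-level data from
#' two-color methylation-enrichment arrays. Two assays are required: `"M"`, the
#' log2 ratio of the methylation-enriched channel over the input channel, and
#' `"A"`, the mean log2 spot intensity used for dye-bias correction. `rowData`
#' carries the probe-to-target map (`sequence_id`); `colData` carries the
#' sample `group` (`"tumor"` or `"control"`).
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment]
#' @export
setClass("ProbeSet", contains = "SummarizedExperiment")

setValidity("ProbeSet", function(object) {
    msg <- NULL
    if (!all(c("M", "A") %in% names(assays(object))))
        msg <- c(msg, "assays must contain 'M' (log2 ratio) and 'A' (mean intensity)")
    if (!"sequence_id" %in% names(rowData(object)))
        msg <- c(msg, "rowData must contain 'sequence_id'")
    if (!"group" %in% names(colData(object)))
        msg <- c(msg, "colData must contain 'group'")
    else if (!all(object$group %in% c("tumor", "control")))
        msg <- c(msg, "group must be 'tumor' or 'control'")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated sample names")
    if (is.null(msg)) TRUE else msg
})

#' Construct a ProbeSet
#'
#' @param M numeric matrix of log2 ratios (probes x samples).
#' @param A numeric matrix of mean log2 intensities, same dimensions as `M`.
#' @param sequenceId character vector mapping each probe (row) to its target
#'   sequence (CpG region or CDS).
#' @param group character vector per sample, `"tumor"` or `"control"`.
#' @param ... further arguments passed to
#'   [SummarizedExperiment::SummarizedExperiment] (e.g. `colData`).
#' @return A [ProbeSet-class] object.
#' @export
ProbeSet <- function(M, A, sequenceId, group, ...) {
    se <- SummarizedExperiment(
        assays  = SimpleList(M = M, A = A),
        rowData = DataFrame(sequence_id = sequenceId),
        ...
    )
    se$group <- group
    new("ProbeSet", se)
}

#' Sequence-level methylation container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a sequence x sample
#' methylation matrix (assay `"meth"`). `rowData$sequence_class` distinguishes
#' CpG regions from CDS targets; `colData$group` labels tumors and controls.
#' `metadata()` tracks provenance: `scale` (`"log2ratio"`, `"beta"` or
#' `"change"`), `normalized` and `filtered` flags.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment]
#' @export
setClass("MethylExperiment", contains = "SummarizedExperiment")

setValidity("MethylExperiment", function(object) {
    msg <- NULL
    if (!"meth" %in% names(assays(object)))
        msg <- c(msg, "assays must contain 'meth'")
    if (!"group" %in% names(colData(object)))
        msg <- c(msg, "colData must contain 'group'")
    else if (!all(object$group %in% c("tumor", "control")))
        msg <- c(msg, "group must be 'tumor' or 'control'")
    if (is.null(rownames(object)))
        msg <- c(msg, "sequence identifiers (rownames) are required")
    if (is.null(msg)) TRUE else msg
})

#' Construct a MethylExperiment
#'
#' @param meth numeric matrix, sequences x samples, with rownames.
#' @param group character vector per sample (`"tumor"`/`"control"`).
#' @param sequenceClass optional character vector per sequence
#'   (`"CpG"`/`"CDS"`).
#' @param scale character scalar recording the value scale.
#' @param ... passed to [SummarizedExperiment::SummarizedExperiment].
#' @return A [MethylExperiment-class].
#' @export
MethylExperiment <- function(meth, group,
                             sequenceClass = NULL,
                             scale = "log2ratio", ...) {
    rd <- if (is.null(sequenceClass)) NULL else DataFrame(sequence_class = sequenceClass)
    se <- SummarizedExperiment(assays = SimpleList(meth = meth), rowData = rd, ...)
    se$group <- group
    me <- new("MethylExperiment", se)
    metadata(me)$scale <- scale
    metadata(me)$normalized <- FALSE
    metadata(me)$filtered <- FALSE
    me
}

#' Methylation variability profiles (MVPs)
#'
#' Per-sample kernel density curves of differential methylation (sample minus
#' control-median reference) evaluated on one shared grid. Each column of
#' `density` integrates to 1 (trapezoidal rule) over `grid`.
#'
#' @slot grid ordered numeric evaluation grid, shared by all profiles.
#' @slot density non-negative matrix, `length(grid)` rows, one column per
#'   sample.
#' @slot group character per sample, `"tumor"` or `"control"`.
#' @slot bw numeric per-sample kernel bandwidths used.
#' @export
setClass("MVProfileSet",
    slots = c(grid = "numeric", density = "matrix",
              group = "character", bw = "numeric"))

setValidity("MVProfileSet", function(object) {
    msg <- NULL
    if (is.unsorted(object@grid, strictly = TRUE))
        msg <- c(msg, "grid must be strictly increasing")
    if (nrow(object@density) != length(object@grid))
        msg <- c(msg, "density rows must match grid length")
    if (ncol(object@density) != length(object@group))
        msg <- c(msg, "one group label per profile required")
    if (any(object@density < 0))
        msg <- c(msg, "densities must be non-negative")
    ints <- apply(object@density, 2, .trapz, x = object@grid)
    if (any(abs(ints - 1) > 1e-6))
        msg <- c(msg, "each profile must integrate to 1 (+/- 1e-6) over the grid")
    if (is.null(msg)) TRUE else msg
})

#' Hierarchical clustering assignment
#'
#' @slot cluster named integer vector, sample -> cluster id.
#' @slot k number of clusters.
#' @slot method linkage criterion used.
#' @slot distance distance used.
#' @slot sequenceIds identifiers of the sequences the clustering was computed
#'   on.
#' @slot tree the underlying `hclust` object.
#' @export
setClass("ClusterAssignment",
    slots = c(cluster = "integer", k = "integer", method = "character",
              distance = "character", sequenceIds = "character", tree = "ANY"))

setValidity("ClusterAssignment", function(object) {
    msg <- NULL
    if (is.null(names(object@cluster)))
        msg <- c(msg, "cluster assignment must be named by sample")
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    if (length(unique(object@cluster)) > object@k)
        msg <- c(msg, "more distinct clusters than k")
    if (is.null(msg)) TRUE else msg
})

#' Consensus clustering result
#'
#' Co-assignment frequencies from repeated clustering over random sample
#' subsets: entry (i, j) is the fraction of subsamples containing both i and j
#' in which they landed in the same cluster (0 = never, 1 = always).
#'
#' @slot consensus symmetric sample x sample matrix in \[0, 1\], unit diagonal.
#' @slot assignment final cluster assignment obtained from the consensus
#'   matrix.
#' @slot k cluster count.
#' @slot subsetSize number of top-variability sequences used.
#' @slot nResamples number of subsampling iterations.
#' @slot sampleFraction fraction of samples drawn per iteration.
#' @export
setClass("ConsensusResult",
    slots = c(consensus = "matrix", assignment = "integer", k = "integer",
              subsetSize = "integer", nResamples = "integer",
              sampleFraction = "numeric"))

setValidity("ConsensusResult", function(object) {
    cm <- object@consensus
    msg <- NULL
    if (nrow(cm) != ncol(cm) || !isTRUE(all.equal(cm, t(cm), tolerance = 1e-12)))
        msg <- c(msg, "consensus matrix must be symmetric")
    if (any(cm < 0 | cm > 1, na.rm = TRUE))
        msg <- c(msg, "consensus entries must lie in [0, 1]")
    if (any(abs(diag(cm) - 1) > 1e-12))
        msg <- c(msg, "consensus diagonal must equal 1")
    if (length(object@assignment) != nrow(cm))
        msg <- c(msg, "one final assignment per sample required")
    if (is.null(msg)) TRUE else msg
})

## ---- accessors ------------------------------------------------------------

#' Sample group labels
#' @param x a ProbeSet, MethylExperiment or MVProfileSet.
#' @return character vector of `"tumor"`/`"control"` labels.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "SummarizedExperiment", function(x) {
    setNames(as.character(x$group), colnames(x))
})

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "MVProfileSet", function(x) {
    setNames(x@group, colnames(x@density))
})

#' Sequence class (CpG / CDS) per sequence
#' @param x a MethylExperiment.
#' @return named character vector, or NULL when no class annotation is present.
#' @export
setGeneric("sequenceClass", function(x) standardGeneric("sequenceClass"))

#' @rdname sequenceClass
#' @export
setMethod("sequenceClass", "MethylExperiment", function(x) {
    if (!"sequence_class" %in% names(rowData(x))) return(NULL)
    setNames(as.character(rowData(x)$sequence_class), rownames(x))
})

#' MVP evaluation grid
#' @param x an MVProfileSet.
#' @export
setGeneric("mvpGrid", function(x) standardGeneric("mvpGrid"))
#' @rdname mvpGrid
#' @export
setMethod("mvpGrid", "MVProfileSet", function(x) x@grid)

#' MVP density matrix (grid x samples)
#' @param x an MVProfileSet.
#' @export
setGeneric("mvpDensity", function(x) standardGeneric("mvpDensity"))
#' @rdname mvpDensity
#' @export
setMethod("mvpDensity", "MVProfileSet", function(x) x@density)

#' Cluster membership
#' @param x a ClusterAssignment or ConsensusResult.
#' @return named integer vector, sample -> cluster id.
#' @export
setGeneric("clusterAssignment", function(x) standardGeneric("clusterAssignment"))
#' @rdname clusterAssignment
#' @export
setMethod("clusterAssignment", "ClusterAssignment", function(x) x@cluster)
#' @rdname clusterAssignment
#' @export
setMethod("clusterAssignment", "ConsensusResult", function(x) x@assignment)

#' Consensus co-assignment matrix
#' @param x a ConsensusResult.
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))
#' @rdname consensusMatrix
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x) x@consensus)

## ---- show methods ---------------------------------------------------------

setMethod("show", "MVProfileSet", function(object) {
    cat("MVProfileSet with", ncol(object@density), "profiles (",
        sum(object@group == "tumor"), "tumor /",
        sum(object@group == "control"), "control )\n")
    cat("  grid:", length(object@grid), "points on [",
        format(min(object@grid), digits = 3), ",",
        format(max(object@grid), digits = 3), "]\n")
})

setMethod("show", "ClusterAssignment", function(object) {
    cat("ClusterAssignment:", length(object@cluster), "samples in",
        object@k, "clusters (", object@method, "linkage,",
        object@distance, "distance )\n")
    print(table(cluster = object@cluster))
})

setMethod("show", "ConsensusResult", function(object) {
    cat("ConsensusResult: k =", object@k, ", subset size =", object@subsetSize,
        ",", object@nResamples, "resamples at fraction",
        object@sampleFraction, "\n")
    print(table(cluster = object@assignment))
})
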