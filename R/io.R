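## Readers and writers for the plain-text artifact formats, fixture
## persistence for the simulator, and end-to-end pipeline orchestration.
## All tables are TSV; lines starting with '#' are provenance comments.
## Genomic coordinates are 1-based inclusive everywhere inside the package;
## conversion to 0-based half-open happens only in the BED writer.

.readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop("empty data section in ", path)
    df
}

.writeTsv <- function(df, path, header = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.requireCols <- function(df, cols, path) {
    missing <- setdiff(cols, names(df))
    if (length(missing))
        stop("missing required column(s) in ", path, ": ",
             paste(missing, collapse = ", "))
}

.numericMatrix <- function(df, idCol, path) {
    num <- df[, setdiff(names(df), idCol), drop = FALSE]
    m <- as.matrix(num)
    if (!is.numeric(m)) {
        badCol <- names(num)[!vapply(num, is.numeric, logical(1))][1]
        badRow <- which(is.na(suppressWarnings(as.numeric(num[[badCol]]))))[1]
        stop("non-numeric cell in ", path, ", column '", badCol,
             "', data row ", badRow)
    }
    rownames(m) <- df[[idCol]]
    m
}

#' Read a probe-level table into a ProbeSet
#'
#' @param probesPath TSV with `probe_id`, `sequence_id` and one log2-ratio
#'   column per sample.
#' @param intensitiesPath TSV with `probe_id` and one mean-intensity column
#'   per sample (same samples).
#' @param samplesPath sample sheet TSV with `sample_id` and `group`.
#' @return a [ProbeSet-class].
#' @export
readProbeTable <- function(probesPath, intensitiesPath, samplesPath) {
    pr <- .readTsv(probesPath)
    .requireCols(pr, c("probe_id", "sequence_id"), probesPath)
    if (anyDuplicated(pr$probe_id))
        stop("duplicated probe_id in ", probesPath, ": ",
             pr$probe_id[duplicated(pr$probe_id)][1])
    M <- .numericMatrix(pr[, setdiff(names(pr), "sequence_id")],
                        "probe_id", probesPath)
    it <- .readTsv(intensitiesPath)
    .requireCols(it, "probe_id", intensitiesPath)
    A <- .numericMatrix(it, "probe_id", intensitiesPath)
    if (!identical(dim(M), dim(A)) ||
        !identical(rownames(M), rownames(A)) ||
        !identical(colnames(M), colnames(A)))
        stop("probe and intensity tables disagree in probes or samples")
    ss <- readClinical(samplesPath)
    idx <- match(colnames(M), ss$sample_id)
    if (anyNA(idx))
        stop("sample sheet lacks samples: ",
             paste(colnames(M)[is.na(idx)], collapse = ", "))
    ProbeSet(M, A, sequenceId = pr$sequence_id, group = ss$group[idx])
}

#' Write a ProbeSet to probe/intensity TSV files
#' @param probes a [ProbeSet-class].
#' @param probesPath,intensitiesPath output paths.
#' @param header optional provenance comment.
#' @export
writeProbeTable <- function(probes, probesPath, intensitiesPath,
                            header = NULL) {
    M <- assay(probes, "M")
    .writeTsv(data.frame(probe_id = rownames(M),
                         sequence_id = rowData(probes)$sequence_id,
                         M, check.names = FALSE),
              probesPath, header)
    A <- assay(probes, "A")
    .writeTsv(data.frame(probe_id = rownames(A), A, check.names = FALSE),
              intensitiesPath, header)
    invisible(c(probesPath, intensitiesPath))
}

#' Read / write a sequence x sample methylation matrix
#'
#' @param path TSV with `sequence_id` then one column per sample; an
#'   optional `sequence_class` column is honored.
#' @param samplesPath sample sheet TSV supplying the group labels.
#' @return a [MethylExperiment-class].
#' @export
readMethylMatrix <- function(path, samplesPath) {
    df <- .readTsv(path)
    .requireCols(df, "sequence_id", path)
    if (anyDuplicated(df$sequence_id))
        stop("duplicated sequence_id in ", path, ": ",
             df$sequence_id[duplicated(df$sequence_id)][1])
    cls <- NULL
    if ("sequence_class" %in% names(df)) {
        cls <- df$sequence_class
        df$sequence_class <- NULL
    }
    m <- .numericMatrix(df, "sequence_id", path)
    ss <- readClinical(samplesPath)
    idx <- match(colnames(m), ss$sample_id)
    if (anyNA(idx))
        stop("sample sheet lacks samples: ",
             paste(colnames(m)[is.na(idx)], collapse = ", "))
    MethylExperiment(m, group = ss$group[idx], sequenceClass = cls)
}

#' @rdname readMethylMatrix
#' @param x a [MethylExperiment-class].
#' @param header optional provenance comment.
#' @export
writeMethylMatrix <- function(x, path, header = NULL) {
    m <- assay(x, "meth")
    df <- data.frame(sequence_id = rownames(m), check.names = FALSE)
    cls <- sequenceClass(x)
    if (!is.null(cls)) df$sequence_class <- unname(cls)
    .writeTsv(cbind(df, m), path, header)
    invisible(path)
}

#' Read / write per-sequence genomic annotation
#'
#' TSV columns: `sequence_id`, `chrom`, `start`, `end` (1-based inclusive),
#' `sequence_class`, `locations` (comma-separated multi-label),
#' `gene_symbol` (empty allowed).
#'
#' @param path annotation TSV.
#' @return a [GenomicRanges::GRanges] named by sequence id.
#' @export
readAnnotation <- function(path) {
    df <- .readTsv(path)
    .requireCols(df, c("sequence_id", "chrom", "start", "end",
                       "sequence_class", "locations"), path)
    if (anyDuplicated(df$sequence_id))
        stop("duplicated sequence_id in ", path, ": ",
             df$sequence_id[duplicated(df$sequence_id)][1])
    bad <- which(df$start > df$end)
    if (length(bad))
        stop("start > end at data row ", bad[1], " in ", path)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end))
    names(gr) <- df$sequence_id
    gr$sequence_class <- df$sequence_class
    gr$locations <- IRanges::CharacterList(strsplit(df$locations, ","))
    if (any(lengths(gr$locations) == 0))
        stop("empty locations at data row ",
             which(lengths(gr$locations) == 0)[1], " in ", path)
    gr$gene_symbol <- if ("gene_symbol" %in% names(df)) {
        gs <- df$gene_symbol; gs[gs %in% c("", "NA")] <- NA_character_; gs
    } else NA_character_
    gr
}

#' @rdname readAnnotation
#' @param annotation a [GenomicRanges::GRanges] as produced by
#'   [simulateMethylArray()].
#' @param header optional provenance comment.
#' @export
writeAnnotation <- function(annotation, path, header = NULL) {
    df <- data.frame(
        sequence_id = names(annotation),
        chrom = as.character(GenomicRanges::seqnames(annotation)),
        start = GenomicRanges::start(annotation),
        end = GenomicRanges::end(annotation),
        sequence_class = annotation$sequence_class,
        locations = vapply(annotation$locations, paste,
                           character(1), collapse = ","),
        gene_symbol = ifelse(is.na(annotation$gene_symbol), "",
                             annotation$gene_symbol),
        stringsAsFactors = FALSE)
    .writeTsv(df, path, header)
    invisible(path)
}

#' Read / write the clinical / sample-sheet table
#' @param path TSV with at least `sample_id` and `group`.
#' @return data.frame.
#' @export
readClinical <- function(path) {
    df <- .readTsv(path)
    .requireCols(df, c("sample_id", "group"), path)
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id in ", path, ": ",
             df$sample_id[duplicated(df$sample_id)][1])
    if (!all(df$group %in% c("tumor", "control")))
        stop("group must be 'tumor' or 'control' in ", path)
    for (col in c("ttp_event", "lss_event"))
        if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
    df
}

#' @rdname readClinical
#' @param clinical data.frame.
#' @param header optional provenance comment.
#' @export
writeClinical <- function(clinical, path, header = NULL) {
    .writeTsv(clinical, path, header)
    invisible(path)
}

#' Export significant sequences as BED6
#'
#' Conversion to 0-based half-open happens here, at the writer boundary.
#' Score is -10 log10 of the Bonferroni-adjusted p, capped at 1000; strand
#' is `.`.
#'
#' @param dmr a [mwwDmrTest()] result.
#' @param annotation [GenomicRanges::GRanges] named by sequence id.
#' @param path output BED path.
#' @param direction optional `"hyper"`/`"hypo"` restriction.
#' @export
writeDmrBed <- function(dmr, annotation, path, direction = NULL) {
    sel <- dmr[dmr$significant, , drop = FALSE]
    if (!is.null(direction)) sel <- sel[sel$direction %in% direction, ]
    gr <- annotation[sel$sequence_id]
    score <- round(pmin(1000, -10 * log10(pmax(sel$p_bonf, 1e-300))))
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,   # 0-based half-open
        end = GenomicRanges::end(gr),
        name = sel$sequence_id,
        score = score,
        strand = ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Persist a simulated experiment as plain-text fixtures
#'
#' Writes probes.tsv, intensities.tsv, annotation.tsv, clinical.tsv and
#' truth.json; the tables round-trip losslessly through the readers.
#'
#' @param sim a `MethylSimulation` from [simulateMethylArray()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of written paths.
#' @export
writeFixtures <- function(sim, dir) {
    stopifnot(inherits(sim, "MethylSimulation"))
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create directory: ", dir)
    paths <- c(probes = file.path(dir, "probes.tsv"),
               intensities = file.path(dir, "intensities.tsv"),
               annotation = file.path(dir, "annotation.tsv"),
               clinical = file.path(dir, "clinical.tsv"),
               truth = file.path(dir, "truth.json"))
    hdr <- paste0("methdisrupt fixtures seed=", sim$config$seed)
    writeProbeTable(sim$probes, paths["probes"], paths["intensities"],
                    header = hdr)
    writeAnnotation(sim$annotation, paths["annotation"], header = hdr)
    writeClinical(sim$clinical, paths["clinical"], header = hdr)
    truth <- sim$truth
    jsonlite::write_json(
        list(hyperIds = truth$hyperIds, hypoIds = truth$hypoIds,
             subgroup = as.list(truth$subgroup),
             signatureMap = truth$signatureMap,
             disruption = as.list(truth$disruption),
             disruptionProneIds = truth$disruptionProneIds),
        paths["truth"], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}

#' Reload fixtures written by [writeFixtures()]
#' @param dir fixture directory.
#' @return list with `probes`, `annotation`, `clinical`, `truth`.
#' @export
readFixtures <- function(dir) {
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    truth$hyperIds <- as.character(truth$hyperIds)
    truth$hypoIds <- as.character(truth$hypoIds)
    truth$subgroup <- unlist(truth$subgroup)
    truth$disruption <- unlist(truth$disruption)
    truth$disruptionProneIds <- as.character(truth$disruptionProneIds)
    list(probes = readProbeTable(file.path(dir, "probes.tsv"),
                                 file.path(dir, "intensities.tsv"),
                                 file.path(dir, "clinical.tsv")),
         annotation = readAnnotation(file.path(dir, "annotation.tsv")),
         clinical = readClinical(file.path(dir, "clinical.tsv")),
         truth = truth)
}

#' Pipeline configuration
#'
#' Collects every stage parameter plus the root seed. Each stage derives a
#' named substream seed from the root so stages are individually
#' reproducible. Serializes to/from YAML.
#'
#' @param probesPath,intensitiesPath,clinicalPath,annotationPath input files
#'   (all `NULL` to run on a fresh simulation).
#' @param span loess span; `enrichThreshold`, `minFraction` the enrichment
#'   filter; `alpha` the family-wise level; `corrThreshold`, `nComponents`,
#'   `k` the stratification parameters; `subsetSizes`, `nResamples`,
#'   `sampleFraction` the consensus parameters; `endpoint`, `lssCutoff` the
#'   survival read-outs.
#' @param enrichThreshold,minFraction,alpha,corrThreshold,nComponents,k
#'   see above.
#' @param subsetSizes,nResamples,sampleFraction,endpoint,lssCutoff see above.
#' @param seed root seed.
#' @param outDir output directory.
#' @param verbose print stage progress.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(probesPath = NULL, intensitiesPath = NULL,
                           clinicalPath = NULL, annotationPath = NULL,
                           span = 0.3, enrichThreshold = 0.5,
                           minFraction = 0.25, alpha = 0.01,
                           corrThreshold = 0.85, nComponents = 2, k = 3,
                           subsetSizes = c(250, 500, 1000, 2000),
                           nResamples = 1000, sampleFraction = 0.8,
                           endpoint = "LSS", lssCutoff = 180,
                           seed = 1L, outDir = "methdisrupt-results",
                           verbose = TRUE) {
    stopifnot(span > 0, span <= 1,
              enrichThreshold > 0, enrichThreshold < 1,
              minFraction >= 0, minFraction <= 1,
              alpha > 0, alpha < 1,
              corrThreshold > 0, corrThreshold < 1,
              nComponents >= 1, k >= 2,
              all(subsetSizes >= 2), nResamples >= 1,
              sampleFraction > 0, sampleFraction <= 1,
              endpoint %in% c("LSS", "TTP"))
    structure(as.list(environment()), class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file with `pipelineConfig()` fields.
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(pipelineConfig, vals)
}

.configHash <- function(config) {
    # hash only result-relevant fields: output location and verbosity do not
    # change the computation
    cfg <- config[setdiff(names(config), c("outDir", "verbose"))]
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], tmp)
    unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Orchestrates preprocess (loess dye correction, QC, quantile
#' normalization, probe-median aggregation, enrichment filter), differential
#' methylation, PCA/Ward stratification with survival read-out, and the
#' methylation-disruption stage (MVPs, MVS, consensus clustering,
#' disrupted-group flagging). Every output file carries a header comment
#' with the config hash and seed; outputs are deterministic given the seed.
#'
#' @param config a `PipelineConfig`; when no input paths are set, a
#'   simulation at the default small scale is generated with the config seed.
#' @param sim optional pre-built `MethylSimulation` overriding the input
#'   paths.
#' @return invisible list with every stage's result objects and the run log.
#' @export
runPipeline <- function(config = pipelineConfig(), sim = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    hash <- .configHash(config)
    hdr <- paste0("methdisrupt seed=", config$seed, " config=", hash)
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    log <- character(0)
    say <- function(...) {
        line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
        log <<- c(log, line)
        if (config$verbose) message(line)
    }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
    }

    ## -- inputs ------------------------------------------------------------
    if (is.null(sim) && is.null(config$probesPath)) {
        say("simulate: generating default-scale experiment, seed ", config$seed)
        sim <- simulateMethylArray(simConfig(seed = config$seed))
    }
    if (!is.null(sim)) {
        probes <- sim$probes; clinical <- sim$clinical
        annotation <- sim$annotation
    } else {
        say("read: ", config$probesPath)
        probes <- stage("read", readProbeTable(config$probesPath,
                                               config$intensitiesPath,
                                               config$clinicalPath))
        clinical <- stage("read", readClinical(config$clinicalPath))
        annotation <- if (is.null(config$annotationPath)) NULL
                      else stage("read", readAnnotation(config$annotationPath))
    }

    ## -- preprocess --------------------------------------------------------
    say("preprocess: ", nrow(probes), " probes x ", ncol(probes), " samples")
    probes <- stage("preprocess", loessDyeCorrect(probes, span = config$span))
    qc <- stage("preprocess", qcFilterArrays(probes))
    probes <- quantileNormalize(qc$probes)
    ms <- stage("preprocess", aggregateToSequences(probes, annotation))
    msF <- stage("preprocess",
                 filterLowMethylation(ms, config$enrichThreshold,
                                      config$minFraction))
    say("preprocess: retained ", nrow(msF), "/", nrow(ms), " sequences")
    writeMethylMatrix(msF, file.path(config$outDir, "matrix.tsv"), hdr)

    ## -- differential ------------------------------------------------------
    dmr <- stage("differential", mwwDmrTest(msF, alpha = config$alpha))
    say("differential: ", sum(dmr$significant), " DMRs (",
        sum(dmr$significant & dmr$direction == "hyper"), " hyper / ",
        sum(dmr$significant & dmr$direction == "hypo"), " hypo)")
    .writeTsv(dmr, file.path(config$outDir, "dmr.tsv"), hdr)
    enr <- NULL
    if (!is.null(annotation)) {
        enr <- lapply(c(hyper = "hyper", hypo = "hypo"), function(d)
            stage("differential",
                  suppressWarnings(locationEnrichment(dmr, annotation, d,
                                                      config$alpha))))
        .writeTsv(do.call(rbind, enr),
                  file.path(config$outDir, "location_enrichment.tsv"), hdr)
        writeDmrBed(dmr, annotation, file.path(config$outDir, "dmr.bed"))
    }

    ## -- stratify ----------------------------------------------------------
    sel <- stage("stratify", pcaSelectSequences(msF, config$corrThreshold,
                                                config$nComponents))
    say("stratify: ", length(sel$selected), " PC-correlated sequences")
    km <- NULL; clusters <- NULL; assoc <- NULL
    if (length(sel$selected) >= 2) {
        clusters <- stage("stratify",
                          wardCluster(msF, k = config$k,
                                      sequenceIds = sel$selected))
        .writeTsv(data.frame(sample_id = names(clusterAssignment(clusters)),
                             cluster = clusterAssignment(clusters)),
                  file.path(config$outDir, "clusters.tsv"), hdr)
        assoc <- tryCatch(
            suppressWarnings(clusterClinicalAssociation(clusters, clinical)),
            error = function(e) NULL)
        km <- stage("stratify", .bestWorstLogrank(clusters, clinical,
                                                  config$endpoint))
        if (!is.null(km))
            say("stratify: log-rank ", km$groups[1], " vs ", km$groups[2],
                " p = ", signif(km$p, 3))
    } else say("stratify: too few selected sequences, clustering skipped")

    ## -- disrupt -----------------------------------------------------------
    changes <- stage("disrupt", differentialMatrix(msF))
    profiles <- stage("disrupt", mvpProfiles(changes))
    mvs <- stage("disrupt", mvsScores(profiles))
    .writeTsv(data.frame(sample_id = names(mvs$scores), mvs = mvs$scores),
              file.path(config$outDir, "mvs.tsv"), hdr)
    .writeTsv(data.frame(grid = profiles@grid, profiles@density,
                         check.names = FALSE),
              file.path(config$outDir, "mvp_curves.tsv"), hdr)
    sizes <- config$subsetSizes[config$subsetSizes <= nrow(changes)]
    cons <- stage("disrupt",
                  consensusCluster(changes, subsetSizes = sizes,
                                   k = config$k,
                                   nResamples = config$nResamples,
                                   sampleFraction = config$sampleFraction,
                                   seed = .stageSeed(config$seed, "consensus")))
    for (s in names(cons))
        .writeTsv(data.frame(sample_id = rownames(consensusMatrix(cons[[s]])),
                             consensusMatrix(cons[[s]]), check.names = FALSE),
                  file.path(config$outDir, paste0("consensus_", s, ".tsv")),
                  hdr)
    disrupted <- tryCatch(
        flagDisruptedGroup(cons[[length(cons)]], mvs, clinical,
                           config$lssCutoff),
        error = function(e) { say("disrupt: flagging skipped: ",
                                  conditionMessage(e)); NULL })
    if (!is.null(disrupted))
        say("disrupt: cluster ", disrupted$cluster, " most disrupted, ",
            "short-LSS Fisher p = ", signif(disrupted$p, 3))

    writeLines(log, file.path(config$outDir, "run.log"))
    invisible(list(probes = probes, qc = qc$report, matrix = msF, dmr = dmr,
                   enrichment = enr, selection = sel, clusters = clusters,
                   association = assoc, km = km, changes = changes,
                   profiles = profiles, mvs = mvs, consensus = cons,
                   disrupted = disrupted, log = log, configHash = hash))
}

# survival read-out pair: clusters with the best and worst median LSS/TTP
# among clusters with >= 2 events (the pairing the study reports)
.bestWorstLogrank <- function(clusters, clinical, endpoint) {
    cl <- clusterAssignment(clusters)
    cols <- if (endpoint == "LSS") c("lss_days", "lss_event")
            else c("ttp_days", "ttp_event")
    idx <- match(names(cl), clinical$sample_id)
    time <- clinical[[cols[1]]][idx]
    event <- as.logical(clinical[[cols[2]]][idx])
    ok <- names(which(tapply(event, cl, sum, na.rm = TRUE) >= 2))
    if (length(ok) < 2) return(NULL)
    med <- tapply(time[event], cl[event], stats::median)[ok]
    pair <- as.integer(c(names(med)[which.max(med)],
                         names(med)[which.min(med)]))
    if (pair[1] == pair[2]) return(NULL)
    kmLogrank(cl, clinical, endpoint, groups = pair)
}
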