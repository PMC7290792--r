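#' @include AllClasses.R genome-io.R peak-ops.R pairing.R tss-profile.R
#' @include annotation.R cooccurrence.R enrichment.R
NULL

#' PipelineConfig: inputs and parameters of the co-occupancy pipeline
#'
#' Paths to the input files plus every tunable of the analysis. Defaults
#' are the standard analysis parameters: top 20,000 query peaks by score,
#' 1000 bp maximum summit distance, 100 bp close-pair threshold, 5 kb
#' promoter / 25 kb far windows, ORA with minimum overlap 3 and p < 0.01.
#'
#' @export
setClass("PipelineConfig",
         representation(peaksA = "character", peaksB = "character",
                        chromSizes = "character", blacklist = "character",
                        geneModels = "character", geneSets = "character",
                        peakFormat = "character", geneModelFormat = "character",
                        topN = "numeric", topNSubject = "numericOrNULL",
                        maxPairDist = "numeric", closePairThreshold = "numeric",
                        binWidth = "numeric", maWindow = "numeric",
                        annotation = "AnnotationParams",
                        minOverlap = "numeric", pCutoff = "numeric",
                        permutations = "numeric", seed = "numeric",
                        outputDir = "character"))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    if (object@topN <= 0 || object@maxPairDist <= 0 ||
        object@closePairThreshold <= 0)
        msg <- c(msg, "thresholds must be positive")
    if (object@closePairThreshold > object@maxPairDist)
        msg <- c(msg, "closePairThreshold must be <= maxPairDist")
    if (length(msg)) msg else TRUE
})

#' @param peaksA,peaksB peak files (query and subject factor).
#' @param chromSizes chromosome-sizes TSV.
#' @param blacklist optional blacklist BED (`NA` to skip).
#' @param geneModels optional gene-model file (`NA` to skip TSS profiling,
#'   annotation and gene selection).
#' @param geneSets optional GMT file (`NA` to skip ORA).
#' @param peakFormat `"narrowPeak"` or `"bed"`.
#' @param geneModelFormat `"bed12"` or `"tsv"`.
#' @param topN peaks kept from the query set (by score; default 20000).
#' @param topNSubject peaks kept from the subject set (`NULL` = all).
#' @param maxPairDist summit-distance cutoff for pairing (bp).
#' @param closePairThreshold strict threshold for the close-pair fraction
#'   and the regulatory-gene filter (bp).
#' @param binWidth histogram bin width (bp).
#' @param maWindow moving-average window (bp).
#' @param annotation an [annotationParams()].
#' @param minOverlap,pCutoff ORA filters.
#' @param permutations Forbes permutation count (0 = no permutation test).
#' @param seed integer seed for any randomized step.
#' @param outputDir directory for the TSV/JSON outputs.
#' @return a `PipelineConfig`.
#' @rdname PipelineConfig-class
#' @export
pipelineConfig <- function(peaksA, peaksB, chromSizes,
                           blacklist = NA_character_,
                           geneModels = NA_character_,
                           geneSets = NA_character_,
                           peakFormat = "narrowPeak",
                           geneModelFormat = "bed12",
                           topN = 20000, topNSubject = NULL,
                           maxPairDist = 1000, closePairThreshold = 100,
                           binWidth = 50, maWindow = 100,
                           annotation = annotationParams(),
                           minOverlap = 3, pCutoff = 0.01,
                           permutations = 0, seed = 1,
                           outputDir = tempfile("cooccupancy_")) {
    obj <- new("PipelineConfig", peaksA = peaksA, peaksB = peaksB,
               chromSizes = chromSizes, blacklist = blacklist,
               geneModels = geneModels, geneSets = geneSets,
               peakFormat = peakFormat, geneModelFormat = geneModelFormat,
               topN = topN, topNSubject = topNSubject,
               maxPairDist = maxPairDist,
               closePairThreshold = closePairThreshold,
               binWidth = binWidth, maWindow = maWindow,
               annotation = annotation, minOverlap = minOverlap,
               pCutoff = pCutoff, permutations = permutations, seed = seed,
               outputDir = outputDir)
    validObject(obj)
    obj
}

.writeTsv <- function(df, path, comment = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comment))
        writeLines(paste0("# ", comment), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full co-occupancy analysis
#'
#' Executes the pipeline end to end: read inputs, remove blacklisted
#' peaks, keep the top-N query peaks by score, pair nearest summits,
#' profile distances to TSS, assign genomic elements, map pairs to genes,
#' select promoter-proximal regulated genes, compute the Forbes
#' co-occurrence of the two coverage tracks, and (when gene sets are
#' given) run pathway over-representation on the selected genes. Every
#' intermediate is written as TSV under `config@outputDir` (coordinates in
#' output tables are 0-based half-open, stated in a header comment) plus a
#' JSON run log recording parameters and the per-stage counts. Reruns with
#' the same config and seed produce byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) a list with all in-memory results: `pairs`,
#'   `histogram`, `closePairs`, `tssProfile`, `movingAverage`,
#'   `elementDistribution`, `geneTable`, `regulatoryGenes`, `forbes`,
#'   `ora`, `log`.
#' @export
runPipeline <- function(config) {
    stopifnot(is(config, "PipelineConfig"))
    dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
    counts <- list()
    genome <- .stage("read_genome", readChromSizes(config@chromSizes))
    blacklist <- if (!is.na(config@blacklist))
        .stage("read_blacklist", readRegions(config@blacklist, seqinfo = genome))
    else CoverageTrack()
    A <- .stage("read_peaks_A",
                readPeaks(config@peaksA, format = config@peakFormat,
                          seqinfo = genome))
    B <- .stage("read_peaks_B",
                readPeaks(config@peaksB, format = config@peakFormat,
                          seqinfo = genome))
    counts$peaks_in <- c(A = length(A), B = length(B))
    A <- .stage("filter_blacklist", filterBlacklist(A, blacklist))
    B <- .stage("filter_blacklist", filterBlacklist(B, blacklist))
    counts$after_blacklist <- c(A = length(A), B = length(B))
    A <- .stage("top_n", topNByScore(A, config@topN))
    if (!is.null(config@topNSubject))
        B <- .stage("top_n", topNByScore(B, config@topNSubject))
    counts$after_top_n <- c(A = length(A), B = length(B))

    pairs <- .stage("pairing", nearestPairs(A, B, config@maxPairDist))
    counts$pairs <- length(pairs)
    hist <- distanceHistogram(pairs, config@binWidth)
    close <- .stage("close_pairs",
                    fractionWithin(pairs, config@closePairThreshold))
    counts$close_pairs <- close$count

    p <- as.data.frame(pairs)
    p$querySummit <- p$querySummit - 1L
    p$subjectSummit <- p$subjectSummit - 1L
    p$midpoint <- p$midpoint - 1L
    .writeTsv(p, file.path(config@outputDir, "pairs.tsv"),
              "coordinates: 0-based; distance: summit-to-summit bp")
    .writeTsv(hist, file.path(config@outputDir, "distance_histogram.tsv"),
              sprintf("half-open distance bins of width %g bp",
                      config@binWidth))
    .writeTsv(close, file.path(config@outputDir, "close_pairs.tsv"),
              sprintf("pairs with summit distance < %g bp",
                      config@closePairThreshold))

    tssProf <- maCurve <- elemDist <- geneTable <- NULL
    regGenes <- character()
    if (!is.na(config@geneModels)) {
        genes <- .stage("read_gene_models",
                        readGeneModels(config@geneModels,
                                       format = config@geneModelFormat,
                                       seqinfo = genome))
        tssProf <- .stage("tss_profile", nearestTssProfile(pairs, genes))
        maCurve <- movingAverageCurve(tssProf, config@maWindow)
        elemDist <- .stage("annotation",
                           elementDistribution(pairs, genes,
                                               config@annotation))
        geneTable <- .stage("gene_mapping",
                            mapPairsToGenes(pairs, genes, config@annotation))
        regGenes <- .stage("gene_selection", selectRegulatoryGenes(
            geneTable, pairDistanceCutoff = config@closePairThreshold))
        counts$genes <- length(regGenes)
        tp <- tssProf; tp$midpoint <- tp$midpoint - 1L
        .writeTsv(tp, file.path(config@outputDir, "tss_profile.tsv"),
                  "midpoint 0-based; tss_distance signed bp, upstream negative in gene orientation")
        .writeTsv(maCurve, file.path(config@outputDir, "moving_average.tsv"),
                  sprintf("centered %g bp window on the TSS-distance axis",
                          config@maWindow))
        .writeTsv(elemDist,
                  file.path(config@outputDir, "element_distribution.tsv"),
                  "element classes in priority order")
        gt <- geneTable; gt$midpoint <- gt$midpoint - 1L
        .writeTsv(gt, file.path(config@outputDir, "gene_table.tsv"),
                  "midpoint 0-based; tss_distance signed bp")
        writeLines(regGenes,
                   file.path(config@outputDir, "regulatory_genes.txt"))
    }

    fb <- .stage("forbes", {
        ex <- if (length(blacklist)) blacklist else NULL
        if (config@permutations > 0)
            forbesPermutationTest(toCoverage(A), toCoverage(B), genome,
                                  exclude = ex, M = config@permutations,
                                  seed = config@seed)
        else forbesCoefficient(toCoverage(A), toCoverage(B), genome,
                               exclude = ex)
    })
    fbDf <- data.frame(track_a = peakLabel(A), track_b = peakLabel(B),
                       forbes = fb@fc, overlap_bp = fb@overlapBp,
                       coverage_a = fb@coverageA, coverage_b = fb@coverageB,
                       genome_bp = fb@genomeBp,
                       p_value = if (is.null(fb@pvalue)) NA else fb@pvalue)
    .writeTsv(fbDf, file.path(config@outputDir, "forbes.tsv"),
              "Forbes coefficient = overlap * G / (covA * covB) on the effective (non-blacklisted) genome")

    ora <- NULL
    if (!is.na(config@geneSets) && length(regGenes)) {
        sets <- .stage("read_gene_sets", readGeneSets(config@geneSets))
        ora <- .stage("ora", runOra(regGenes, sets,
                                    minOverlap = config@minOverlap,
                                    pCutoff = config@pCutoff))
        .writeTsv(ora, file.path(config@outputDir, "ora.tsv"),
                  sprintf("hypergeometric ORA; filters: overlap >= %g and p < %g",
                          config@minOverlap, config@pCutoff))
    }

    log <- list(
        package = "cooccupancy",
        version = as.character(utils::packageVersion("cooccupancy")),
        seed = config@seed,
        parameters = list(
            topN = config@topN,
            topNSubject = config@topNSubject,
            maxPairDist = config@maxPairDist,
            closePairThreshold = config@closePairThreshold,
            promoter = config@annotation@promoter,
            farLimit = config@annotation@farLimit,
            tssWindow = config@annotation@tssWindow,
            maxGeneDistance = config@annotation@maxGeneDistance,
            minOverlap = config@minOverlap,
            pCutoff = config@pCutoff,
            permutations = config@permutations),
        counts = counts)
    jsonlite::write_json(log, file.path(config@outputDir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(pairs = pairs, histogram = hist, closePairs = close,
                   tssProfile = tssProf, movingAverage = maCurve,
                   elementDistribution = elemDist, geneTable = geneTable,
                   regulatoryGenes = regGenes, forbes = fb, ora = ora,
                   log = log))
}
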