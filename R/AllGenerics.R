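#' @include AllClasses.R
NULL

#' @export
setGeneric("peakLabel", function(x) standardGeneric("peakLabel"))
#' @export
setGeneric("peakSummits", function(x) standardGeneric("peakSummits"))
#' @export
setGeneric("peakScores", function(x) standardGeneric("peakScores"))
#' @export
setGeneric("peakNames", function(x) standardGeneric("peakNames"))
#' @export
setGeneric("coveredBp", function(x) standardGeneric("coveredBp"))
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @export
setGeneric("geneExons", function(x) standardGeneric("geneExons"))
#' @export
setGeneric("geneTss", function(x) standardGeneric("geneTss"))
#' @export
setGeneric("pairDistances", function(x) standardGeneric("pairDistances"))
#' @export
setGeneric("pairMidpoints", function(x) standardGeneric("pairMidpoints"))
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
#' @export
setGeneric("forbes", function(x) standardGeneric("forbes"))
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Accessors
#'
#' Small accessors for the package classes: `peakLabel`, `peakSummits`
#' (absolute 1-based), `peakScores`, `peakNames` for `PeakSet`; `coveredBp`
#' (total covered base pairs) for `CoverageTrack`; `geneIds`, `geneRanges`,
#' `geneExons`, `geneTss` for `GeneModels`; `pairDistances`, `pairMidpoints`
#' and `pairTable` (the full pair `DataFrame`) for `PairSet`; `forbes`
#' (the coefficient) for `ForbesResult`; `pathwayIds`, `pathwayNames` and
#' `geneSets` for `PathwayCollection`.
#'
#' @param x the object.
#' @name accessors
#' @aliases peakLabel peakSummits peakScores peakNames coveredBp geneIds
#'   geneRanges geneExons geneTss pairDistances pairMidpoints pairTable
#'   forbes pathwayIds pathwayNames geneSets
NULL

#' @rdname accessors
setMethod("peakLabel", "PeakSet", function(x) x@label)
#' @rdname accessors
setMethod("peakSummits", "PeakSet", function(x) mcols(x)$summit)
#' @rdname accessors
setMethod("peakScores", "PeakSet", function(x) mcols(x)$score)
#' @rdname accessors
setMethod("peakNames", "PeakSet", function(x) mcols(x)$name)

#' @rdname accessors
setMethod("coveredBp", "CoverageTrack", function(x) sum(as.numeric(width(x))))
#' @rdname accessors
setMethod("coveredBp", "GRanges",
          function(x) sum(as.numeric(width(GenomicRanges::reduce(x)))))

#' @rdname accessors
setMethod("geneIds", "GeneModels", function(x) mcols(x@genes)$gene_id)
#' @rdname accessors
setMethod("geneRanges", "GeneModels", function(x) x@genes)
#' @rdname accessors
setMethod("geneExons", "GeneModels", function(x) x@exons)
#' @rdname accessors
setMethod("geneTss", "GeneModels", function(x) mcols(x@genes)$tss)
setMethod("length", "GeneModels", function(x) length(x@genes))

#' @rdname accessors
setMethod("pairDistances", "PairSet", function(x) x@pairs$distance)
#' @rdname accessors
setMethod("pairMidpoints", "PairSet", function(x) x@pairs$midpoint)
#' @rdname accessors
setMethod("pairTable", "PairSet", function(x) x@pairs)
setMethod("length", "PairSet", function(x) nrow(x@pairs))

#' @rdname accessors
setMethod("forbes", "ForbesResult", function(x) x@fc)

#' @rdname accessors
setMethod("pathwayIds", "PathwayCollection", function(x) names(x@sets))
#' @rdname accessors
setMethod("pathwayNames", "PathwayCollection", function(x) x@pathwayNames)
#' @rdname accessors
setMethod("geneSets", "PathwayCollection", function(x) x@sets)
setMethod("length", "PathwayCollection", function(x) length(x@sets))

setMethod("show", "PeakSet", function(object) {
    cat(sprintf("PeakSet '%s' with %d peaks\n", object@label, length(object)))
    callNextMethod()
})

setMethod("show", "GeneModels", function(object) {
    cat(sprintf("GeneModels with %d genes (%d exons total)\n",
                length(object), sum(lengths(object@exons))))
})

setMethod("show", "PairSet", function(object) {
    cat(sprintf(
        "PairSet: %d %s-%s pairs (summit distance <= %g bp)\n",
        length(object), object@queryLabel, object@subjectLabel,
        object@maxDistance))
    if (length(object))
        cat(sprintf("  median summit distance: %g bp\n",
                    stats::median(object@pairs$distance)))
})

setMethod("show", "ForbesResult", function(object) {
    cat(sprintf("FC: %.1f (overlap %s bp; coverage %s / %s bp; genome %s bp)\n",
                object@fc, format(object@overlapBp, big.mark = ","),
                format(object@coverageA, big.mark = ","),
                format(object@coverageB, big.mark = ","),
                format(object@genomeBp, big.mark = ",")))
    if (!is.null(object@pvalue))
        cat(sprintf("permutation p = %.4g (%d permutations)\n",
                    object@pvalue, as.integer(object@nPerm)))
})

setMethod("show", "PathwayCollection", function(object) {
    cat(sprintf("PathwayCollection with %d pathways (%d distinct genes)\n",
                length(object), length(unique(unlist(object@sets)))))
})

#' Coerce a PairSet to a data.frame
#'
#' @param x a `PairSet`.
#' @param ... unused.
#' @export
as.data.frame.PairSet <- function(x, ...) as.data.frame(x@pairs)
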