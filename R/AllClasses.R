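#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- isSorted
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList granges seqnames start end
#'   width strand strand<- start<- end<-
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqinfo seqinfo<- seqnames
#'   seqlevels sortSeqlevels
#' @importFrom BiocGenerics sort unlist
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' PeakSet: a scored, summit-annotated set of ChIP-seq peaks
#'
#' A `PeakSet` extends [GenomicRanges::GRanges] with the metadata columns
#' `name` (peak identifier), `score` (ranking score, e.g. MACS signalValue)
#' and `summit` (absolute 1-based position of the peak summit, the base of
#' maximal signal), plus a `label` slot naming the transcription factor.
#'
#' Peaks are kept sorted by (chromosome, start) and every summit must lie
#' inside its peak interval. Coordinates are 1-based closed internally, as
#' for any `GRanges`; the readers and writers convert from/to the 0-based
#' half-open BED convention.
#'
#' @slot label single string, the factor name (e.g. `"ChREBP"`).
#' @export
setClass("PeakSet", contains = "GRanges",
         representation(label = "character"),
         prototype(label = NA_character_))

setValidity("PeakSet", function(object) {
    msg <- character()
    if (length(object@label) != 1L)
        msg <- c(msg, "'label' must be a single string")
    mc <- mcols(object)
    need <- c("name", "score", "summit")
    if (!all(need %in% colnames(mc)))
        return(paste("PeakSet requires mcols:", paste(need, collapse = ", ")))
    if (length(object)) {
        s <- mc$summit
        if (any(is.na(s)) || any(s < start(object)) || any(s > end(object)))
            msg <- c(msg, "every summit must lie within its peak interval")
        ord <- order(as.integer(seqnames(object)), start(object))
        if (!identical(ord, seq_along(object)))
            msg <- c(msg, "peaks must be sorted by (chromosome, start)")
        sl <- seqlengths(object)
        if (any(!is.na(sl))) {
            lim <- sl[as.character(seqnames(object))]
            bad <- !is.na(lim) & end(object) > lim
            if (any(bad))
                msg <- c(msg, sprintf("%d peak(s) extend beyond chromosome ends",
                                      sum(bad)))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param gr a `GRanges` with mcols `name`, `score`, `summit` (1-based
#'   absolute summit positions).
#' @param label factor name for the set.
#' @param seqinfo optional [GenomeInfoDb::Seqinfo] binding the coordinate
#'   frame; chromosome names must match exactly (no "chr" normalisation) —
#'   peaks on unknown chromosomes raise an error listing the offending names.
#' @return a `PeakSet`, sorted by coordinate.
#' @export
PeakSet <- function(gr, label = NA_character_, seqinfo = NULL) {
    if (!is(gr, "GRanges")) stop("'gr' must be a GRanges")
    if (!is.null(seqinfo)) {
        unknown <- setdiff(as.character(unique(seqnames(gr))),
                           seqnames(seqinfo))
        if (length(unknown))
            stop("chromosome name(s) absent from genome: ",
                 paste(unknown, collapse = ", "))
        GenomeInfoDb::seqlevels(gr) <- seqnames(seqinfo)
        seqinfo(gr) <- seqinfo
    } else {
        gr <- GenomeInfoDb::sortSeqlevels(gr)
    }
    gr <- gr[order(as.integer(seqnames(gr)), start(gr))]
    obj <- as(gr, "PeakSet")
    obj@label <- as.character(label)
    validObject(obj)
    obj
}

#' CoverageTrack: merged, disjoint binary genomic coverage
#'
#' A `CoverageTrack` extends `GRanges` and holds the union of a set of
#' intervals as sorted, merged, non-overlapping, unstranded ranges — the
#' binary representation that base-pair overlap statistics (notably the
#' Forbes coefficient) are computed on.
#'
#' @export
setClass("CoverageTrack", contains = "GRanges")

setValidity("CoverageTrack", function(object) {
    if (length(object) == 0L) return(TRUE)
    msg <- character()
    if (!all(as.character(strand(object)) == "*"))
        msg <- c(msg, "coverage intervals must be unstranded")
    red <- GenomicRanges::reduce(granges(object))
    if (length(red) != length(object) ||
        sum(width(red)) != sum(width(object)))
        msg <- c(msg, "intervals must be merged and non-overlapping")
    if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack
#'
#' Merges (reduces) the input intervals; strand is discarded.
#'
#' @param gr a `GRanges` (or anything coercible).
#' @return a `CoverageTrack`.
#' @export
CoverageTrack <- function(gr = GRanges()) {
    gr <- granges(as(gr, "GRanges"))
    strand(gr) <- "*"
    gr <- GenomicRanges::reduce(BiocGenerics::sort(gr))
    as(gr, "CoverageTrack")
}

#' GeneModels: strand-aware gene models with ordered exons
#'
#' Holds one `GRanges` of gene spans (strand required; mcols `gene_id`,
#' `tss`, `tes` with the transcription start/end site as absolute 1-based
#' positions derived from strand) and a parallel `GRangesList` of exons.
#' Exons are stored in 5'->3' gene orientation (so the first element of each
#' list entry is the first exon of the gene, not the leftmost one).
#'
#' @slot genes `GRanges` of gene spans.
#' @slot exons `GRangesList`, one entry per gene.
#' @export
setClass("GeneModels",
         representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModels", function(object) {
    g <- object@genes
    msg <- character()
    if (length(g) != length(object@exons))
        return("'genes' and 'exons' must be parallel")
    need <- c("gene_id", "tss", "tes")
    if (!all(need %in% colnames(mcols(g))))
        return(paste("gene mcols must contain", paste(need, collapse = ", ")))
    if (length(g)) {
        st <- as.character(strand(g))
        if (any(!st %in% c("+", "-")))
            msg <- c(msg, "every gene must have strand '+' or '-'")
        tssExp <- ifelse(st == "+", start(g), end(g))
        tesExp <- ifelse(st == "+", end(g), start(g))
        if (!all(mcols(g)$tss == tssExp) || !all(mcols(g)$tes == tesExp))
            msg <- c(msg, "tss/tes must be the strand-appropriate gene extremities")
        for (i in seq_along(g)) {
            ex <- object@exons[[i]]
            if (length(ex) == 0L) { msg <- c(msg, "genes need >=1 exon"); break }
            s <- start(ex); e <- end(ex)
            ord <- if (st[i] == "+") order(s) else order(-s)
            if (!identical(ord, seq_along(ex))) {
                msg <- c(msg, "exons must be ordered 5'->3' in gene orientation")
                break
            }
            css <- sort(s); cee <- sort(e)
            if (any(css[-1] <= cee[-length(cee)])) {
                msg <- c(msg, "exons must be non-overlapping"); break
            }
            if (min(s) < start(g)[i] || max(e) > end(g)[i]) {
                msg <- c(msg, "exons must lie within the gene span"); break
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct GeneModels
#'
#' @param genes `GRanges` of gene spans with strand and an mcol `gene_id`;
#'   `tss`/`tes` are filled in from strand if absent.
#' @param exons `GRangesList` parallel to `genes`, exons in coordinate or
#'   gene orientation (reordered to gene orientation internally).
#' @return a `GeneModels` object.
#' @export
GeneModels <- function(genes, exons) {
    st <- as.character(strand(genes))
    mcols(genes)$tss <- ifelse(st == "+", start(genes), end(genes))
    mcols(genes)$tes <- ifelse(st == "+", end(genes), start(genes))
    exons <- GRangesList(lapply(seq_along(genes), function(i) {
        ex <- granges(exons[[i]])
        strand(ex) <- st[i]
        ex[if (st[i] == "+") order(start(ex)) else order(-start(ex))]
    }))
    obj <- new("GeneModels", genes = genes, exons = exons)
    validObject(obj)
    obj
}

#' PairSet: nearest-summit peak pairs between two peak sets
#'
#' Produced by [nearestPairs()]. Each row pairs one query peak with its
#' nearest subject peak on the same chromosome by summit-to-summit distance;
#' only pairs with distance <= the applied maximum are kept, and there is at
#' most one pair per query peak.
#'
#' @slot pairs a `DataFrame` with columns `chrom`, `queryName`,
#'   `querySummit`, `subjectName`, `subjectSummit`, `distance`, `midpoint`
#'   (floor of the mean of the two summits, 1-based).
#' @slot maxDistance the summit-distance cutoff that was applied (bp).
#' @slot queryLabel,subjectLabel factor names of the two sets.
#' @export
setClass("PairSet",
         representation(pairs = "DataFrame", maxDistance = "numeric",
                        queryLabel = "character", subjectLabel = "character"))

setValidity("PairSet", function(object) {
    p <- object@pairs
    need <- c("chrom", "queryName", "querySummit", "subjectName",
              "subjectSummit", "distance", "midpoint")
    if (!all(need %in% colnames(p)))
        return(paste("pairs needs columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(p)) {
        if (any(p$distance != abs(p$querySummit - p$subjectSummit)))
            msg <- c(msg, "distance must equal |querySummit - subjectSummit|")
        if (any(p$distance > object@maxDistance))
            msg <- c(msg, "pair distances must be <= maxDistance")
        if (anyDuplicated(p$queryName))
            msg <- c(msg, "at most one pair per query peak")
    }
    if (length(msg)) msg else TRUE
})

#' ForbesResult: Forbes-coefficient co-occurrence of two coverage tracks
#'
#' The Forbes coefficient is the ratio of observed to expected base-pair
#' overlap of two binary tracks under independence:
#' `FC = O * G / (cA * cB)` where `O` is the observed overlap, `cA`/`cB` the
#' per-track coverages and `G` the effective genome length. `FC ~ 1` means
#' no association; large values mean co-occurrence.
#'
#' @slot fc the Forbes coefficient.
#' @slot overlapBp,coverageA,coverageB,genomeBp the components, in bp.
#' @slot pvalue optional permutation p-value (`NULL` if not computed).
#' @slot nPerm number of permutations behind `pvalue` (`NULL` if none).
#' @export
setClass("ForbesResult",
         representation(fc = "numeric", overlapBp = "numeric",
                        coverageA = "numeric", coverageB = "numeric",
                        genomeBp = "numeric", pvalue = "numericOrNULL",
                        nPerm = "numericOrNULL"),
         prototype(pvalue = NULL, nPerm = NULL))

setValidity("ForbesResult", function(object) {
    msg <- character()
    if (object@overlapBp > min(object@coverageA, object@coverageB))
        msg <- c(msg, "overlap cannot exceed either coverage")
    expected <- object@overlapBp * object@genomeBp /
        (object@coverageA * object@coverageB)
    if (abs(object@fc - expected) > 1e-8 * max(1, expected))
        msg <- c(msg, "fc must equal overlap * G / (coverageA * coverageB)")
    if (!is.null(object@pvalue) &&
        (object@pvalue <= 0 || object@pvalue > 1))
        msg <- c(msg, "pvalue must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' PathwayCollection: named pathway gene sets
#'
#' A light container for GMT-style pathway collections: pathway ids mapped
#' to a descriptive name and a set of unique member gene identifiers.
#'
#' @slot sets named list of character vectors (names = pathway ids).
#' @slot pathwayNames character vector of descriptions, parallel to `sets`.
#' @export
setClass("PathwayCollection",
         representation(sets = "list", pathwayNames = "character"))

setValidity("PathwayCollection", function(object) {
    msg <- character()
    if (length(object@sets) != length(object@pathwayNames))
        msg <- c(msg, "'sets' and 'pathwayNames' must be parallel")
    if (anyDuplicated(names(object@sets)))
        msg <- c(msg, "pathway ids must be unique")
    if (length(object@sets)) {
        if (any(!vapply(object@sets, length, 1L)))
            msg <- c(msg, "member lists must be non-empty")
        if (any(vapply(object@sets, anyDuplicated, 1L) > 0L))
            msg <- c(msg, "member gene ids must be unique within a pathway")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PathwayCollection
#'
#' @param sets named list of character vectors of member gene ids
#'   (duplicates within a pathway are removed).
#' @param pathwayNames optional descriptions (defaults to the ids).
#' @return a `PathwayCollection`.
#' @export
PathwayCollection <- function(sets, pathwayNames = NULL) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        stop("'sets' must be a named list")
    if (anyDuplicated(names(sets)))
        stop("duplicate pathway id(s): ",
             paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
    sets <- lapply(sets, function(g) unique(as.character(g)))
    if (is.null(pathwayNames)) pathwayNames <- names(sets)
    obj <- new("PathwayCollection", sets = sets,
               pathwayNames = as.character(pathwayNames))
    validObject(obj)
    obj
}

#' AnnotationParams: windows for genomic-element assignment
#'
#' Distance windows (all in bp, measured from the TSS or TES in gene
#' orientation) used when assigning positions to genomic elements and when
#' mapping peak pairs to genes:
#' promoter = less than `promoter` bp upstream of the TSS; 5'/3' far =
#' between `promoter` and `farLimit` bp up-/downstream; TSS = within
#' `tssWindow` bp of the TSS; pairs farther than `maxGeneDistance` from the
#' TSS and outside the gene span are not linked to a gene.
#'
#' @export
setClass("AnnotationParams",
         representation(promoter = "numeric", farLimit = "numeric",
                        tssWindow = "numeric", maxGeneDistance = "numeric"))

setValidity("AnnotationParams", function(object) {
    if (!(object@tssWindow < object@promoter &&
          object@promoter < object@farLimit))
        return("need tssWindow < promoter < farLimit")
    if (object@maxGeneDistance <= 0) return("maxGeneDistance must be > 0")
    TRUE
})

#' @param promoter promoter length upstream of the TSS (bp; default 5000).
#' @param farLimit outer limit of the far up-/downstream windows (bp;
#'   default 25000, i.e. 25 kb as in gene-matching with a 25 kb distance cap).
#' @param tssWindow half-width of the TSS window (bp; default 200).
#' @param maxGeneDistance maximum |TSS distance| for linking a pair to a gene
#'   unless it falls inside the gene span (bp; default 25000).
#' @return an `AnnotationParams` object.
#' @rdname AnnotationParams-class
#' @export
annotationParams <- function(promoter = 5000, farLimit = 25000,
                             tssWindow = 200, maxGeneDistance = 25000) {
    obj <- new("AnnotationParams", promoter = promoter, farLimit = farLimit,
               tssWindow = tssWindow, maxGeneDistance = maxGeneDistance)
    validObject(obj)
    obj
}

#' The nine genomic-element classes, in priority order
#'
#' Classification priority used by [assignElement()]: the TSS window wins
#' over the first exon, which wins over the first intron, then the rest of
#' the gene body, then the distance windows (promoter, 5' far upstream of
#' the TSS; 3' near, 3' far downstream of the TES), and finally
#' `"unassigned"`.
#'
#' @return character vector of element labels in priority order.
#' @export
elementLevels <- function() {
    c("tss", "first_exon", "first_intron", "gene_body",
      "promoter", "five_prime_far", "three_prime_near", "three_prime_far",
      "unassigned")
}
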