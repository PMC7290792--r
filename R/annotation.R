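#' @include AllClasses.R tss-profile.R
NULL

## Classify midpoints against one gene. Intragenic classes take priority
## over distance windows (a midpoint in the first exon is "tss" only inside
## the +/- tssWindow), mirroring the area hierarchy of Rgmatch-style gene
## matching. First exon/intron are the 5'-most in gene orientation.
.classifyAgainstGene <- function(midpoint, genes, gi, params) {
    g <- geneRanges(genes)[gi]
    st <- as.character(strand(g))
    tss <- geneTss(genes)[gi]
    tes <- mcols(geneRanges(genes))$tes[gi]
    ex <- geneExons(genes)[[gi]]
    d <- signedTssDistance(midpoint, tss, st)
    e <- signedTssDistance(midpoint, tes, st)   # >0 means past the gene end
    el <- rep("unassigned", length(midpoint))
    inSpan <- midpoint >= start(g) & midpoint <= end(g)
    el[inSpan] <- "gene_body"
    if (length(ex) >= 2L) {
        i1s <- if (st == "+") end(ex)[1L] + 1L else end(ex)[2L] + 1L
        i1e <- if (st == "+") start(ex)[2L] - 1L else start(ex)[1L] - 1L
        inI1 <- midpoint >= i1s & midpoint <= i1e
        el[inI1] <- "first_intron"
    }
    inE1 <- midpoint >= start(ex)[1L] & midpoint <= end(ex)[1L]
    el[inE1] <- "first_exon"
    el[abs(d) <= params@tssWindow] <- "tss"
    out <- !inSpan & el == "unassigned"
    el[out & d < 0 & d > -params@promoter] <- "promoter"
    el[out & d <= -params@promoter & d >= -params@farLimit] <- "five_prime_far"
    sel <- el == "unassigned" & out & e > 0
    el[sel & e < params@promoter] <- "three_prime_near"
    el[sel & e >= params@promoter & e <= params@farLimit] <- "three_prime_far"
    list(element = el, tssDistance = d, inSpan = inSpan)
}

#' Assign positions to a genomic element of one gene
#'
#' Classifies position(s) against a single gene using the element windows
#' in `params`. Priority: TSS window (+/- `tssWindow` bp of the TSS) >
#' first exon > first intron > gene body > promoter (< `promoter` bp
#' upstream of the TSS) > 5' far (`promoter`..`farLimit` bp upstream) >
#' 3' near (< `promoter` bp downstream of the TES) > 3' far
#' (`promoter`..`farLimit` bp downstream) > unassigned.
#'
#' @param position position(s) (1-based, e.g. pair midpoints).
#' @param genes a [GeneModels] object.
#' @param gene gene index or gene id within `genes`.
#' @param params an [annotationParams()] object.
#' @return a `data.frame` with columns `element` (see [elementLevels()]),
#'   `gene_id` (NA where unassigned), `tss_distance`.
#' @export
assignElement <- function(position, genes, gene, params = annotationParams()) {
    stopifnot(is(genes, "GeneModels"))
    gi <- if (is.character(gene)) match(gene, geneIds(genes)) else as.integer(gene)
    if (is.na(gi) || gi < 1L || gi > length(genes))
        stop("unknown gene: ", gene)
    cl <- .classifyAgainstGene(position, genes, gi, params)
    data.frame(element = factor(cl$element, levels = elementLevels()),
               gene_id = ifelse(cl$element == "unassigned", NA_character_,
                                geneIds(genes)[gi]),
               tss_distance = cl$tssDistance)
}

## nearest gene + classification for each pair midpoint
.annotatePairs <- function(pairs, genes, params) {
    p <- pairTable(pairs)
    n <- nrow(p)
    res <- data.frame(pair = seq_len(n), chrom = p$chrom,
                      midpoint = p$midpoint,
                      gene_id = NA_character_,
                      element = rep("unassigned", n),
                      tss_distance = NA_integer_,
                      in_gene = FALSE,
                      pair_distance = p$distance)
    if (length(genes) == 0L || n == 0L) return(res)
    nn <- .nearestGene(p$chrom, p$midpoint, genes)
    for (gi in unique(nn$geneIndex[!is.na(nn$geneIndex)])) {
        idx <- which(nn$geneIndex == gi)
        cl <- .classifyAgainstGene(p$midpoint[idx], genes, gi, params)
        assigned <- cl$element != "unassigned"
        res$element[idx] <- cl$element
        res$tss_distance[idx] <- cl$tssDistance
        res$in_gene[idx] <- cl$inSpan
        res$gene_id[idx[assigned]] <- geneIds(genes)[gi]
    }
    res
}

#' Distribution of peak pairs over genomic elements
#'
#' Each pair midpoint is annotated against its nearest gene (by absolute
#' TSS distance) and classified into one of the nine element classes; the
#' table reports counts and fractions over all pairs (fractions sum to 1).
#' With an empty gene list every pair is unassigned.
#'
#' @param pairs a [PairSet].
#' @param genes a [GeneModels] object.
#' @param params an [annotationParams()] object.
#' @return a `data.frame` with columns `element`, `count`, `fraction`,
#'   one row per element class in priority order.
#' @export
elementDistribution <- function(pairs, genes, params = annotationParams()) {
    stopifnot(is(pairs, "PairSet"))
    ann <- .annotatePairs(pairs, genes, params)
    lv <- elementLevels()
    cnt <- table(factor(ann$element, levels = lv))
    data.frame(element = lv, count = as.integer(cnt),
               fraction = if (nrow(ann)) as.numeric(cnt) / nrow(ann)
                          else rep(NA_real_, length(lv)))
}

#' Map peak pairs to their nearest genes
#'
#' Gene-level report in the spirit of Rgmatch's `--report gene`: one row
#' per pair linked to its nearest gene, kept when the absolute TSS distance
#' is at most `params@maxGeneDistance` (default 25 kb) or when the midpoint
#' lies inside the gene span (the inside-gene override).
#'
#' @param pairs a [PairSet].
#' @param genes a [GeneModels] object.
#' @param params an [annotationParams()] object.
#' @return a `data.frame` with columns `gene_id`, `pair`, `chrom`,
#'   `midpoint`, `element`, `tss_distance`, `pair_distance`.
#' @export
mapPairsToGenes <- function(pairs, genes, params = annotationParams()) {
    ann <- .annotatePairs(pairs, genes, params)
    keep <- !is.na(ann$gene_id) &
        (abs(ann$tss_distance) <= params@maxGeneDistance | ann$in_gene)
    out <- ann[keep, c("gene_id", "pair", "chrom", "midpoint", "element",
                       "tss_distance", "pair_distance")]
    rownames(out) <- NULL
    out
}

#' Select promoter-proximal regulated genes from a gene table
#'
#' Applies the gene-list filter used for over-representation analysis:
#' keep genes having at least one pair whose signed TSS distance lies in
#' `[-upstream, +downstream]` (default -5000..+2500 bp, i.e. promoter
#' through first exon) and whose peak-to-peak distance is strictly below
#' `pairDistanceCutoff` (default 100 bp, the co-localized pairs).
#'
#' @param geneTable output of [mapPairsToGenes()].
#' @param upstream upstream limit in bp (positive number; default 5000).
#' @param downstream downstream limit in bp (default 2500).
#' @param pairDistanceCutoff strict pair-distance cutoff in bp (default 100).
#' @return sorted, deduplicated character vector of gene ids.
#' @export
selectRegulatoryGenes <- function(geneTable, upstream = 5000,
                                  downstream = 2500,
                                  pairDistanceCutoff = 100) {
    stopifnot(all(c("gene_id", "tss_distance", "pair_distance") %in%
                  colnames(geneTable)))
    keep <- geneTable$tss_distance >= -upstream &
        geneTable$tss_distance <= downstream &
        geneTable$pair_distance < pairDistanceCutoff
    sort(unique(geneTable$gene_id[keep]))
}
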