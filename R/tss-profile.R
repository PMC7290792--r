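#' @include AllClasses.R
NULL

#' Signed distance from a position to a TSS, in gene orientation
#'
#' Upstream distances are negative and downstream positive relative to the
#' direction of transcription: for a `+` gene the distance is
#' `position - TSS`, for a `-` gene it is `TSS - position`. Positions may be
#' in any consistent coordinate base since only differences are taken.
#'
#' @param position position(s), e.g. pair midpoints.
#' @param tss TSS position(s), recycled against `position`.
#' @param strand `"+"` or `"-"`, recycled.
#' @return integer signed distance(s) in bp.
#' @export
signedTssDistance <- function(position, tss, strand) {
    stopifnot(all(strand %in% c("+", "-")))
    n <- max(length(position), length(tss), length(strand))
    position <- rep_len(position, n)
    tss <- rep_len(tss, n)
    strand <- rep_len(strand, n)
    as.integer(ifelse(strand == "+", position - tss, tss - position))
}

## Nearest gene by |signed TSS distance| for positions on one chromosome
## frame; ties go to the lexicographically smallest gene id. Returns the
## gene index (NA where the chromosome carries no gene) and the signed
## distance computed with the winning gene's strand.
.nearestGene <- function(chrom, position, genes) {
    g <- geneRanges(genes)
    gChrom <- as.character(seqnames(g))
    tss <- geneTss(genes)
    ids <- geneIds(genes)
    st <- as.character(strand(g))
    geneIdx <- rep(NA_integer_, length(position))
    for (ch in unique(chrom)) {
        gi <- which(gChrom == ch)
        pi <- which(chrom == ch)
        if (!length(gi) || !length(pi)) next
        ord <- gi[order(tss[gi], ids[gi])]
        ss <- tss[ord]
        n <- length(ss)
        p <- position[pi]
        i <- findInterval(p, ss)
        iL <- pmax(i, 1L); iR <- pmin(i + 1L, n)
        dl <- ifelse(i >= 1L, p - ss[iL], Inf)
        dr <- ifelse(i < n, ss[iR] - p, Inf)
        jL <- match(ss[iL], ss)   # smallest id at that TSS value
        jR <- match(ss[iR], ss)
        pick <- ifelse(dl <= dr, jL, jR)
        both <- which(dl == dr & jL != jR)
        if (length(both)) {
            idL <- ids[ord[jL[both]]]; idR <- ids[ord[jR[both]]]
            pick[both] <- ifelse(idL <= idR, jL[both], jR[both])
        }
        geneIdx[pi] <- ord[pick]
    }
    ok <- !is.na(geneIdx)
    d <- rep(NA_integer_, length(position))
    d[ok] <- signedTssDistance(position[ok], tss[geneIdx[ok]], st[geneIdx[ok]])
    list(geneIndex = geneIdx, signedDistance = d)
}

#' Distance-to-TSS profile of peak pairs
#'
#' For each pair, the gene whose TSS is closest (by absolute distance) to
#' the pair midpoint on the same chromosome is found, and the signed
#' distance (upstream negative, in gene orientation) recorded together with
#' the pair's summit distance. Pairs on chromosomes without genes are
#' omitted. Equidistant TSSs are resolved to the lexicographically smaller
#' gene id.
#'
#' @param pairs a [PairSet].
#' @param genes a [GeneModels] object (non-empty).
#' @return a `data.frame` with columns `pair`, `chrom`, `midpoint`,
#'   `gene_id`, `tss_distance` (signed bp), `pair_distance` (bp).
#' @export
nearestTssProfile <- function(pairs, genes) {
    stopifnot(is(pairs, "PairSet"), is(genes, "GeneModels"))
    if (length(genes) == 0L) stop("gene list is empty")
    p <- pairTable(pairs)
    nn <- .nearestGene(p$chrom, p$midpoint, genes)
    ok <- !is.na(nn$geneIndex)
    data.frame(pair = which(ok),
               chrom = p$chrom[ok],
               midpoint = p$midpoint[ok],
               gene_id = geneIds(genes)[nn$geneIndex[ok]],
               tss_distance = nn$signedDistance[ok],
               pair_distance = p$distance[ok])
}

#' Moving average of pair distance along the TSS-distance axis
#'
#' Summarises a [nearestTssProfile()] table as a moving-average curve: at
#' each evaluation point `x` (the sorted unique TSS distances), the mean
#' pair distance over records whose TSS distance falls in the centered
#' window `[x - window/2, x + window/2)` is reported. With
#' `type = "records"` the window is instead a centered count of `window`
#' records along the sorted TSS-distance axis.
#'
#' @param records output of [nearestTssProfile()].
#' @param window window size: bp for `type = "bp"` (default 100), a record
#'   count for `type = "records"`.
#' @param type window interpretation.
#' @return a `data.frame` with columns `tss_distance`,
#'   `mean_pair_distance`, `n_records`.
#' @export
movingAverageCurve <- function(records, window = 100,
                               type = c("bp", "records")) {
    type <- match.arg(type)
    stopifnot(window > 0)
    if (nrow(records) == 0L)
        return(data.frame(tss_distance = numeric(),
                          mean_pair_distance = numeric(),
                          n_records = integer()))
    ord <- order(records$tss_distance)
    s <- records$tss_distance[ord]
    pd <- records$pair_distance[ord]
    if (type == "records") {
        h <- floor(window / 2)
        n <- length(s)
        lo <- pmax(seq_len(n) - h, 1L)
        hi <- pmin(seq_len(n) + h, n)
        cs <- cumsum(pd)
        mn <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
        return(data.frame(tss_distance = s, mean_pair_distance = mn,
                          n_records = hi - lo + 1L))
    }
    x <- unique(s)
    eps <- 1e-9
    a <- findInterval(x - window / 2 - eps, s)   # records strictly below window
    b <- findInterval(x + window / 2 - eps, s)   # records below upper bound
    cs <- c(0, cumsum(pd))
    cnt <- b - a
    data.frame(tss_distance = x,
               mean_pair_distance = (cs[b + 1L] - cs[a + 1L]) / cnt,
               n_records = cnt)
}
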