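#' @include AllClasses.R
NULL

#' Pair each query peak with its nearest subject peak by summit distance
#'
#' For every query peak, the subject peak on the same chromosome with the
#' smallest summit-to-summit distance is found ("bedtools closest" on the
#' summits: one nearest feature per query). Pairs farther apart than
#' `maxDist` are discarded. Distance ties are broken deterministically: the
#' subject with the smaller start coordinate wins, then the smaller name.
#' Query peaks on chromosomes with no subject peaks produce no pair;
#' inter-chromosomal pairs are impossible by construction.
#'
#' Note that the operation is not symmetric in (query, subject): each query
#' contributes at most one pair, while a subject peak may appear in several.
#'
#' @param query,subject [PeakSet]s sharing a coordinate frame.
#' @param maxDist maximum summit-to-summit distance kept (bp; the analysis
#'   default is 1000, i.e. pairs with distance > 1000 bp are discarded).
#' @return a [PairSet].
#' @export
nearestPairs <- function(query, subject, maxDist = 1000) {
    stopifnot(is(query, "PeakSet"), is(subject, "PeakSet"), maxDist > 0)
    qChrom <- as.character(seqnames(query))
    sChrom <- as.character(seqnames(subject))
    shared <- intersect(unique(qChrom), unique(sChrom))
    empty <- DataFrame(chrom = character(), queryName = character(),
                       querySummit = integer(), subjectName = character(),
                       subjectSummit = integer(), distance = integer(),
                       midpoint = integer())
    if (length(shared) == 0L) {
        warning("query and subject share no chromosomes; empty PairSet")
        return(new("PairSet", pairs = empty, maxDistance = maxDist,
                   queryLabel = peakLabel(query),
                   subjectLabel = peakLabel(subject)))
    }
    out <- vector("list", length(shared))
    for (ci in seq_along(shared)) {
        ch <- shared[ci]
        qi <- which(qChrom == ch)
        si <- which(sChrom == ch)
        q <- peakSummits(query)[qi]
        ssum <- peakSummits(subject)[si]
        sstart <- start(subject)[si]
        sname <- peakNames(subject)[si]
        ord <- order(ssum, sstart, sname)
        ss <- ssum[ord]
        n <- length(ss)
        i <- findInterval(q, ss)
        iL <- pmax(i, 1L); iR <- pmin(i + 1L, n)
        dl <- ifelse(i >= 1L, q - ss[iL], Inf)
        dr <- ifelse(i < n, ss[iR] - q, Inf)
        dmin <- pmin(dl, dr)
        ## first occurrence of a summit value in 'ord' order is already the
        ## (start, name)-smallest subject carrying that summit
        jL <- match(ss[iL], ss)
        jR <- match(ss[iR], ss)
        pick <- ifelse(dl <= dr, jL, jR)
        both <- which(dl == dr & jL != jR)
        if (length(both)) {
            oL <- ord[jL[both]]; oR <- ord[jR[both]]
            takeL <- sstart[oL] < sstart[oR] |
                (sstart[oL] == sstart[oR] & sname[oL] <= sname[oR])
            pick[both] <- ifelse(takeL, jL[both], jR[both])
        }
        sj <- ord[pick]
        keep <- dmin <= maxDist
        out[[ci]] <- DataFrame(
            chrom = rep(ch, sum(keep)),
            queryName = peakNames(query)[qi][keep],
            querySummit = q[keep],
            subjectName = sname[sj][keep],
            subjectSummit = ssum[sj][keep],
            distance = as.integer(dmin[keep]),
            midpoint = as.integer(floor((q[keep] + ssum[sj][keep]) / 2)))
    }
    pairs <- do.call(rbind, out)
    new("PairSet", pairs = pairs, maxDistance = maxDist,
        queryLabel = peakLabel(query), subjectLabel = peakLabel(subject))
}

#' Histogram of pair summit distances
#'
#' Counts pair distances into half-open bins `[k*w, (k+1)*w)`; bins are
#' contiguous from 0 up to the largest observed distance, so the counts sum
#' to the number of pairs.
#'
#' @param pairs a [PairSet].
#' @param binWidth bin width in bp (> 0).
#' @return a `data.frame` with columns `bin_start`, `bin_end`, `count`.
#' @export
distanceHistogram <- function(pairs, binWidth = 50) {
    stopifnot(is(pairs, "PairSet"), binWidth > 0)
    d <- pairDistances(pairs)
    if (length(d) == 0L)
        return(data.frame(bin_start = numeric(), bin_end = numeric(),
                          count = integer()))
    k <- floor(d / binWidth)
    bins <- 0:max(k)
    data.frame(bin_start = bins * binWidth,
               bin_end = (bins + 1) * binWidth,
               count = as.integer(tabulate(k + 1L, nbins = max(k) + 1L)))
}

#' Count and percentage of pairs closer than a threshold
#'
#' Reports how many pairs have summit distance strictly below `threshold`,
#' and that count as a percentage of all pairs rounded to one decimal
#' (e.g. 7928 of 11022 pairs below 100 bp -> 71.9).
#'
#' @param pairs a [PairSet].
#' @param threshold distance threshold in bp (strict `<`).
#' @return a `data.frame` with columns `count`, `total`, `percentage`.
#' @export
fractionWithin <- function(pairs, threshold = 100) {
    stopifnot(is(pairs, "PairSet"))
    n <- length(pairs)
    if (n == 0L) stop("fraction undefined for an empty PairSet")
    if (threshold > pairs@maxDistance + 1)
        warning("threshold exceeds the applied maximum pair distance")
    cnt <- sum(pairDistances(pairs) < threshold)
    data.frame(count = cnt, total = n,
               percentage = round(100 * cnt / n, 1))
}
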