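#' @include AllClasses.R
NULL

#' Remove peaks overlapping a blacklist
#'
#' Discards every peak whose interval overlaps a blacklist region by at
#' least one base pair (the standard blacklist rule: any overlap, not just
#' summit containment). Peak order is preserved; an empty result is allowed.
#'
#' @param peaks a [PeakSet].
#' @param blacklist a [CoverageTrack] (or `GRanges`) of regions to exclude.
#' @return the filtered `PeakSet`.
#' @export
filterBlacklist <- function(peaks, blacklist) {
    stopifnot(is(peaks, "PeakSet"))
    if (length(blacklist) == 0L || length(peaks) == 0L) return(peaks)
    hit <- IRanges::overlapsAny(granges(peaks), granges(as(blacklist, "GRanges")),
                                ignore.strand = TRUE)
    peaks[!hit]
}

#' Keep the top-N peaks by score
#'
#' Returns the `min(n, length(peaks))` peaks with highest score, re-sorted
#' by coordinate. Score ties at the boundary are broken deterministically by
#' (chromosome, start) ascending, so repeated runs select the same peaks.
#'
#' @param peaks a [PeakSet].
#' @param n number of peaks to keep (> 0).
#' @return a `PeakSet` of at most `n` peaks.
#' @export
topNByScore <- function(peaks, n) {
    stopifnot(is(peaks, "PeakSet"), n > 0)
    if (length(peaks) <= n) return(peaks)
    ord <- order(-peakScores(peaks), as.integer(seqnames(peaks)), start(peaks))
    keep <- sort(ord[seq_len(n)])
    peaks[keep]
}

#' Merge peak intervals into a binary coverage track
#'
#' The union of the full peak intervals; total covered bp equals the size
#' of the union (<= the sum of peak lengths, with equality iff disjoint).
#'
#' @param peaks a [PeakSet] (or any `GRanges`).
#' @param mode `"interval"` uses the full peak intervals; `"summit"` uses
#'   `summit +/- flank` windows instead.
#' @param flank half-width used in summit mode (bp).
#' @return a [CoverageTrack].
#' @export
toCoverage <- function(peaks, mode = c("interval", "summit"), flank = 250) {
    mode <- match.arg(mode)
    if (mode == "summit" && is(peaks, "PeakSet")) {
        s <- peakSummits(peaks)
        gr <- GRanges(seqnames(peaks),
                      IRanges(pmax(1, s - flank), s + flank),
                      seqinfo = seqinfo(peaks))
        if (any(!is.na(seqlengths(gr)))) {
            lim <- seqlengths(gr)[as.character(seqnames(gr))]
            end(gr) <- pmin(end(gr), ifelse(is.na(lim), end(gr), lim))
        }
        return(CoverageTrack(gr))
    }
    CoverageTrack(granges(as(peaks, "GRanges")))
}
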