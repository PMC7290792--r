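#' @include AllClasses.R
NULL

.effectiveGenomeBp <- function(genome, exclude = NULL) {
    G <- sum(as.numeric(seqlengths(genome)))
    if (!is.null(exclude) && length(exclude))
        G <- G - coveredBp(CoverageTrack(exclude))
    G
}

.restrictTrack <- function(track, exclude = NULL) {
    gr <- granges(as(track, "GRanges"))
    strand(gr) <- "*"
    gr <- GenomicRanges::reduce(BiocGenerics::sort(gr))
    if (!is.null(exclude) && length(exclude))
        gr <- GenomicRanges::setdiff(gr, granges(as(exclude, "GRanges")),
                                     ignore.strand = TRUE)
    gr
}

#' Forbes-coefficient co-occurrence of two coverage tracks
#'
#' Computes the Forbes coefficient at base-pair resolution on the effective
#' genome: `FC = O * G / (cA * cB)`, where `O` is the observed overlap in
#' bp, `cA`/`cB` the per-track coverages and `G` the total genome length
#' minus any excluded (e.g. blacklisted) bases. Tracks are intersected with
#' the non-excluded region before measuring, so the coefficient and any
#' permutation null share one coordinate universe. `FC = 1` is the
#' expectation under independent placement; `FC = 0` for disjoint tracks.
#'
#' @param A,B [CoverageTrack]s (or `GRanges`; merged internally).
#' @param genome a [GenomeInfoDb::Seqinfo] with chromosome lengths.
#' @param exclude optional regions removed from the universe.
#' @return a [ForbesResult].
#' @export
forbesCoefficient <- function(A, B, genome, exclude = NULL) {
    grA <- .restrictTrack(A, exclude)
    grB <- .restrictTrack(B, exclude)
    G <- .effectiveGenomeBp(genome, exclude)
    if (G <= 0) stop("effective genome length must be > 0")
    cA <- sum(as.numeric(width(grA)))
    cB <- sum(as.numeric(width(grB)))
    if (cA == 0 || cB == 0)
        stop("Forbes coefficient undefined for an empty track")
    O <- .overlapBp(grA, grB)
    new("ForbesResult", fc = O * G / (cA * cB), overlapBp = O,
        coverageA = cA, coverageB = cB, genomeBp = G)
}

#' Randomly relocate a track's intervals within the genome
#'
#' Places every interval uniformly at random on its own chromosome (the
#' per-chromosome interval length multiset is preserved), avoiding excluded
#' regions; placements may overlap each other and are merged afterwards, so
#' the shuffled coverage is at most the original. This is the null model
#' used by [forbesPermutationTest()].
#'
#' @param track a [CoverageTrack] (or `GRanges`).
#' @param genome a `Seqinfo` with chromosome lengths.
#' @param exclude optional regions that shuffled intervals must not touch.
#' @param seed optional integer for reproducible placement; with `NULL` the
#'   current RNG stream is used.
#' @param maxTries resampling rounds before giving up on a crowded
#'   chromosome.
#' @return a [CoverageTrack].
#' @export
shuffleTrack <- function(track, genome, exclude = NULL, seed = NULL,
                         maxTries = 100) {
    gr <- granges(as(track, "GRanges"))
    doShuffle <- function()
        as(.shuffleGr(gr, genome, exclude, maxTries), "CoverageTrack")
    if (is.null(seed)) doShuffle() else withr::with_seed(seed, doShuffle())
}

## overlap bp of two reduced (disjoint-interval) GRanges: with both inputs
## merged, each overlap segment appears in exactly one hit pair
.overlapBp <- function(grA, grB) {
    h <- GenomicRanges::findOverlaps(grA, grB, ignore.strand = TRUE)
    if (length(h) == 0L) return(0)
    qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
    sum(as.numeric(pmin(end(grA)[qh], end(grB)[sh]) -
                   pmax(start(grA)[qh], start(grB)[sh]) + 1))
}

## uniform relocation of interval widths on one chromosome, as reduced
## IRanges; rejection-sampled against an excluded IRanges set
.shuffleIRanges <- function(w, L, exclude = NULL, maxTries = 100) {
    starts <- rep(NA_real_, length(w))
    todo <- seq_along(w)
    for (it in seq_len(maxTries)) {
        cand <- 1 + floor(stats::runif(length(todo)) * (L - w[todo] + 1))
        if (!is.null(exclude)) {
            bad <- IRanges::overlapsAny(IRanges(cand, width = w[todo]),
                                        exclude)
        } else bad <- rep(FALSE, length(todo))
        starts[todo[!bad]] <- cand[!bad]
        todo <- todo[bad]
        if (!length(todo)) break
    }
    if (length(todo))
        stop("could not place ", length(todo), " interval(s) after ",
             maxTries, " attempts")
    IRanges::reduce(IRanges(starts, width = w))
}

## uniform per-chromosome relocation returning a plain reduced GRanges
.shuffleGr <- function(gr, genome, exclude = NULL, maxTries = 100) {
    exGr <- if (!is.null(exclude) && length(exclude))
        granges(as(exclude, "GRanges")) else NULL
    chroms <- as.character(seqnames(gr))
    uch <- unique(chroms)
    outChrom <- character(0); outStart <- numeric(0); outW <- numeric(0)
    for (ch in uch) {
        w <- width(gr)[chroms == ch]
        L <- seqlengths(genome)[[ch]]
        if (is.na(L)) stop("no length for chromosome ", ch)
        if (any(w > L)) stop("interval longer than chromosome ", ch)
        starts <- rep(NA_real_, length(w))
        todo <- seq_along(w)
        for (it in seq_len(maxTries)) {
            cand <- 1 + floor(stats::runif(length(todo)) * (L - w[todo] + 1))
            if (!is.null(exGr)) {
                cgr <- GRanges(ch, IRanges(cand, width = w[todo]))
                bad <- IRanges::overlapsAny(cgr, exGr, ignore.strand = TRUE)
            } else bad <- rep(FALSE, length(todo))
            starts[todo[!bad]] <- cand[!bad]
            todo <- todo[bad]
            if (!length(todo)) break
        }
        if (length(todo))
            stop("could not place ", length(todo), " interval(s) on ",
                 ch, " after ", maxTries, " attempts")
        outChrom <- c(outChrom, rep(ch, length(w)))
        outStart <- c(outStart, starts)
        outW <- c(outW, w)
    }
    GenomicRanges::reduce(GRanges(outChrom, IRanges(outStart, width = outW)))
}

#' Permutation test for Forbes-coefficient co-occurrence
#'
#' Shuffles track `B` `M` times with [shuffleTrack()] and reports
#' `p = (1 + #\{FC_perm >= FC_obs\}) / (M + 1)`, the standard add-one
#' permutation p-value (bounded below by `1/(M+1)`).
#'
#' @param A,B [CoverageTrack]s.
#' @param genome a `Seqinfo`.
#' @param exclude optional excluded regions (shared by observed and null).
#' @param M number of permutations (>= 19).
#' @param seed integer seed for the permutation stream.
#' @return a [ForbesResult] carrying `pvalue` and `nPerm`.
#' @export
forbesPermutationTest <- function(A, B, genome, exclude = NULL, M = 99,
                                  seed = 1) {
    stopifnot(M >= 19)
    obs <- forbesCoefficient(A, B, genome, exclude)
    grA <- .restrictTrack(A, exclude)
    grB <- .restrictTrack(B, exclude)
    G <- obs@genomeBp
    ## per-chromosome IRanges views: the permutation loop stays in light
    ## IRanges arithmetic instead of rebuilding GRanges per shuffle
    chB <- as.character(seqnames(grB))
    uch <- unique(chB)
    aByChrom <- lapply(uch, function(ch) {
        sel <- as.character(seqnames(grA)) == ch
        IRanges(start(grA)[sel], end(grA)[sel])
    })
    exByChrom <- lapply(uch, function(ch) {
        if (is.null(exclude) || !length(exclude)) return(NULL)
        ex <- granges(as(exclude, "GRanges"))
        sel <- as.character(seqnames(ex)) == ch
        if (!any(sel)) NULL else IRanges(start(ex)[sel], end(ex)[sel])
    })
    wByChrom <- lapply(uch, function(ch) width(grB)[chB == ch])
    LByChrom <- seqlengths(genome)[uch]
    cA <- obs@coverageA
    perm <- withr::with_seed(seed, vapply(seq_len(M), function(i) {
        O <- 0; cB <- 0
        for (k in seq_along(uch)) {
            ir <- .shuffleIRanges(wByChrom[[k]], LByChrom[[k]],
                                  exByChrom[[k]])
            cB <- cB + sum(as.numeric(IRanges::width(ir)))
            h <- IRanges::findOverlaps(aByChrom[[k]], ir)
            if (length(h)) {
                qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
                O <- O + sum(as.numeric(
                    pmin(end(aByChrom[[k]])[qh], end(ir)[sh]) -
                    pmax(start(aByChrom[[k]])[qh], start(ir)[sh]) + 1))
            }
        }
        O * G / (cA * cB)
    }, numeric(1)))
    p <- (1 + sum(perm >= forbes(obs))) / (M + 1)
    new("ForbesResult", fc = obs@fc, overlapBp = obs@overlapBp,
        coverageA = obs@coverageA, coverageB = obs@coverageB,
        genomeBp = obs@genomeBp, pvalue = p, nPerm = as.numeric(M))
}

#' Pairwise Forbes-coefficient matrix over several tracks
#'
#' @param tracks named list of [CoverageTrack]s (>= 2).
#' @param genome a `Seqinfo`.
#' @param exclude optional excluded regions.
#' @return a symmetric numeric matrix of Forbes coefficients; the diagonal
#'   entry for track *i* equals `G / coverage_i` (a track compared with
#'   itself).
#' @export
pairwiseForbesMatrix <- function(tracks, genome, exclude = NULL) {
    stopifnot(is.list(tracks), length(tracks) >= 2,
              !is.null(names(tracks)))
    n <- length(tracks)
    m <- matrix(NA_real_, n, n, dimnames = list(names(tracks), names(tracks)))
    for (i in seq_len(n)) for (j in i:n) {
        fc <- forbes(forbesCoefficient(tracks[[i]], tracks[[j]], genome,
                                       exclude))
        m[i, j] <- fc
        m[j, i] <- fc
    }
    m
}
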