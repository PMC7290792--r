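#' @include AllClasses.R
NULL

#' SyntheticConfig: study conditions for the cistrome simulator
#'
#' Bundles the parameters of the synthetic genome, gene models and
#' co-localized peak-set pair. The defaults are the conditions the rest of
#' the package is exercised under: a 100 Mb genome in four chromosomes, two
#' peak sets of 2,000 peaks each, half of set B planted with 20 bp Gaussian
#' summit jitter around set A summits, lognormal peak lengths around 400 bp
#' (typical called-peak widths), exponential scores and a 1% blacklist.
#'
#' @slot chromLengths chromosome lengths in bp.
#' @slot nGenes number of genes.
#' @slot nPeaksA,nPeaksB peak counts of sets A and B.
#' @slot rho fraction of B peaks planted co-localized with A peaks, in [0,1].
#' @slot sigma Gaussian summit jitter of planted peaks (bp).
#' @slot peakLengthMeanLog,peakLengthSdLog lognormal peak-length parameters.
#' @slot scoreRate rate of the exponential score distribution.
#' @slot blacklistFraction approximate genome fraction covered by the
#'   blacklist, in [0, 1).
#' @slot seed integer seed; all generators are deterministic given it.
#' @export
setClass("SyntheticConfig",
         representation(chromLengths = "numeric", nGenes = "numeric",
                        nPeaksA = "numeric", nPeaksB = "numeric",
                        rho = "numeric", sigma = "numeric",
                        peakLengthMeanLog = "numeric",
                        peakLengthSdLog = "numeric", scoreRate = "numeric",
                        blacklistFraction = "numeric", seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (any(object@chromLengths <= 0)) msg <- c(msg, "chromosome lengths must be > 0")
    if (object@nGenes <= 0 || object@nPeaksA <= 0 || object@nPeaksB <= 0)
        msg <- c(msg, "counts must be > 0")
    if (object@rho < 0 || object@rho > 1) msg <- c(msg, "rho must be in [0, 1]")
    if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
    if (object@blacklistFraction < 0 || object@blacklistFraction >= 1)
        msg <- c(msg, "blacklistFraction must be in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' @param chromLengths chromosome lengths in bp.
#' @param nGenes,nPeaksA,nPeaksB counts.
#' @param rho planted co-localization fraction.
#' @param sigma summit jitter sd (bp).
#' @param peakLengthMeanLog,peakLengthSdLog lognormal peak-length parameters.
#' @param scoreRate exponential score rate.
#' @param blacklistFraction blacklist genome fraction.
#' @param seed integer seed.
#' @return a `SyntheticConfig`.
#' @rdname SyntheticConfig-class
#' @export
syntheticConfig <- function(chromLengths = rep(25e6, 4), nGenes = 1000,
                            nPeaksA = 2000, nPeaksB = 2000, rho = 0.5,
                            sigma = 20, peakLengthMeanLog = log(400),
                            peakLengthSdLog = 0.25, scoreRate = 0.1,
                            blacklistFraction = 0.01, seed = 1) {
    obj <- new("SyntheticConfig", chromLengths = chromLengths,
               nGenes = nGenes, nPeaksA = nPeaksA, nPeaksB = nPeaksB,
               rho = rho, sigma = sigma,
               peakLengthMeanLog = peakLengthMeanLog,
               peakLengthSdLog = peakLengthSdLog, scoreRate = scoreRate,
               blacklistFraction = blacklistFraction, seed = seed)
    validObject(obj)
    obj
}

#' Generate a synthetic genome and blacklist
#'
#' Chromosomes `chr1..chrK` with the configured lengths; the blacklist is a
#' set of random 5 kb intervals covering approximately
#' `blacklistFraction` of the genome (slightly less after merging).
#' Deterministic given `config@seed`.
#'
#' @param config a [syntheticConfig()].
#' @return `list(genome = Seqinfo, blacklist = CoverageTrack)`.
#' @export
generateGenome <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    lens <- config@chromLengths
    genome <- Seqinfo(sprintf("chr%d", seq_along(lens)), seqlengths = lens,
                      genome = "synthetic")
    blkLen <- 5000
    blacklist <- withr::with_seed(config@seed, {
        nb <- round(config@blacklistFraction * lens / blkLen)
        chrom <- rep(sprintf("chr%d", seq_along(lens)), nb)
        s <- 1 + floor(stats::runif(sum(nb)) * (rep(lens, nb) - blkLen + 1))
        CoverageTrack(GRanges(chrom, IRanges(s, width = blkLen)))
    })
    if (length(blacklist)) {
        GenomeInfoDb::seqlevels(blacklist) <- seqnames(genome)
        seqinfo(blacklist) <- genome
    }
    list(genome = genome, blacklist = blacklist)
}

## uniform placement of intervals of widths w on chromosomes 'chrom',
## avoiding 'avoid'; bounded retries
.placeUniform <- function(chrom, w, genome, avoid = NULL, maxTries = 200) {
    starts <- rep(NA_real_, length(w))
    L <- seqlengths(genome)[chrom]
    todo <- seq_along(w)
    for (it in seq_len(maxTries)) {
        cand <- 1 + floor(stats::runif(length(todo)) * (L[todo] - w[todo] + 1))
        if (!is.null(avoid) && length(avoid)) {
            cgr <- GRanges(chrom[todo], IRanges(cand, width = w[todo]))
            bad <- IRanges::overlapsAny(cgr, granges(as(avoid, "GRanges")),
                                        ignore.strand = TRUE)
        } else bad <- rep(FALSE, length(todo))
        starts[todo[!bad]] <- cand[!bad]
        todo <- todo[bad]
        if (!length(todo)) break
    }
    if (length(todo))
        stop("could not place ", length(todo),
             " interval(s) after ", maxTries, " attempts")
    starts
}

#' Generate non-overlapping synthetic gene models
#'
#' Genes are placed uniformly (spans non-overlapping, lengths uniform in
#' 2-20 kb, random strands) with 2-10 exons each; the first and last exon
#' end at the gene extremities, so the TSS falls in the first exon as for
#' real gene models. Deterministic given `config@seed`.
#'
#' @param config a [syntheticConfig()].
#' @param genome the `Seqinfo` from [generateGenome()].
#' @return a [GeneModels] object.
#' @export
generateGeneModels <- function(config, genome) {
    stopifnot(is(config, "SyntheticConfig"))
    nG <- config@nGenes
    lens <- seqlengths(genome)
    if (sum(as.numeric(lens)) < nG * 40000)
        stop("genome too small for ", nG, " genes")
    withr::with_seed(config@seed + 1, {
        chrom <- sample(seqnames(genome), nG, replace = TRUE,
                        prob = lens / sum(as.numeric(lens)))
        gl <- floor(stats::runif(nG, 2000, 20000))
        placed <- GRanges()
        starts <- rep(NA_real_, nG)
        todo <- seq_len(nG)
        for (it in 1:200) {
            cand <- 1 + floor(stats::runif(length(todo)) *
                              (lens[chrom[todo]] - gl[todo] + 1))
            cgr <- GRanges(chrom[todo], IRanges(cand, width = gl[todo]))
            bad <- IRanges::overlapsAny(cgr, placed)
            sh <- GenomicRanges::findOverlaps(cgr, cgr)
            dup <- S4Vectors::queryHits(sh) < S4Vectors::subjectHits(sh)
            bad[S4Vectors::subjectHits(sh)[dup]] <- TRUE
            placed <- suppressWarnings(c(placed, cgr[!bad]))
            starts[todo[!bad]] <- cand[!bad]
            todo <- todo[bad]
            if (!length(todo)) break
        }
        if (length(todo)) stop("could not place all genes without overlap")
        st <- sample(c("+", "-"), nG, replace = TRUE)
        ord <- order(match(chrom, seqnames(genome)), starts)
        chrom <- chrom[ord]; starts <- starts[ord]; gl <- gl[ord]; st <- st[ord]
        genes <- GRanges(chrom, IRanges(starts, width = gl), strand = st,
                         seqinfo = genome)
        mcols(genes)$gene_id <- sprintf("G%05d", seq_len(nG))
        exons <- GRangesList(lapply(seq_len(nG), function(i) {
            m <- sample(2:10, 1)
            cuts <- sort(sample.int(gl[i] - 2L, 2L * m - 2L)) + starts[i]
            bounds <- c(starts[i], cuts, starts[i] + gl[i])
            es <- bounds[seq(1, 2 * m - 1, by = 2)]
            ee <- bounds[seq(2, 2 * m, by = 2)] - 1
            ee[m] <- starts[i] + gl[i] - 1
            GRanges(chrom[i], IRanges(es, ee))
        }))
        GeneModels(genes, exons)
    })
}

#' Generate a pair of peak sets with known co-localization ground truth
#'
#' Set A is placed uniformly outside the blacklist. A fraction `rho` of set
#' B is "planted": each planted peak picks an A partner (without
#' replacement while possible, else with replacement) and places its summit
#' at the partner summit plus `round(Normal(0, sigma))` jitter (redrawn if
#' it would leave the chromosome); its interval is drawn so the summit lies
#' inside it and inside the chromosome. The remaining B peaks are uniform
#' background outside the blacklist. Scores are exponential; summits of
#' non-planted peaks are uniform within their peak. Deterministic given
#' `config@seed`.
#'
#' @param config a [syntheticConfig()].
#' @param genome the `Seqinfo` from [generateGenome()].
#' @param blacklist the blacklist `CoverageTrack` (may be empty).
#' @return `list(A = PeakSet, B = PeakSet, truth = data.frame)` where
#'   `truth` has one row per B peak: `name`, `planted`, `partner` (A peak
#'   name or NA), `jitter` (bp or NA).
#' @export
generatePeaksetPair <- function(config, genome, blacklist = CoverageTrack()) {
    stopifnot(is(config, "SyntheticConfig"))
    nA <- config@nPeaksA; nB <- config@nPeaksB
    lens <- seqlengths(genome)
    prob <- lens / sum(as.numeric(lens))
    withr::with_seed(config@seed + 2, {
        drawW <- function(n) pmax(50, round(stats::rlnorm(
            n, config@peakLengthMeanLog, config@peakLengthSdLog)))
        ## ---- set A ----
        wA <- drawW(nA)
        chA <- sample(seqnames(genome), nA, replace = TRUE, prob = prob)
        sA <- .placeUniform(chA, wA, genome, avoid = blacklist)
        sumA <- sA + floor(stats::runif(nA) * wA)
        nameA <- sprintf("A_%05d", seq_len(nA))
        grA <- GRanges(chA, IRanges(sA, width = wA), seqinfo = genome,
                       name = nameA, score = stats::rexp(nA, config@scoreRate),
                       summit = as.integer(sumA))
        ## ---- set B ----
        nPlant <- floor(config@rho * nB)
        partner <- if (nPlant > 0) {
            if (nA >= nPlant) sample.int(nA, nPlant)
            else sample.int(nA, nPlant, replace = TRUE)
        } else integer(0)
        wB <- drawW(nB)
        chB <- character(nB); startB <- numeric(nB); sumB <- numeric(nB)
        jitter <- rep(NA_real_, nB)
        if (nPlant > 0) {
            chB[1:nPlant] <- as.character(chA[partner])
            Lp <- lens[chB[1:nPlant]]
            j <- round(stats::rnorm(nPlant, 0, config@sigma))
            s <- sumA[partner] + j
            bad <- which(s < 1 | s > Lp)
            while (length(bad)) {
                j[bad] <- round(stats::rnorm(length(bad), 0, config@sigma))
                s[bad] <- sumA[partner[bad]] + j[bad]
                bad <- bad[s[bad] < 1 | s[bad] > Lp[bad]]
            }
            jitter[1:nPlant] <- j
            sumB[1:nPlant] <- s
            ## interval containing the summit, inside the chromosome
            sMin <- pmax(1, s - wB[1:nPlant] + 1)
            sMax <- pmin(s, Lp - wB[1:nPlant] + 1)
            startB[1:nPlant] <- sMin + floor(stats::runif(nPlant) *
                                             (sMax - sMin + 1))
        }
        if (nPlant < nB) {
            bg <- (nPlant + 1):nB
            chB[bg] <- sample(seqnames(genome), length(bg), replace = TRUE,
                              prob = prob)
            startB[bg] <- .placeUniform(chB[bg], wB[bg], genome,
                                        avoid = blacklist)
            sumB[bg] <- startB[bg] + floor(stats::runif(length(bg)) * wB[bg])
        }
        nameB <- sprintf("B_%05d", seq_len(nB))
        grB <- GRanges(chB, IRanges(startB, width = wB), seqinfo = genome,
                       name = nameB, score = stats::rexp(nB, config@scoreRate),
                       summit = as.integer(sumB))
        truth <- data.frame(name = nameB,
                            planted = seq_len(nB) <= nPlant,
                            partner = c(nameA[partner],
                                        rep(NA_character_, nB - nPlant)),
                            jitter = jitter)
        list(A = PeakSet(grA, label = "A", seqinfo = genome),
             B = PeakSet(grB, label = "B", seqinfo = genome),
             truth = truth)
    })
}

#' Generate a pathway collection with one spiked (enriched) pathway
#'
#' Draws `nPathways` pathways uniformly from the gene universe, then
#' replaces part of one designated pathway with genes from a candidate
#' list: its candidate overlap is a hypergeometric draw shifted upward by
#' `spikeShift` genes, so the spiked pathway is genuinely over-represented
#' in the candidate list while all others follow the null.
#'
#' @param genes character vector, the gene universe.
#' @param nPathways number of pathways.
#' @param sizeRange integer range of pathway sizes (default 250-750; sizes
#'   large enough that null p-values are close to continuous).
#' @param candidates designated candidate gene list (default: a random 10%
#'   of the universe).
#' @param spikeShift extra candidate genes forced into the spiked pathway
#'   (default 50, about seven null standard deviations at the default
#'   sizes, so the designed enrichment is unambiguous).
#' @param seed integer seed.
#' @return `list(collection = PathwayCollection, spiked = pathway id,
#'   candidates = character vector)`.
#' @export
generateGeneSets <- function(genes, nPathways = 50,
                             sizeRange = c(250, 750), candidates = NULL,
                             spikeShift = 50, seed = 1) {
    genes <- unique(as.character(genes))
    N <- length(genes)
    stopifnot(nPathways >= 1, max(sizeRange) <= N)
    withr::with_seed(seed, {
        if (is.null(candidates))
            candidates <- sample(genes, max(1, round(0.1 * N)))
        candidates <- intersect(unique(candidates), genes)
        nC <- length(candidates)
        other <- setdiff(genes, candidates)
        sizes <- sample(sizeRange[1]:sizeRange[2], nPathways, replace = TRUE)
        sets <- lapply(sizes, function(K) sample(genes, K))
        spikedIdx <- sample.int(nPathways, 1)
        K <- sizes[spikedIdx]
        k0 <- stats::rhyper(1, nC, N - nC, K)
        k <- min(K, nC, k0 + spikeShift)
        sets[[spikedIdx]] <- c(sample(candidates, k),
                               sample(other, K - k))
        ids <- sprintf("PW%04d", seq_len(nPathways))
        names(sets) <- ids
        list(collection = PathwayCollection(
                 sets, pathwayNames = sprintf("synthetic pathway %d",
                                              seq_len(nPathways))),
             spiked = ids[spikedIdx], candidates = candidates)
    })
}
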