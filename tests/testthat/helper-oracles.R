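suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

## build a PeakSet from plain vectors (1-based closed coordinates)
makePeaks <- function(chrom, start, end, summit = NULL, score = NULL,
                      name = NULL, label = "test", seqinfo = NULL) {
    n <- length(start)
    if (is.null(summit)) summit <- floor((start + end) / 2)
    if (is.null(score)) score <- rep(1, n)
    if (is.null(name)) name <- sprintf("%s_%03d", label, seq_len(n))
    gr <- GRanges(chrom, IRanges(start, end), name = name, score = score,
                  summit = as.integer(summit))
    PeakSet(gr, label = label, seqinfo = seqinfo)
}

## brute-force nearest-subject search with the package's tie rule:
## minimal |summit distance|, then smallest subject start, then name
bruteNearestPairs <- function(query, subject, maxDist) {
    qc <- as.character(seqnames(query)); qs <- peakSummits(query)
    sc <- as.character(seqnames(subject)); ss <- peakSummits(subject)
    sstart <- start(subject); sname <- peakNames(subject)
    byChrom <- split(seq_along(ss), sc)
    outQ <- character(0); outS <- character(0); outD <- integer(0)
    for (i in seq_along(qs)) {
        cand <- byChrom[[qc[i]]]
        if (is.null(cand)) next
        d <- abs(ss[cand] - qs[i])
        dmin <- min(d)
        if (dmin > maxDist) next
        best <- cand[d == dmin]
        best <- best[order(sstart[best], sname[best])][1]
        outQ <- c(outQ, peakNames(query)[i])
        outS <- c(outS, sname[best])
        outD <- c(outD, dmin)
    }
    if (!length(outQ)) return(NULL)
    data.frame(queryName = outQ, subjectName = outS, distance = outD)
}

## dense per-bp boolean coverage oracle (small genomes only)
denseCoverage <- function(gr, chromLens) {
    lapply(names(chromLens), function(ch) {
        v <- logical(chromLens[[ch]])
        sel <- as.character(seqnames(gr)) == ch
        for (i in which(sel)) v[start(gr)[i]:end(gr)[i]] <- TRUE
        v
    }) |> setNames(names(chromLens))
}

denseForbesParts <- function(A, B, chromLens) {
    a <- denseCoverage(as(A, "GRanges"), chromLens)
    b <- denseCoverage(as(B, "GRanges"), chromLens)
    list(overlap = sum(mapply(function(x, y) sum(x & y), a, b)),
         cA = sum(vapply(a, sum, 0)), cB = sum(vapply(b, sum, 0)))
}

## independent hypergeometric upper tail: explicit sum of choose() terms
chooseSumTail <- function(k, n, K, N) {
    i <- k:min(n, K)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## small random PeakSet on a given genome
randomPeaks <- function(n, chromLens, label, width = 200) {
    chrom <- sample(names(chromLens), n, replace = TRUE)
    start <- floor(runif(n, 1, unlist(chromLens)[chrom] - width)) + 1
    summit <- start + floor(runif(n) * width)
    makePeaks(chrom, start, start + width - 1, summit = summit,
              score = runif(n), label = label)
}

## two-exon '+'/'-' gene helper: exons as list of c(start, end), 1-based
makeGenes <- function(chrom, start, end, strand, ids, exons = NULL) {
    genes <- GRanges(chrom, IRanges(start, end), strand = strand,
                     gene_id = ids)
    if (is.null(exons))
        exons <- lapply(seq_along(genes), function(i)
            GRanges(chrom[i], IRanges(start[i], end[i])))
    else
        exons <- lapply(seq_along(genes), function(i) {
            m <- do.call(rbind, exons[[i]])
            GRanges(chrom[i], IRanges(m[, 1], m[, 2]))
        })
    GeneModels(genes, GRangesList(exons))
}
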