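#' @include AllClasses.R
NULL

## All on-disk formats use the BED convention: 0-based half-open intervals,
## summits serialized as offsets from the interval start. In memory
## everything is a GRanges (1-based closed); the converters below are the
## only place the two conventions meet.

.splitFields <- function(lines) strsplit(trimws(lines, "right"), "[ \t]+")

.asNum <- function(x, path, ln, what) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v)))
        stop(sprintf("parse error in '%s' at line %d: non-numeric %s",
                     path, ln[which(is.na(v))[1L]], what))
    v
}

#' Read a chromosome-sizes table
#'
#' @param path two-column TSV (chromosome name, length in bp).
#' @param assembly assembly label stored in the returned object.
#' @return a [GenomeInfoDb::Seqinfo].
#' @export
readChromSizes <- function(path, assembly = NA_character_) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    f <- .splitFields(lines)
    bad <- which(lengths(f) < 2L)
    if (length(bad))
        stop(sprintf("parse error in '%s' at line %d: expected 2 fields",
                     path, bad[1L]))
    nm <- vapply(f, `[`, "", 1L)
    len <- .asNum(vapply(f, `[`, "", 2L), path, seq_along(f), "length")
    if (anyDuplicated(nm))
        stop("duplicate chromosome name(s): ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    if (any(len <= 0)) stop("chromosome lengths must be > 0")
    Seqinfo(nm, seqlengths = len, genome = assembly)
}

#' Read called peaks from narrowPeak or BED
#'
#' narrowPeak (ENCODE, 10 columns) carries a per-peak summit offset in
#' column 10 and a signalValue in column 7; the peak score is taken from
#' signalValue when it is >= 0 (MACS ranks peaks by signal), falling back to
#' the BED score column otherwise. Plain BED (>= 3 columns) has no summit;
#' the summit is set to the floor of the interval midpoint.
#'
#' Records whose summit offset falls outside the peak interval are dropped
#' with a warning; a narrowPeak offset of -1 (summit not reported) also
#' falls back to the midpoint. Malformed lines raise an error naming the
#' line number.
#'
#' @param path input file.
#' @param format `"narrowPeak"` or `"bed"`.
#' @param label factor name for the resulting set (default: file base name).
#' @param seqinfo optional `Seqinfo`; chromosome names must match exactly.
#' @return a [PeakSet], sorted by coordinate.
#' @export
readPeaks <- function(path, format = c("narrowPeak", "bed"),
                      label = NULL, seqinfo = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (is.null(label))
        label <- sub("\\.[^.]*$", "", basename(path))
    lines <- readLines(path)
    keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
        !startsWith(lines, "track") & !startsWith(lines, "browser")
    f <- .splitFields(lines[keep])
    ln <- which(keep)
    minCols <- if (format == "narrowPeak") 10L else 3L
    bad <- which(lengths(f) < minCols)
    if (length(bad))
        stop(sprintf("parse error in '%s' at line %d: expected >= %d fields",
                     path, ln[bad[1L]], minCols))
    if (length(f) == 0L) {
        gr0 <- GRanges()
        mcols(gr0) <- DataFrame(name = character(0), score = numeric(0),
                                summit = integer(0))
        return(PeakSet(gr0, label = label, seqinfo = seqinfo))
    }
    col <- function(i) vapply(f, `[`, "", i)
    chrom <- col(1L)
    start0 <- .asNum(col(2L), path, ln, "start")
    end0 <- .asNum(col(3L), path, ln, "end")
    if (any(start0 < 0) || any(end0 <= start0))
        stop(sprintf("parse error in '%s' at line %d: need 0 <= start < end",
                     path, ln[which(start0 < 0 | end0 <= start0)[1L]]))
    n <- length(f)
    name <- if (all(lengths(f) >= 4L)) col(4L) else sprintf("peak_%d", seq_len(n))
    bedScore <- if (all(lengths(f) >= 5L))
        .asNum(col(5L), path, ln, "score") else rep(0, n)
    mid1 <- floor((start0 + end0) / 2) + 1
    if (format == "narrowPeak") {
        signal <- .asNum(col(7L), path, ln, "signalValue")
        score <- ifelse(signal >= 0, signal, bedScore)
        offset <- .asNum(col(10L), path, ln, "summit offset")
        summit1 <- ifelse(offset == -1, mid1, start0 + offset + 1)
        bad <- offset != -1 & (offset < 0 | offset >= end0 - start0)
        if (any(bad)) {
            warning(sprintf(
                "dropping %d record(s) with summit offset outside the interval (e.g. line %d)",
                sum(bad), ln[which(bad)[1L]]))
            keep2 <- !bad
            chrom <- chrom[keep2]; start0 <- start0[keep2]; end0 <- end0[keep2]
            name <- name[keep2]; score <- score[keep2]; summit1 <- summit1[keep2]
        }
    } else {
        score <- bedScore
        summit1 <- mid1
    }
    gr <- GRanges(chrom, IRanges(start0 + 1, end0),
                  name = name, score = score, summit = as.integer(summit1))
    PeakSet(gr, label = label, seqinfo = seqinfo)
}

#' Write a PeakSet as ENCODE narrowPeak
#'
#' The score is written to the signalValue column (7) and the summit as an
#' offset from the interval start (column 10), so that reading the file back
#' with [readPeaks()] reproduces coordinates, scores and summits exactly.
#'
#' @param x a `PeakSet`.
#' @param path output file.
#' @export
writePeaks <- function(x, path) {
    df <- data.frame(
        chrom = as.character(seqnames(x)),
        start = sprintf("%d", start(x) - 1L),
        end = sprintf("%d", end(x)),
        name = peakNames(x),
        score = 0L, strand = ".",
        signalValue = peakScores(x), pValue = -1, qValue = -1,
        peak = sprintf("%d", peakSummits(x) - start(x)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write plain BED (0-based half-open)
#'
#' @param gr a `GRanges` (e.g. a `CoverageTrack` or blacklist).
#' @param path output file.
#' @export
writeBed <- function(gr, path) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = sprintf("%d", start(gr) - 1L),
                     end = sprintf("%d", end(gr)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a blacklist (or any region set) as a CoverageTrack
#'
#' @param path BED file (>= 3 columns).
#' @param seqinfo optional `Seqinfo`.
#' @return a [CoverageTrack] (merged intervals).
#' @export
readRegions <- function(path, seqinfo = NULL) {
    lines <- readLines(path)
    keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
    f <- .splitFields(lines[keep])
    ln <- which(keep)
    bad <- which(lengths(f) < 3L)
    if (length(bad))
        stop(sprintf("parse error in '%s' at line %d: expected >= 3 fields",
                     path, ln[bad[1L]]))
    if (!length(f)) return(CoverageTrack())
    chrom <- vapply(f, `[`, "", 1L)
    start0 <- .asNum(vapply(f, `[`, "", 2L), path, ln, "start")
    end0 <- .asNum(vapply(f, `[`, "", 3L), path, ln, "end")
    gr <- GRanges(chrom, IRanges(start0 + 1, end0))
    if (!is.null(seqinfo)) {
        unknown <- setdiff(as.character(unique(seqnames(gr))), seqnames(seqinfo))
        if (length(unknown))
            stop("chromosome name(s) absent from genome: ",
                 paste(unknown, collapse = ", "))
        GenomeInfoDb::seqlevels(gr) <- seqnames(seqinfo)
        seqinfo(gr) <- seqinfo
    }
    CoverageTrack(gr)
}

.parseBlocks <- function(txt, path, ln) {
    pieces <- strsplit(txt, "[,;]")[[1]]
    pieces <- pieces[nzchar(pieces)]
    m <- regmatches(pieces, regexec("^([0-9]+)-([0-9]+)$", pieces))
    if (any(lengths(m) != 3L))
        stop(sprintf("parse error in '%s' at line %d: bad exon block syntax",
                     path, ln))
    s0 <- as.numeric(vapply(m, `[`, "", 2L))
    e0 <- as.numeric(vapply(m, `[`, "", 3L))
    if (any(e0 <= s0))
        stop(sprintf("parse error in '%s' at line %d: empty exon block",
                     path, ln))
    cbind(s0, e0)
}

#' Read gene models from BED12 or a simple TSV
#'
#' BED12: exons are reconstructed from the block fields (blockCount must
#' match blockSizes/blockStarts, else the line is a parse error); strand is
#' required — records without `+`/`-` strand are rejected with a warning,
#' since the TSS cannot be placed without orientation.
#'
#' TSV: six tab-separated columns `id, chrom, strand, TSS, TES, blocks`
#' with TSS/TES as 0-based positions of the first/last transcribed base and
#' blocks as absolute 0-based half-open exon intervals `"a-b;c-d"`.
#'
#' @param path input file.
#' @param format `"bed12"` or `"tsv"`.
#' @param seqinfo optional `Seqinfo`.
#' @return a [GeneModels] object.
#' @export
readGeneModels <- function(path, format = c("bed12", "tsv"), seqinfo = NULL) {
    format <- match.arg(format)
    lines <- readLines(path)
    keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
    f <- .splitFields(lines[keep])
    ln <- which(keep)
    minCols <- if (format == "bed12") 12L else 6L
    bad <- which(lengths(f) < minCols)
    if (length(bad))
        stop(sprintf("parse error in '%s' at line %d: expected %d fields",
                     path, ln[bad[1L]], minCols))
    genes <- GRanges(); exons <- list()
    dropped <- 0L
    for (i in seq_along(f)) {
        r <- f[[i]]
        if (format == "bed12") {
            strand <- r[6L]
            if (!strand %in% c("+", "-")) { dropped <- dropped + 1L; next }
            start0 <- .asNum(r[2L], path, ln[i], "start")
            end0 <- .asNum(r[3L], path, ln[i], "end")
            nBlocks <- .asNum(r[10L], path, ln[i], "blockCount")
            sizes <- as.numeric(strsplit(r[11L], ",")[[1]])
            offs <- as.numeric(strsplit(r[12L], ",")[[1]])
            if (length(sizes) != nBlocks || length(offs) != nBlocks ||
                any(is.na(sizes)) || any(is.na(offs)))
                stop(sprintf(
                    "parse error in '%s' at line %d: blockCount does not match blockSizes/blockStarts",
                    path, ln[i]))
            exS0 <- start0 + offs
            exE0 <- exS0 + sizes
            if (max(exE0) > end0 || min(exS0) < start0)
                stop(sprintf("parse error in '%s' at line %d: blocks outside gene span",
                             path, ln[i]))
            id <- r[4L]
            gene <- GRanges(r[1L], IRanges(start0 + 1, end0), strand = strand,
                            gene_id = id)
        } else {
            strand <- r[3L]
            if (!strand %in% c("+", "-")) { dropped <- dropped + 1L; next }
            tss0 <- .asNum(r[4L], path, ln[i], "TSS")
            tes0 <- .asNum(r[5L], path, ln[i], "TES")
            blocks <- .parseBlocks(r[6L], path, ln[i])
            exS0 <- blocks[, 1L]; exE0 <- blocks[, 2L]
            start0 <- if (strand == "+") tss0 else tes0
            end0 <- if (strand == "+") tes0 + 1 else tss0 + 1
            if (end0 <= start0)
                stop(sprintf("parse error in '%s' at line %d: TSS/TES inconsistent with strand",
                             path, ln[i]))
            id <- r[1L]
            gene <- GRanges(r[2L], IRanges(start0 + 1, end0), strand = strand,
                            gene_id = id)
        }
        genes <- suppressWarnings(c(genes, gene))
        exons[[length(exons) + 1L]] <-
            GRanges(as.character(seqnames(gene)), IRanges(exS0 + 1, exE0))
    }
    if (dropped)
        warning(sprintf("rejected %d gene record(s) without '+'/'-' strand",
                        dropped))
    if (!is.null(seqinfo) && length(genes)) {
        unknown <- setdiff(as.character(unique(seqnames(genes))),
                           seqnames(seqinfo))
        if (length(unknown))
            stop("chromosome name(s) absent from genome: ",
                 paste(unknown, collapse = ", "))
        GenomeInfoDb::seqlevels(genes) <- seqnames(seqinfo)
        seqinfo(genes) <- seqinfo
        exons <- lapply(exons, function(ex) {
            GenomeInfoDb::seqlevels(ex) <- seqnames(seqinfo)
            seqinfo(ex) <- seqinfo
            ex
        })
    }
    GeneModels(genes, GRangesList(exons))
}

#' Write gene models as BED12
#'
#' @param x a `GeneModels` object.
#' @param path output file.
#' @export
writeGeneModels <- function(x, path) {
    g <- geneRanges(x)
    rows <- vapply(seq_along(g), function(i) {
        ex <- BiocGenerics::sort(geneExons(x)[[i]], ignore.strand = TRUE)
        s0 <- start(g)[i] - 1L
        paste(as.character(seqnames(g))[i], sprintf("%d", s0),
              sprintf("%d", end(g)[i]), mcols(g)$gene_id[i], 0L,
              as.character(strand(g))[i], sprintf("%d", s0),
              sprintf("%d", end(g)[i]), "0", length(ex),
              paste0(paste(width(ex), collapse = ","), ","),
              paste0(paste(start(ex) - 1L - s0, collapse = ","), ","),
              sep = "\t")
    }, "")
    writeLines(rows, path)
    invisible(path)
}

#' Read pathway gene sets from a GMT file
#'
#' Each line holds a pathway id, a description and >= 1 member gene id,
#' tab-separated. Duplicate member ids within a pathway are deduplicated;
#' a duplicated pathway id is an error.
#'
#' @param path GMT file.
#' @return a [PathwayCollection].
#' @export
readGeneSets <- function(path) {
    lines <- readLines(path)
    keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
    f <- strsplit(lines[keep], "\t")
    ln <- which(keep)
    bad <- which(lengths(f) < 3L)
    if (length(bad))
        stop(sprintf("parse error in '%s' at line %d: expected >= 3 tab-separated fields",
                     path, ln[bad[1L]]))
    ids <- vapply(f, `[`, "", 1L)
    if (anyDuplicated(ids))
        stop("duplicate pathway id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    sets <- lapply(f, function(r) unique(r[-c(1L, 2L)]))
    names(sets) <- ids
    PathwayCollection(sets, pathwayNames = vapply(f, `[`, "", 2L))
}

#' Write a PathwayCollection as GMT
#'
#' @param x a `PathwayCollection`.
#' @param path output file.
#' @export
writeGeneSets <- function(x, path) {
    rows <- vapply(seq_len(length(x)), function(i) {
        paste(c(pathwayIds(x)[i], pathwayNames(x)[i], geneSets(x)[[i]]),
              collapse = "\t")
    }, "")
    writeLines(rows, path)
    invisible(path)
}

#' Write a chromosome-sizes table
#'
#' @param seqinfo a `Seqinfo`.
#' @param path output file.
#' @export
writeChromSizes <- function(seqinfo, path) {
    writeLines(sprintf("%s\t%d", seqnames(seqinfo), seqlengths(seqinfo)), path)
    invisible(path)
}
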