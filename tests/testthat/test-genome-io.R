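test_that("narrowPeak fields map to peaks: summit offset, signalValue score", {
    f <- withr::local_tempfile(lines = c(
        "chr1\t100\t200\tp1\t0\t.\t13.5\t-1\t-1\t50",
        "chr1\t300\t400\tp2\t7\t.\t-1\t-1\t-1\t-1",
        "chr2\t0\t10\tp3\t0\t.\t2\t-1\t-1\t3"))
    ps <- readPeaks(f, "narrowPeak")
    expect_s4_class(ps, "PeakSet")
    expect_equal(length(ps), 3L)
    ## 0-based [100,200) summit offset 50 -> absolute 0-based 150
    expect_equal(start(ps)[1], 101)
    expect_equal(end(ps)[1], 200)
    expect_equal(peakSummits(ps)[1] - 1L, 150L)
    expect_equal(peakScores(ps)[1], 13.5)
    ## signalValue -1 falls back to the score column; offset -1 -> midpoint
    expect_equal(peakScores(ps)[2], 7)
    expect_equal(peakSummits(ps)[2] - 1L, 350L)
    expect_equal(peakSummits(ps)[3] - 1L, 3L)
})

test_that("BED peaks get floor-midpoint summits and stay sorted", {
    f <- withr::local_tempfile(lines = c(
        "chr2\t500\t600", "chr1\t100\t201", "chr1\t50\t80"))
    ps <- readPeaks(f, "bed")
    ## sorted by (chromosome, start)
    expect_equal(start(ps), c(51, 101, 501))
    ## 0-based floor((100+201)/2) = 150
    expect_equal(peakSummits(ps)[2] - 1L, 150L)
    expect_equal(peakSummits(ps)[1] - 1L, 65L)
})

test_that("read sizes match an independent line count for several files", {
    for (n in c(3L, 5L)) {
        rows <- sprintf("chr1\t%d\t%d", (1:n) * 1000, (1:n) * 1000 + 100)
        f <- withr::local_tempfile(lines = sample(rows))
        ps <- readPeaks(f, "bed")
        expect_equal(length(ps), n)
        expect_false(is.unsorted(start(ps)))
    }
})

test_that("malformed peak lines raise errors naming the line number", {
    f <- withr::local_tempfile(lines = c(
        "chr1\t100\t200\tp\t0\t.\t1\t-1\t-1\t10", "chr1\t300"))
    expect_error(readPeaks(f, "narrowPeak"), "line 2")
    f2 <- withr::local_tempfile(lines = c("chr1\txx\t200"))
    expect_error(readPeaks(f2, "bed"), "line 1")
})

test_that("records with out-of-interval summit offsets are dropped with a warning", {
    f <- withr::local_tempfile(lines = c(
        "chr1\t100\t200\tp1\t0\t.\t1\t-1\t-1\t50",
        "chr1\t300\t400\tp2\t0\t.\t1\t-1\t-1\t150"))
    expect_warning(ps <- readPeaks(f, "narrowPeak"), "summit offset")
    expect_equal(length(ps), 1L)
    expect_equal(peakNames(ps), "p1")
})

test_that("narrowPeak round-trip preserves coordinates, scores and summits", {
    ps <- makePeaks("chr1", c(101, 501), c(300, 700),
                    summit = c(180, 650), score = c(5.25, 1.5),
                    name = c("a", "b"))
    f <- withr::local_tempfile()
    writePeaks(ps, f)
    back <- readPeaks(f, "narrowPeak")
    expect_equal(start(back), start(ps))
    expect_equal(end(back), end(ps))
    expect_equal(peakSummits(back), peakSummits(ps))
    expect_equal(peakScores(back), peakScores(ps))
    expect_equal(peakNames(back), peakNames(ps))
})

test_that("peaks validate against the genome instead of being clipped", {
    si <- GenomeInfoDb::Seqinfo(c("chr1"), 1000)
    f <- withr::local_tempfile(lines = "chrX\t10\t20")
    expect_error(readPeaks(f, "bed", seqinfo = si), "chrX")
    f2 <- withr::local_tempfile(lines = "chr1\t900\t1100")
    ## GRanges itself also warns about the out-of-bound range; the contract
    ## under test is the hard error, not the upstream warning
    expect_error(suppressWarnings(readPeaks(f2, "bed", seqinfo = si)),
                 "beyond chromosome")
})

test_that("BED12 gene models derive TSS/TES and exons from strand", {
    ## '+' gene [1000,5000) blocks [1000,1200) and [4000,5000)
    plus <- "chr1\t1000\t5000\tgp\t0\t+\t1000\t5000\t0\t2\t200,1000,\t0,3000,"
    minus <- "chr1\t1000\t5000\tgm\t0\t-\t1000\t5000\t0\t2\t200,1000,\t0,3000,"
    f <- withr::local_tempfile(lines = c(plus, minus))
    gm <- readGeneModels(f, "bed12")
    expect_equal(length(gm), 2L)
    tss0 <- geneTss(gm) - 1L
    expect_equal(tss0, c(1000L, 4999L))
    ## first exon in gene orientation: '+' -> leftmost, '-' -> rightmost
    expect_equal(start(geneExons(gm)[[1]])[1] - 1L, 1000L)
    expect_equal(start(geneExons(gm)[[2]])[1] - 1L, 4000L)
    expect_equal(mcols(geneRanges(gm))$tes - 1L, c(4999L, 1000L))
})

test_that("gene records without strand are rejected, block mismatch errors", {
    noStrand <- "chr1\t0\t100\tg1\t0\t.\t0\t100\t0\t1\t100,\t0,"
    ok <- "chr1\t0\t100\tg2\t0\t+\t0\t100\t0\t1\t100,\t0,"
    f <- withr::local_tempfile(lines = c(noStrand, ok))
    expect_warning(gm <- readGeneModels(f, "bed12"), "strand")
    expect_equal(geneIds(gm), "g2")
    badBlocks <- "chr1\t0\t100\tg3\t0\t+\t0\t100\t0\t2\t100,\t0,"
    f2 <- withr::local_tempfile(lines = badBlocks)
    expect_error(readGeneModels(f2, "bed12"), "blockCount")
})

test_that("TSV gene models and BED12 writer round-trip", {
    tsv <- c("g1\tchr1\t+\t1000\t4999\t1000-1200;4000-5000",
             "g2\tchr2\t-\t4999\t1000\t1000-1200;4000-5000")
    f <- withr::local_tempfile(lines = tsv)
    gm <- readGeneModels(f, "tsv")
    expect_equal(geneTss(gm) - 1L, c(1000L, 4999L))
    expect_equal(as.character(strand(geneRanges(gm))), c("+", "-"))
    f2 <- withr::local_tempfile()
    writeGeneModels(gm, f2)
    back <- readGeneModels(f2, "bed12")
    expect_equal(geneTss(back), geneTss(gm))
    expect_equal(lengths(geneExons(back)), lengths(geneExons(gm)))
    expect_equal(start(geneRanges(back)), start(geneRanges(gm)))
})

test_that("exon counts match blockCount across a multi-gene fixture", {
    set.seed(11)
    n <- 10
    rows <- vapply(seq_len(n), function(i) {
        nb <- sample(1:4, 1)
        sizes <- sample(50:150, nb, replace = TRUE)
        gaps <- if (nb > 1) sample(100:300, nb - 1, replace = TRUE) else integer(0)
        offs <- cumsum(c(0, sizes[-nb] + gaps))
        span <- offs[nb] + sizes[nb]
        s0 <- i * 10000
        sprintf("chr1\t%d\t%d\tg%02d\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                s0, s0 + span, i, sample(c("+", "-"), 1), s0, s0 + span, nb,
                paste0(paste(sizes, collapse = ","), ","),
                paste0(paste(offs, collapse = ","), ","))
    }, "")
    f <- withr::local_tempfile(lines = rows)
    gm <- readGeneModels(f, "bed12")
    expect_equal(length(gm), n)
    nb <- as.integer(sub(".*\t0\t(\\d+)\t[0-9,]+,\t.*", "\\1", rows))
    expect_equal(unname(lengths(geneExons(gm))), nb)
})

test_that("GMT reading dedups members and rejects duplicate pathway ids", {
    f <- withr::local_tempfile(lines = c(
        "P1\tdesc one\tg1\tg2", "P2\tdesc two\tg1\tg1", "P3\td\tg9\tg8\tg7"))
    gs <- readGeneSets(f)
    expect_equal(length(gs), 3L)
    expect_equal(geneSets(gs)$P1, c("g1", "g2"))
    expect_equal(geneSets(gs)$P2, "g1")
    expect_equal(pathwayNames(gs)[1], "desc one")
    f2 <- withr::local_tempfile(lines = c("P1\td\tg1", "P1\td\tg2"))
    expect_error(readGeneSets(f2), "duplicate pathway")
    f3 <- withr::local_tempfile(lines = "P1\tonly-two-fields")
    expect_error(readGeneSets(f3), "line 1")
})

test_that("chromosome sizes round-trip through Seqinfo", {
    f <- withr::local_tempfile(lines = c("chr1\t1000000", "chr2\t2000000"))
    si <- readChromSizes(f, assembly = "toy")
    expect_equal(unname(GenomeInfoDb::seqlengths(si)), c(1e6, 2e6))
    f2 <- withr::local_tempfile()
    writeChromSizes(si, f2)
    expect_equal(GenomeInfoDb::seqlengths(readChromSizes(f2)),
                 GenomeInfoDb::seqlengths(si))
})
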