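## one hand-built '+' gene that can exercise every element class:
## span [50000, 62000), exon1 [50000,50500), intron1 [50500,52000),
## exon2 [52000,53000), intron2, exon3 [60000,62000)
truthGene <- function() {
    makeGenes("chr1", 50001, 62000, "+", "G1",
              exons = list(list(c(50001, 50500), c(52001, 53000),
                                c(60001, 62000))))
}

test_that("every element class is recovered at its defining position", {
    gm <- truthGene()
    expected <- c(
        "50151" = "tss",             # TSS + 150, inside the +/-200 window
        "49901" = "tss",             # 100 bp upstream still TSS window
        "50400" = "first_exon",      # in exon1, outside the TSS window
        "51000" = "first_intron",    # between exon1 and exon2
        "52500" = "gene_body",       # exon2
        "55000" = "gene_body",       # intron2
        "47001" = "promoter",        # 3 kb upstream
        "40001" = "five_prime_far",  # 10 kb upstream
        "63000" = "three_prime_near",# 1 kb past the TES
        "70000" = "three_prime_far", # 8 kb past the TES
        "95000" = "unassigned",      # 33 kb downstream
        "20000" = "unassigned")      # 30 kb upstream
    got <- assignElement(as.integer(names(expected)), gm, "G1")
    expect_equal(as.character(got$element), unname(expected))
    ## unassigned positions carry no gene id
    expect_true(all(is.na(got$gene_id[got$element == "unassigned"])))
    expect_true(all(!is.na(got$gene_id[got$element != "unassigned"])))
})

test_that("element windows honor the documented boundaries and priorities", {
    gm <- truthGene()
    el <- function(x) as.character(assignElement(x, gm, "G1")$element)
    ## TSS window is inclusive at +/- 200 and beats the first exon
    expect_equal(el(50201), "tss")
    expect_equal(el(50202), "first_exon")
    ## the promoter ends where the 5' far window begins (5 kb upstream)
    expect_equal(el(50001 - 4999), "promoter")
    expect_equal(el(50001 - 5000), "five_prime_far")
    expect_equal(el(50001 - 25000), "five_prime_far")
    expect_equal(el(50001 - 25001), "unassigned")
    ## 3' near/far split 5 kb after the TES (gene end, not the TSS)
    expect_equal(el(62000 + 4999), "three_prime_near")
    expect_equal(el(62000 + 5000), "three_prime_far")
    expect_equal(el(62000 + 25000), "three_prime_far")
    expect_equal(el(62000 + 25001), "unassigned")
})

test_that("minus-strand genes classify in gene orientation", {
    ## '-' gene: TSS at the right end; first exon is the rightmost
    gm <- makeGenes("chr1", 50001, 62000, "-", "G1",
                    exons = list(list(c(50001, 52000), c(60001, 62000))))
    el <- function(x) as.character(assignElement(x, gm, "G1")$element)
    expect_equal(el(62000), "tss")
    expect_equal(el(61000), "first_exon")
    expect_equal(el(55000), "first_intron")
    expect_equal(el(51000), "gene_body")
    expect_equal(el(62000 + 3000), "promoter")       # upstream = right side
    expect_equal(el(62000 + 10000), "five_prime_far")
    expect_equal(el(50001 - 1000), "three_prime_near")
    expect_equal(el(50001 - 10000), "three_prime_far")
})

test_that("element distribution recovers generating proportions and gene order is irrelevant", {
    set.seed(77)
    exA <- list(c(100001, 100600), c(105001, 105600), c(119001, 120000))
    gm <- makeGenes(rep("chr1", 3), c(100001, 300001, 500001),
                    c(120000, 320000, 520000), c("+", "-", "+"),
                    c("gA", "gB", "gC"),
                    exons = list(exA, list(c(300001, 320000)),
                                 list(c(500001, 520000))))
    ## known elements of gA: 60 promoter midpoints, 40 in its second intron
    mids <- c(runif(60, 100001 - 4800, 100000 - 201),
              runif(40, 106001, 118800))
    pr <- new("PairSet", pairs = DataFrame(
        chrom = "chr1", queryName = sprintf("q%d", 1:100),
        querySummit = as.integer(mids), subjectName = "s",
        subjectSummit = as.integer(mids), distance = 0L,
        midpoint = as.integer(mids)),
        maxDistance = 1000, queryLabel = "Q", subjectLabel = "S")
    dist <- elementDistribution(pr, gm)
    expect_equal(sum(dist$count), 100L)
    expect_equal(sum(dist$fraction), 1)
    expect_equal(dist$count[dist$element == "promoter"], 60L)
    expect_equal(dist$count[dist$element == "gene_body"], 40L)
    ## permuting gene input order changes nothing
    gmR <- makeGenes(rep("chr1", 3), c(500001, 100001, 300001),
                     c(520000, 120000, 320000), c("+", "+", "-"),
                     c("gC", "gA", "gB"),
                     exons = list(list(c(500001, 520000)), exA,
                                  list(c(300001, 320000))))
    expect_equal(elementDistribution(pr, gmR), dist)
    ## empty gene list -> everything unassigned
    gm0 <- makeGenes("chr2", 1000, 2000, "+", "far")
    d0 <- elementDistribution(pr, gm0)
    expect_equal(d0$count[d0$element == "unassigned"], 100L)
})

test_that("pair-to-gene mapping applies the 25 kb cutoff with inside-gene override", {
    ## 50 kb gene with three exons so its middle is plain gene body
    gm <- makeGenes("chr1", 100001, 150000, "+", "G1",
                    exons = list(list(c(100001, 101000), c(120001, 121000),
                                      c(149001, 150000))))
    mk <- function(mid, d = 10L) new("PairSet", pairs = DataFrame(
        chrom = "chr1", queryName = "q1", querySummit = as.integer(mid),
        subjectName = "s", subjectSummit = as.integer(mid + d),
        distance = d, midpoint = as.integer(mid + floor(d / 2))),
        maxDistance = 1000, queryLabel = "Q", subjectLabel = "S")
    ## 30 kb upstream of the only TSS and outside the gene: no row
    expect_equal(nrow(mapPairsToGenes(mk(100001 - 30000), gm)), 0L)
    ## inside the gene body 40 kb from the TSS: kept by the override
    inside <- mapPairsToGenes(mk(140001), gm)
    expect_equal(inside$gene_id, "G1")
    expect_equal(inside$element, "gene_body")
    ## 2 kb upstream: promoter row
    up <- mapPairsToGenes(mk(98001), gm)
    expect_equal(up$element, "promoter")
    expect_equal(up$tss_distance, -1995L)
})

test_that("regulatory-gene selection enforces both the window and the pair cutoff", {
    tbl <- data.frame(
        gene_id = c("g1", "g2", "g3", "g4", "g5"),
        tss_distance = c(-100L, 2400L, 2600L, -4999L, 0L),
        pair_distance = c(50L, 150L, 50L, 99L, 100L))
    ## g2 fails the pair cutoff, g3 the window, g5 is not strictly < 100
    expect_equal(selectRegulatoryGenes(tbl), c("g1", "g4"))
    ## tightening any cutoff never grows the list
    base <- selectRegulatoryGenes(tbl)
    expect_true(all(selectRegulatoryGenes(tbl, upstream = 1000) %in% base))
    expect_true(all(selectRegulatoryGenes(tbl, pairDistanceCutoff = 60) %in% base))
    ## known qualifying subset is recovered exactly on a synthetic table
    set.seed(12)
    n <- 60
    tbl2 <- data.frame(gene_id = sprintf("g%02d", 1:n),
                       tss_distance = sample(-8000:4000, n),
                       pair_distance = sample(0:300, n, replace = TRUE))
    want <- with(tbl2, sort(gene_id[tss_distance >= -5000 &
                                    tss_distance <= 2500 &
                                    pair_distance < 100]))
    expect_equal(selectRegulatoryGenes(tbl2), want)
})
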