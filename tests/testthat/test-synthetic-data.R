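smallConfig <- function(...) {
    syntheticConfig(chromLengths = rep(5e6, 2), nGenes = 60,
                    nPeaksA = 300, nPeaksB = 300, ...)
}

test_that("genome generation is deterministic with the configured blacklist share", {
    cfg <- smallConfig(blacklistFraction = 0.02, seed = 4)
    g1 <- generateGenome(cfg)
    g2 <- generateGenome(cfg)
    expect_equal(sum(as.numeric(GenomeInfoDb::seqlengths(g1$genome))), 1e7)
    expect_identical(start(g1$blacklist), start(g2$blacklist))
    frac <- coveredBp(g1$blacklist) / 1e7
    expect_gt(frac, 0.01); expect_lt(frac, 0.03)
    ## zero fraction -> empty blacklist
    g0 <- generateGenome(smallConfig(blacklistFraction = 0))
    expect_equal(length(g0$blacklist), 0L)
})

test_that("generated gene models satisfy every GeneModels invariant", {
    cfg <- smallConfig(seed = 6)
    g <- generateGenome(cfg)
    gm <- generateGeneModels(cfg, g$genome)
    expect_equal(length(gm), 60L)
    expect_true(validObject(gm))
    ## spans non-overlapping (strand-blind)
    expect_true(all(GenomicRanges::countOverlaps(
        geneRanges(gm), geneRanges(gm), ignore.strand = TRUE) == 1L))
    ## TSS equals the strand-appropriate extremity (independent recheck)
    st <- as.character(strand(geneRanges(gm)))
    expect_equal(geneTss(gm),
                 ifelse(st == "+", start(geneRanges(gm)),
                        end(geneRanges(gm))))
    ## 2-10 exons per gene
    expect_true(all(lengths(geneExons(gm)) >= 2 &
                    lengths(geneExons(gm)) <= 10))
})

test_that("rho = 1 with zero jitter makes every B summit a planted A summit", {
    cfg <- smallConfig(rho = 1, sigma = 0, seed = 9)
    g <- generateGenome(cfg)
    pp <- generatePeaksetPair(cfg, g$genome, g$blacklist)
    expect_true(all(pp$truth$planted))
    expect_true(all(peakSummits(pp$B) %in% peakSummits(pp$A)))
    pr <- nearestPairs(pp$B, pp$A, 1000)
    expect_equal(length(pr), length(pp$B))
    expect_true(all(pairDistances(pr) == 0))
})

test_that("rho = 0 plants nothing and generation is seed-deterministic", {
    cfg <- smallConfig(rho = 0, seed = 10)
    g <- generateGenome(cfg)
    pp <- generatePeaksetPair(cfg, g$genome, g$blacklist)
    expect_false(any(pp$truth$planted))
    expect_true(all(is.na(pp$truth$partner)))
    pp2 <- generatePeaksetPair(cfg, g$genome, g$blacklist)
    expect_identical(peakSummits(pp$A), peakSummits(pp2$A))
    expect_identical(peakSummits(pp$B), peakSummits(pp2$B))
    ## A avoids the blacklist
    expect_false(any(IRanges::overlapsAny(as(pp$A, "GRanges"),
                                          as(g$blacklist, "GRanges"))))
})

test_that("generated data round-trip through the readers without loss", {
    cfg <- smallConfig(seed = 2)
    g <- generateGenome(cfg)
    gm <- generateGeneModels(cfg, g$genome)
    pp <- generatePeaksetPair(cfg, g$genome, g$blacklist)
    dir <- withr::local_tempdir()
    writeChromSizes(g$genome, file.path(dir, "chrom.sizes"))
    writeBed(g$blacklist, file.path(dir, "blacklist.bed"))
    writePeaks(pp$A, file.path(dir, "A.narrowPeak"))
    writeGeneModels(gm, file.path(dir, "genes.bed12"))
    si <- readChromSizes(file.path(dir, "chrom.sizes"))
    expect_equal(GenomeInfoDb::seqlengths(si),
                 GenomeInfoDb::seqlengths(g$genome))
    bl <- readRegions(file.path(dir, "blacklist.bed"), seqinfo = si)
    expect_equal(coveredBp(bl), coveredBp(g$blacklist))
    A <- readPeaks(file.path(dir, "A.narrowPeak"), seqinfo = si)
    expect_equal(start(A), start(pp$A))
    expect_equal(peakSummits(A), peakSummits(pp$A))
    expect_equal(peakScores(A), peakScores(pp$A))
    gm2 <- readGeneModels(file.path(dir, "genes.bed12"), seqinfo = si)
    expect_equal(geneTss(gm2), geneTss(gm))
    expect_equal(lengths(geneExons(gm2)), lengths(geneExons(gm)))
})

test_that("planted pairs are recovered with high precision and recall", {
    cfg <- syntheticConfig(chromLengths = rep(25e6, 2), nGenes = 50,
                           nPeaksA = 500, nPeaksB = 500, rho = 0.6,
                           sigma = 50, seed = 14)
    g <- generateGenome(cfg)
    pp <- generatePeaksetPair(cfg, g$genome, g$blacklist)
    pr <- nearestPairs(pp$B, pp$A, 1000)
    tab <- pairTable(pr)
    called <- tab$queryName[tab$distance <= 3 * 50]
    truthTab <- pp$truth[pp$truth$planted, ]
    recall <- mean(truthTab$name %in% called)
    precision <- mean(called %in% truthTab$name)
    expect_gte(recall, 0.9)
    expect_gte(precision, 0.9)
    ## called planted pairs point at the true partner
    m <- merge(tab, truthTab, by.x = "queryName", by.y = "name")
    close <- m[m$distance <= 150, ]
    expect_gt(mean(close$subjectName == close$partner), 0.95)
})

test_that("spiked pathway dominates ORA while sizes stay in range", {
    universe <- sprintf("gene%04d", 1:5000)
    gs <- generateGeneSets(universe, nPathways = 40,
                           sizeRange = c(250, 750), seed = 5)
    sizes <- lengths(geneSets(gs$collection))
    expect_true(all(sizes >= 250 & sizes <= 750))
    expect_equal(length(gs$collection), 40L)
    res <- runOra(gs$candidates, gs$collection, background = universe)
    expect_equal(res$pathway_id[1], gs$spiked)
    ## determinism
    gs2 <- generateGeneSets(universe, nPathways = 40,
                            sizeRange = c(250, 750), seed = 5)
    expect_identical(geneSets(gs$collection), geneSets(gs2$collection))
})

test_that("null pathway p-values are approximately uniform", {
    ## sizes chosen so the discrete hypergeometric support is fine-grained:
    ## with K in 250-750 and n = 1000 of N = 5000, null overlaps have sd
    ## ~6-10 genes, so p-value levels are dense enough for a KS check
    set.seed(90)
    universe <- sprintf("gene%04d", 1:5000)
    candidates <- sample(universe, 1000)
    ps <- numeric(0)
    for (s in 1:5) {
        gs <- generateGeneSets(universe, nPathways = 100,
                               sizeRange = c(250, 750),
                               candidates = candidates, seed = 100 + s)
        res <- runOra(candidates, gs$collection, background = universe)
        ps <- c(ps, res$p_value[res$pathway_id != gs$spiked])
    }
    ks <- suppressWarnings(stats::ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.01)
})
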