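Package: cooccupancy
Title: Genome-Wide Transcription-Factor Peak Co-Occupancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of co-occupancy between transcription-factor cistromes
    from called ChIP-seq peaks: blacklist filtering and top-N peak selection,
    nearest-summit peak pairing with a distance cutoff, signed distance-to-TSS
    profiling with a moving-average summary, assignment of peak pairs to
    genomic elements (promoter, TSS, first exon/intron, gene body, flanking
    windows), Forbes-coefficient genomic co-occurrence with a permutation
    null, mapping of peak pairs to nearest genes, and hypergeometric pathway
    over-representation analysis. Includes a synthetic cistrome simulator
    with known co-localization ground truth so the whole pipeline is testable
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'tss-profile.R'
    'annotation.R'
    'cooccupancy-package.R'
    'cooccurrence.R'
    'enrichment.R'
    'genome-io.R'
    'pairing.R'
    'peak-ops.R'
    'pipeline.R'
    'synthetic-data.R'
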