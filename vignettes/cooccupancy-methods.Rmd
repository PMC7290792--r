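---
title: "Methods: quantifying transcription-factor peak co-occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transcription-factor peak co-occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooccupancy)
```

## Scope and model

`cooccupancy` starts where peak callers stop. Its unit of analysis is a
*peak pair*: a query peak matched to the nearest subject peak by
summit-to-summit distance, with pairs farther than a cutoff (default
1000 bp) discarded. Two factors that bind the same loci produce an excess
of near-zero summit distances over the uniform background expected from
independent binding; the close-pair fraction (distance < 100 bp by
default), the distance histogram, and the Forbes coefficient of the merged
coverage tracks summarise that excess at different resolutions.

The matching semantics follow "bedtools closest" run on summits: one
nearest subject per query (so the relation is deliberately asymmetric — a
popular subject peak can partner several queries), nearest by absolute
summit distance, ties resolved to the subject with the smaller start
coordinate and then the smaller name so results are reproducible.
Inter-chromosomal pairs are impossible by construction. The direction
matters only marginally in practice but is configurable: the pipeline
treats peak set A as the query.

## Coordinate conventions

On disk everything is BED-convention: 0-based half-open intervals, summits
serialized as offsets from the interval start. In memory all positions live
in `GRanges` (1-based closed) with summits as absolute 1-based positions;
only the readers and writers convert. Pair midpoints are the floor of the
mean of the two summits, which reproduces 0-based floor-midpoint arithmetic
exactly. Signed TSS distances are taken in gene orientation: upstream
negative, downstream positive. This convention is stated in every output
table header. Chromosome names are matched by exact string equality; a peak
on a chromosome absent from the bound genome is an error, and intervals
extending past a chromosome end are reported, never clipped.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `topN` | 20,000 | query peaks kept, ranked by score (narrowPeak signalValue when ≥ 0, else the BED score) |
| `maxDist` | 1,000 bp | summit-distance cutoff defining a pair (kept set is ≤ `maxDist`) |
| close-pair threshold | 100 bp | strict `<` threshold for the co-localized fraction and gene selection |
| `promoter` | 5,000 bp | promoter window upstream of the TSS; also the 3' near limit past the TES |
| `farLimit` | 25,000 bp | outer limit of the 5'/3' far windows |
| `tssWindow` | 200 bp | half-width of the TSS element window |
| `maxGeneDistance` | 25,000 bp | gene-linking cap (25 kb), overridden for midpoints inside the gene span |
| ORA `minOverlap`, `pCutoff` | 3, 0.01 | reporting filters for over-representation |

The distance filter keeps pairs with distance ≤ 1000 bp while the
close-pair fraction uses strict `<`; both thresholds are arguments, so
either reading of "less than" can be reproduced.

## Element assignment

Each pair midpoint is annotated against its nearest gene (smallest absolute
TSS distance; ties go to the lexicographically smaller gene id so input
order never matters). Classification priority is: TSS window (±200 bp) >
first exon > first intron > gene body > promoter (< 5 kb upstream) >
5' far (5–25 kb upstream) > 3' near (< 5 kb downstream of the TES) >
3' far (5–25 kb downstream) > unassigned. Intragenic classes outrank the
distance windows, mirroring the area hierarchy of Rgmatch-style gene
matching, and first exon/intron are the 5'-most in gene orientation, not in
coordinate order. The 3' windows are anchored on the gene end (TES):
anchoring them on the TSS would place "downstream" windows inside the gene
body, contradicting the separate gene-body class. Boundary conventions
(upstream window half-open at exactly 5 kb, far windows closed at 25 kb)
are fixed and tested; a midpoint beyond 25 kb from both extremities is
unassigned.

For the over-representation gene list, genes qualify when at least one pair
sits between −5000 and +2500 bp of their TSS (promoter through first exon)
with pair distance < 100 bp. The ORA background defaults to all genes
annotated in at least one pathway of the collection, the convention of
pathway web tools; a user-supplied universe is accepted. Raw p-values are
filtered (minimum overlap 3, p < 0.01) without multiple-testing correction
by default, matching how such gene lists are commonly screened;
Benjamini–Hochberg adjustment is available as an option.

## The Forbes coefficient and its null

For binary coverage tracks A and B on an effective genome of G bp,

FC = O · G / (c_A · c_B),

where O is the observed base-pair overlap and c_A, c_B the track coverages.
Under independent placement E[O] = c_A c_B / G, so FC ≈ 1 means no
association and FC in the hundreds means strong co-occurrence. Tracks are
the merged full peak intervals by default — summit ± flank windows are
available via `toCoverage(mode = "summit")` for sharper, coverage-matched
comparisons. When a blacklist is supplied it is removed from both the
tracks and G, so the statistic and its null share one coordinate universe.

Significance uses interval shuffling: each interval of B is relocated
uniformly on its own chromosome (length multiset preserved, excluded
regions avoided, overlaps merged), and
p = (1 + #{FC\_perm ≥ FC\_obs}) / (M + 1). The per-chromosome relocation
preserves chromosome composition, which matters when coverage is uneven
across chromosomes. Placement uses bounded rejection sampling; a
chromosome too crowded to accept its intervals raises an error rather than
silently under-placing.

## The synthetic cistrome generator

The simulator provides the study conditions the package is validated
under: a 100 Mb genome (four 25 Mb chromosomes), 1000 non-overlapping
genes of 2–20 kb with 2–10 exons, a 1% blacklist of 5 kb intervals, and
two peak sets of 2000 peaks with lognormal lengths (median 400 bp, a
typical called-peak width) and exponential scores. A fraction ρ of set B
is planted: each planted peak places its summit at a set-A partner summit
plus `round(Normal(0, σ))` jitter (σ = 20 bp by default, the scale of
summit-estimation error at good sequencing depth), with partners sampled
without replacement while possible; ground truth records every planting.
Set A and background B peaks are uniform outside the blacklist; planted B
peaks follow their partner even if that lands them near a blacklist edge,
because the ground-truth pairing takes precedence.

The generator emulates the *statistical* structure of co-occupancy — an
excess of near-zero summit distances over a uniform background with known
expectations for pairing fractions and Forbes coefficients. It does not
emulate sequence-driven features of real cistromes: clustered binding at
CpG islands and enhancers, chromosome-scale coverage biases, copy-number
artifacts, or motif-dependent spacing. Tests passing on it therefore
establish correctness of the computations and recovery of planted signal
under realistic noise, not robustness to every bias of real ChIP-seq.

Pathway collections are drawn uniformly from a gene universe except for
one spiked pathway whose candidate overlap is a hypergeometric draw
shifted upward by 50 genes — about seven null standard deviations at the
default sizes (pathways of 250–750 genes, candidate lists of ~1000 in a
universe of 5000), so recovery is expected in essentially every seed.
Those sizes are also chosen so the null p-value distribution is
fine-grained: hypergeometric p-values are discrete, and with small
pathways the step size would dominate a uniformity check.

## Numerical choices

* Hypergeometric tails come from `stats::phyper`, which works in log space;
  tests cross-check an explicit `choose()`-sum enumeration over the full
  support for all universes up to 25 genes.
* Coverage, overlap and FC are computed at exact base-pair resolution with
  integer interval arithmetic on merged tracks (no binning); tests
  cross-check a dense per-base boolean-array oracle on 100 kb genomes.
* Score ties at the top-N boundary and summit-distance ties in pairing are
  broken by coordinate (then name), so every run of every stage is
  deterministic; all simulation functions take explicit seeds.
* Degenerate inputs are errors, not guesses: empty tracks have no defined
  FC, an empty pair set has no defined close-pair fraction, and an empty
  ORA background is rejected.
* `FC` is reported to one decimal in printed output; full precision is kept
  internally and in TSV output.

## Problem sizes in the test suite

Unit tests run on kilobase-scale toy genomes. The end-to-end checks use the
generator's default conditions (2000 + 2000 peaks on 100 Mb) for pairing
recovery; Forbes null calibration uses 200 replicates of independent tracks
(coverage 1–5%) on a 10 Mb genome with 49-permutation tests; oracle
equivalence uses 100 random pairing instances up to 500 × 500 peaks. These
sizes give stable Monte-Carlo estimates while keeping a full run of the
suite in the minutes range.

## Known limitations

* One nearest gene per pair: a midpoint equidistant between two genes is
  assigned to one of them deterministically, and bidirectional promoters
  are therefore counted once.
* The Forbes permutation null randomizes only track B; correlated
  mappability or chromatin-accessibility biases shared by both factors are
  not modelled and will inflate FC on real data, as they do for any
  overlap statistic without a matched background.
* Gene identifiers are matched case-insensitively after trimming, with no
  alias resolution; pathway analyses require consistent id spaces.
* The moving-average curve is evaluated at the observed TSS distances; in
  sparse regions single records carry the curve, so the companion
  `n_records` column should be consulted before interpreting extremes.
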