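---
title: "Methods: DSB hotspot calling and transcription-replication conflict classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DSB hotspot calling and TRC classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trcmap)
```

## Scope and model

sBLISS labels DNA double-strand break (DSB) ends in fixed cells and
sequences them; each read begins with an 8 nt unique molecular
identifier (UMI) followed by an 8 nt sample barcode. After alignment,
the number of distinct UMIs at a genomic position estimates the number
of independent break molecules there. `trcmap` implements everything
downstream of alignment: deduplication, hotspot calling, genomic
annotation, transcription–replication conflict (TRC) directionality,
and spike-in normalization for companion EU-seq / DRIP-seq count
tables. Read alignment itself, genome-assembly liftover and the
negative-binomial differential test (an external package's job) are
deliberately out of scope; the differential-table filters here operate
on the output of such a test.

## UMI deduplication

Two reads are duplicate candidates when they map at most `pos_window`
(default 10) bp apart on the same chromosome and their UMIs differ by
at most `max_umi_mismatch` (default 1) substitution. We treat this
relation as a graph and collapse its connected components —
single-linkage clustering — so that a chain of adjacent jittered
duplicates collapses into one molecule even when its extremes violate
the pairwise bounds. The description "searching for adjacently mapped
reads" does not pin down whether the original implementation was
greedy-pairwise or transitive; we chose transitive linkage because it
is order-independent (a permutation of the input never changes the
result), and we document it as a design choice. The cluster
representative is the smallest position in the cluster (ties on UMI
broken lexicographically), and per-position UMI counts are the number
of clusters represented there, so the total UMI count equals the number
of inferred molecules. Deduplication is strand-agnostic by default
(break ends from the two sides of a DSB may map to either strand); a
`strand_aware` flag restricts linkage within strands.

At realistic UMI lengths, distinct molecules falling within linkage
reach of one another with near-identical UMIs ("collisions") are merged
irrecoverably; for an 8 nt UMI the probability that two independent
UMIs lie within one mismatch is $(1+3\cdot 8)/4^8 \approx 4\times
10^{-4}$, so collisions matter only in extremely dense libraries. The
simulator's truth table lets tests verify exact molecule-count recovery
on collision-free instances.

## Hotspot ("BLISS+") calling

Libraries are first down-sampled to the total UMI count of the smallest
sample, drawing individual UMIs uniformly without replacement — the
sampling unit is the UMI, not the location record, because the UMI is
the pipeline's signal unit. The genome is then tiled with 2 kb bins
anchored at coordinate 0 (the trailing partial bin is kept and
thresholded identically); each bin's coverage is the summed UMI count
of events inside it. Bins with coverage strictly greater than 22 are
called positive — the threshold is described as a coverage value
*above which* bins are called, so the comparison is strict, with a
`strict = FALSE` escape hatch — and consecutive positive bins are merged
into regions whenever the gap between them (end-to-start in
coordinates, not bin indices) is at most 2 kb. Per-condition region
sets are the interval union over replicates. No background statistical
model is fitted: the caller is a fixed-threshold caller by design, and
the threshold, bin size and gap are all configuration entries.

## Genomic annotation and clusters

Regions are assigned exactly one category with precedence
promoter > intragenic > extragenic. "Promoter" means overlap (≥ 1 bp)
with a strand-aware TSS window, by default −2000/+500 bp around the
TSS; no published definition of the promoter window accompanies the
analysis we reproduce, so we adopt this common convention (the same
order of magnitude as the 2 kb bin) and expose both sides as
parameters. Overlap flags against early-replicated regions (ERRs) and
S-phase transcripts use the ≥ 1 bp criterion, with a
`proximal_distance` slack option (default 0) for "proximal to"
semantics. The transcript set is the genes passing the EU-seq
expression filter (baseMean > 32).

The two boolean flags define at most four classes, but the published
four-cluster scheme cannot be reconstructed from them alone: the
transcript-positive clusters {1,3,4} and ERR-positive clusters {1,2,4}
imply both cluster 1 and cluster 4 are double-positive, and the rule
splitting them is not documented. We therefore map: both flags → 1,
ERR-only → 2, transcript-only → 3, neither → unclustered, and expose
the 1/4 split as configuration — supplying per-region TRC classes and
naming which class moves to cluster 4 — rather than guessing a
biological rule.

## Replication-fork direction and TRC classes

Under hydroxyurea, EdU incorporation marks DNA newly synthesized from
early origins, so within an ERR the EdU-HU signal is maximal near the
origin and decays toward the edges. We locate the origin as the argmax
of the signal inside the ERR after a centered moving average
(`smooth_bins`, default 5 bins; edge windows shrink symmetrically);
tied maxima resolve to the midpoint of the tied plateau, so a flat
profile yields the ERR midpoint. An all-zero profile raises an error
by default, with a documented fallback to the midpoint. Forks move
outward: a position right of the origin is replicated by a right-moving
fork.

Each break region is associated with the nearest ERR and nearest
expressed gene within `assoc_window` (default 10 kb, measured from the
region midpoint; the source analysis describes proximity without
distances, so the window is configuration). The class is then a pure
function of fork direction and gene strand: co-directional when they
agree (right/+ or left/−), head-on when they oppose. Regions lacking
either association, or spanning the origin itself (no single fork
direction), are reported unclassified rather than guessed. The 2×2
rule implies an exact symmetry — flipping every gene strand swaps
head-on and co-directional counts — which the tests assert.

## Spike-in size factors and expression filters

For EU-seq and DRIP-seq, a fixed proportion of foreign-genome material
is spiked into every sample, so between-sample normalization can use
spike rows only: the estimator is the standard median-of-ratios
restricted to spike rows, with rows containing any zero excluded from
the geometric-mean reference (the usual convention, since the log
reference is undefined there). Size factors are defined up to a global
scale — for two samples with spike counts in ratio 2 the factors are
$(1/\sqrt2, \sqrt2)$ — so recovery against known truth is assessed
after rescaling both to geometric mean 1 (`rescale_geomean`). A gene is
"expressed" iff its baseMean (mean of normalized counts across samples)
strictly exceeds 32; the threshold is parameterized per assay since
EU-seq and DRIP-seq need not share it. Gene intervals can be extended
by 10% of gene length at both ends before counting, to capture
enrichment bordering transcripts; the extension is strand-independent
and clipped to chromosome bounds. DEG labeling (padj < 0.05, split by
fold-change sign) and control-gene sampling (500 genes with
padj > 0.5, uniform without replacement, seeded) are pure filters on an
externally supplied differential table.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the
reference simulation used across the test suite: two 1 Mb chromosomes,
12 non-overlapping ERRs (40–80 kb) whose origins sit at their
midpoints, 60 non-overlapping stranded genes, and 20 planted
promoter-proximal hotspots. Each hotspot gene is placed wholly on one
side of an ERR origin with a margin, its strand chosen to realize an
alternating sequence of head-on and co-directional conflicts, and the
±1 kb window around its TSS is recorded as a hotspot with a break rate
of `hotspot_rate_multiplier` × background. Background breaks are a
uniform Poisson process at 0.002 breaks/bp — 4 expected UMIs per 2 kb
bin, safely below a third of the calling threshold of 22 — while the
25-fold multiplier yields ≈ 100 expected UMIs per hotspot bin, at least
three times the threshold. These two rates were chosen once from those
design constraints. PCR duplicates re-emit a molecule with ≤ 10 bp
uniform jitter and a single UMI substitution at the configured rate;
barcodes come from a whitelist with pairwise Hamming distance > 4 so
1-mismatch demultiplexing is unambiguous; mapping quality is a
two-component mixture around the MAPQ 30 boundary, since only the
filter boundary matters downstream. EdU-HU tracks are triangular
(maximal at the origin, linearly decaying to zero at ERR edges,
fork-symmetric); EU tracks are constant per expressed gene body with
partial boundary bins weighted by coverage. Count matrices draw Poisson
counts around spike/gene expectations scaled per-sample by the true
factors, or the exact scaled values in the noise-free mode.

What the generator does *not* emulate: non-uniform break backgrounds
(real BLISS backgrounds track chromatin and replication timing),
sequence-dependent UMI errors or indels, fragment-length effects,
asymmetric or multi-origin ERRs, and expression heterogeneity along
gene bodies. Passing tests therefore demonstrate the correctness of
the algorithms under the stated statistical assumptions, not the
biological completeness of those assumptions; the uniform-Poisson
background in particular is an assumption, flagged as such.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open (BED convention) in every data frame
exchanged between stages; conversion to the 1-based closed convention
of GenomicRanges happens only inside the interval helpers. All
simulation entry points accept a seed and restore the caller's RNG
state; derived stages (reads, counts) use fixed offsets of the
configured seed so the genome and its read sets are independently
reproducible. Down-sampling leaves the smallest sample untouched
byte-for-byte. Empty inputs flow through: an empty break table yields
zero regions and a valid summary; an empty feature set yields
fractions of 0 (with a warning in the overlap matrix). Events beyond
chromosome bounds are errors naming the offending record rather than
silent drops. Rejection-sampled placements (genes, ERRs, hotspot
genes) are bounded and fail with actionable messages when a request
cannot fit.

Test problem sizes — 50 fuzzed dedup instances of ≤ 200 reads against
an $O(n^2)$ oracle, 20-seed recovery runs on the 2 × 1 Mb reference
genome, 100-seed origin-localization runs — were chosen so the full
suite completes in well under a minute while keeping every Monte-Carlo
assertion comfortably inside its stated statistical bound.

## Known limitations

The fixed-threshold caller inherits the original analysis's choice of
an absolute coverage cutoff; it is depth-sensitive, which is exactly
why down-sampling precedes it (the ordering dedup → down-sample → call
is itself a documented choice; the source does not state whether
down-sampling preceded deduplication). Origin location assumes a
single origin per ERR; multi-modal EdU-HU profiles resolve to the
plateau midpoint of the global maximum. Region-to-gene association is
by nearest midpoint distance, which can mis-attribute breaks in dense
gene neighborhoods; the association window is configurable but no
attempt is made to model multi-gene conflicts.
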