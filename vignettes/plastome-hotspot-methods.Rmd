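---
title: "Methods: comparative plastome analysis and divergence-hotspot scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis and divergence-hotspot scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`plastomics` implements a comparative analysis of annotated chloroplast
genomes from closely related plants: structural characterisation, repeat
content, localisation of fast-evolving regions usable as phylogenetic
markers, and maximum-parsimony phylogenomics with congruence testing.
This vignette explains the models and procedures, the parameters that
matter, the numerical conventions, and what the simulation-based tests do
and do not establish about real data.

## Coordinates and containers

Genomes are circular; internally every interval is 0-based half-open, and
features that wrap the origin are stored as two intervals. GenBank
1-based inclusive locations (`a..b`) convert at the I/O boundary via the
bijection `a..b` ↔ `(a-1, b)`. Ambiguity codes other than `N` are mapped
to `N` with a warning, because all downstream statistics are defined over
`{A, C, G, T, N, -}` only. The trans-spliced plastid gene *rps12* is not
treated specially: a genome annotated with its two non-colinear parts as
separate features simply yields two independent named regions.

Tabular results are tibbles; alignments and genomes are light S3
containers, and trees are `ape` `phylo` objects. Fitted objects
(`mp_fit`, `ild_result`, `hotspot_scan`) have `tidy()`/`glance()` methods
and `autoplot()` where a standard display exists. This hybrid shape —
S3 containers for sequence data, tidyverse output for everything tabular
— was chosen because genomes, alignments and trees are not naturally
data frames, while every per-region or per-pair result is.

## Quadripartite structure detection

The inverted repeat is found by exact 25-mer seeding of the genome
against its reverse complement, grouping seeds by diagonal, and extending
the seeded exact run outward *run-wise*: a mismatch stretch is crossed
only onto a further exact run of at least 8 matches, and only while the
overall identity of the extended span stays at or above `min_identity`
(default 0.99). Growing by whole runs rather than single bases means an
exact duplication is recovered with zero boundary creep — a chance
single-base match beyond the true junction is never absorbed — while the
~1% mismatch density of real IR copies is still crossed comfortably
(their exact runs average ~100 bp, far above the 8-base confirmation).
The longer intervening single-copy stretch is labelled LSC by definition;
IRb is the copy following the LSC in coordinate direction. When the two
copies differ in length after extension, `ir_length` is reported as the
length of IRb, a convention recorded in the output. Inverted duplications
shorter than `min_ir` (default 1000 bp) yield a `no_ir` result rather
than an error, and the partition degenerates to a single region.

One identifiability caveat is inherent to the problem: if the first base
of the SSC happens to complement the last base of the SSC, the *maximal*
inverted duplication genuinely extends one base past the planted
junction, and no detector could tell the difference. The simulator
therefore nudges that single base when generating genomes, so planted
boundaries are always the maximal ones; real genomes simply get the
maximal-duplication boundary, which is the only defensible answer.

## Repeat detection and classification

Repeats are maximal local ungapped matches of the genome against itself
(direct) and against its reverse complement (inverted), found by 15-mer
seeding and the same run-wise extension with `min_identity = 0.90` and
`min_len = 30`. Identity is matches over aligned columns of the ungapped
span — a reproducible definition that avoids arbitrary gap placement
inside copies. The trivial self-match is excluded, as is the whole
IRb-vs-IRa duplication; more generally any hit with a copy entirely
inside IRa is dropped, because the structural duplication guarantees an
IRb-image of that hit is already reported (content of the IR is counted
once, as the IRb instance). Inverted hits whose copies overlap
(self-palindromes centred on a point) are dropped.

Overlapping hits merge into one motif (union of footprints, minimum
identity), so a genome region belongs to at most one reported repeat.
Each motif takes exactly one category with precedence
**tandem > palindromic > gene-similarity > dispersed**: tandem means
direct orientation with a gap of at most 10 bp between copies (strict
zero-gap adjacency would miss near-tandem copies that merging would
join; the tolerance is configurable); palindromic means inverted
orientation with a gap of at most 3 kb; gene-similarity means the two
copies overlap two distinct annotated genes. The catch-all dispersed
class comes last so that the specific classes win ties.

## Homologous regions and alignment

Regions are defined on a reference genome: gene and pseudogene footprints
(merged where they overlap) partition the circle; gaps between
consecutive footprints are intergenic spacers named `geneA-geneB` in
reference orientation; within each functional gene, consecutive exon
intervals yield exon and intron regions. Pseudogenes break spacers like
genes do, contribute no exon regions, and their interiors are carried as
noncoding regions so that the regions tile the reference exactly — a
property the tests assert. Homologues in the other genomes are located
through their own annotations (same gene names; same flanking pair for
spacers, with anticodon suffixes optionally stripped and reversed pairs
taken as reverse complements). Minus-strand genes are extracted
reverse-complemented so homologues share orientation. Regions fully
inside IRa are dropped when a partition is supplied.

The built-in aligner is a deterministic center-star: the center is the
sequence maximising the summed pairwise global-alignment score (ties go
to input order), every other sequence is aligned to the center by
affine-gap global alignment, and the pairwise alignments merge under
"once a gap, always a gap". Defaults are match +2, mismatch −1, gap open
−5, gap extend −2, with a gap of length L costing `open + L·extend`;
`N` scores 0 against anything. The pairwise step is a Gotoh dynamic
programme in C (`src/align.cpp`), restricted to a 50-column diagonal band
for sequences over 400 bp — homologous plastome regions drift by a few
indels at most, far less than the band — and full-width below that.
External alignments (e.g. from MAFFT or MUSCLE) can be ingested with
`read_fasta_alignment()` and are the preferred path for real data; the
exclusion list in `pipeline_config()` stands in for the manual curation
of ambiguously aligned loci that published analyses typically apply.

## Divergence statistics

Site classification excludes gaps and `N` from the state counts: a
column is constant with ≤ 1 remaining state, parsimony-informative with
≥ 2 states each seen ≥ 2 times, and a variable singleton otherwise. A gap
never makes a site informative, matching the common treatment of missing
data in parsimony software. PIC% uses the full aligned length as
denominator, so a region's percentage matches how its aligned length is
used by the > 200 bp filter; the value with only non-empty columns in the
denominator is reported alongside for transparency.

p-distances are uncorrected proportions of differing sites. Complete
deletion (the default) removes every column containing any gap or `N`
before comparison; pairwise deletion removes them per pair. Species-level
summaries are means over unordered pairs — all pairs, pairs from
different species, and pairs sharing a species (reported absent when no
such pair exists). "Overall divergence" is operationalised as variable
columns over analysed columns, since percentage-divergence headlines in
comparative plastome work rarely define their metric; the choice is
recorded here and in the output. No multiple-testing correction is
applied anywhere: the scan is a descriptive ranking, not a family of
hypothesis tests.

## Maximum parsimony

Fitch scoring treats characters as unordered and unweighted; gaps and `N`
are fully ambiguous states (a fifth-state mode is deliberately absent
from the defaults, consistent with distances that exclude indels).
Identical columns are collapsed to weighted patterns, and
parsimony-uninformative complete-data patterns contribute a constant
(states − 1) per column on every topology, so searches only rescore
informative patterns.

Three search strategies are provided. Exhaustive enumeration (≤ 9 taxa)
scores every unrooted binary topology via depth-first stepwise insertion.
Branch and bound (≤ 15 taxa) prunes any partial tree whose length already
exceeds the incumbent — valid because adding taxa never decreases MP
length — with the incumbent initialised by greedy stepwise addition; it
is exact and returns all equally most-parsimonious trees. The heuristic
runs seeded random-addition starts (default 10), each followed by
nearest-neighbour interchange to convergence and one sweep of subtree
regrafting, repeating NNI if regrafting improved; it does not replicate
PAUP*'s "hold 20 trees per step" stepwise retention, and its length is an
upper bound checked against branch and bound in the tests. Ties are
retained and summarised by strict consensus.

Bootstrap resampling draws columns with replacement to the original
length, reruns the search per replicate, counts a bipartition when it
appears in the replicate's strict consensus, and returns the > 50%
majority-rule consensus with percentage supports as node labels. All
stochastic steps flow from one integer seed, and supports are
bit-reproducible given (seed, replicates, strategy).

Tree statistics follow the standard parsimony definitions over variable
columns: per column the minimum steps `m` (distinct states − 1) and the
maximum on a star `g` (occurrences − largest state frequency); columns
with `m = 0` are excluded; `CI = ΣM/L`, `RI = (G−L)/(G−M)`,
`RC = CI·RI`. A zero-length tree takes CI = RI = 1, and RI = 1 when
`G = M` (no homoplasy is possible), conventions logged in the output.

## Incongruence length difference test

The ILD (partition homogeneity) statistic compares the observed sum of
the two partitions' MP tree lengths with sums after randomly reassigning
columns to pseudo-partitions of the original sizes (sampling without
replacement; constant columns are retained, the PAUP*-style option
recorded in the configuration). Incongruence is signalled by a *small*
observed sum — separate trees fit incongruent partitions better — so
`p = (1 + #{replicate sum ≤ observed}) / (N + 1)`; the +1 correction
means p is never zero. The convention is stated explicitly because
published implementations differ in direction. For seven or fewer taxa
the MP length of every column subset is obtained exactly by scoring all
topologies once per site pattern and minimising a matrix product, which
makes the permutation loop cheap; larger problems rerun the configured
search per replicate. Defaults are 99 replicates in the test suite and
999 for real analyses (published counts are rarely stated). A partition
with no variable column flags the result as low-power rather than
erroring.

## The hotspot pipeline

`run_scan()` chains extraction → alignment (or ingestion) → site
classification → thresholds → combined-alignment MP tree with bootstrap →
per-region congruence of flagged regions → ranked report. The thresholds
are the field's: aligned length strictly greater than 200 bp to pass,
PIC% ≥ 2 to be informative, PIC% > 3 to be a hotspot, all three
configurable. Ranks order passing regions by PIC% descending with ties
broken alphabetically. Congruence per region is the strict consensus of
its MP trees compared against the combined tree (congruent = RF 0),
plus an ILD test of the region against the concatenated remainder.
`partition_datasets()` splits a whole-genome alignment into the six
standard datasets (complete, protein-coding exons, LSC, SSC, IR,
introns+spacers) by the class of each column's reference residue, with
gap-in-reference columns inheriting the preceding residue's class.
`marker_report()` writes the ranked TSV, Newick trees and a run-metadata
block with no timestamps, so identical configuration and seed reproduce
byte-identical files.

## The simulator and what the tests mean

`simulate_plastome_set()` evolves an annotated quadripartite genome down
a known tree under Jukes–Cantor substitution with per-region rate
multipliers (defaults: coding 0.3, intron 1.0, spacer 1.5, hotspot 10 —
the hierarchy observed in plastomes, with hotspots an order of magnitude
above background). The root sequence is drawn at 63% AT, the
composition typical of plastomes. Sites substitute independently with
`p = 3/4 (1 − exp(−4/3·b·m))`; indels occur only in noncoding regions at
0.1 events per expected substitution with geometric lengths of mean 4, so
exon homology is exact and intron/spacer alignment is the stressed path.
After every branch the IRa is regenerated as the exact reverse complement
of the IRb block, mimicking the copy-correction that keeps real IR copies
nearly identical (disable with `ir_copy_correction = FALSE` to exercise
tolerant IR detection). Planted repeats of the four categories are
written into the root; degraded copies keep a 15-base exact seed and
8-base exact runs between mismatches so they remain detectable by
construction. No gamma rate variation across sites, no gene loss or
pseudogenisation events, and no rearrangement history are simulated —
keeping the ground truth analytically checkable — so inversions are
exercised through static gene-order fixtures instead.

The default design (`default_cymbidium_like_plan()`) is a desk-scale
emulation of a congeneric orchid study: eight individuals from five
species, a ~33 kb genome (LSC ~20 kb, IR ~4.8 kb ×2, SSC ~3.3 kb; scale
factor ~0.2 of a real ~155 kb plastome), ~40 genes including two
intron-containing genes and one pseudogene, three hotspot spacers among
~30 spacers, and five planted repeats. Branch lengths put within-species
p-distance near 0.004, between-species near 0.011 and the overall mean
near 0.009 — the divergence regime in which whole-plastome comparison is
actually needed. All replicate counts in the tests (20 pipeline
replicates, 200 ILD calibration runs, 100 bootstrap replicates) are the
package's chosen problem sizes for a thorough desk-scale run.

Passing these tests shows the machinery is correct and well calibrated
*under the model*: independent JC sites, uniform base composition,
annotation-consistent homology, and indels that never touch coding
sequence. Real plastomes add AT-rich composition, rate variation within
regions, microsatellite slippage, annotation disagreements between
genomes, and alignment ambiguity in the fastest spacers; the exclusion
list and the external-alignment path exist precisely because those
effects need human judgement on real data.

## Numerical conventions and degenerate inputs

Deterministic tie-breaks throughout: first-encountered optimum in
searches, input order for the center-star center, alphabetical order for
equal PIC%. Empty feature tables produce placeholder junction records;
genomes without an IR produce a `no_ir` partition; an all-gap column set
under complete deletion raises "no comparable sites"; two genomes give a
statistics-only scan (no tree); three taxa have a single unrooted
topology, so tree search starts at four. Every stochastic step
(simulation, heuristic starts, bootstrap, ILD permutation) derives from
one integer seed recorded in every report.
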