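---
title: "SSR germplasm characterization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSR germplasm characterization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrcore)
```

`ssrcore` characterizes a germplasm collection from SSR (microsatellite)
marker data: it mines perfect repeats from an assembly, computes per-locus
diversity statistics, clusters accessions, selects a core collection, and
assigns molecular identity codes. This vignette is the package's account of
the statistical machinery, the defaults, and the choices made where the
design was genuinely open. The running context is a dikaryotic fungal
collection (cultivated *Hypsizygus marmoreus* strains), which fixes two
modeling facts: each accession carries at most two alleles per locus, and
scoring is band-based — what the electropherogram shows is the presence or
absence of fragment sizes, not an ordered diploid genotype.

## Repeat mining

`find_ssrs()` reports every maximal perfect tandem repeat of a primitive
1–6 bp unit whose repeat count reaches the per-unit-length threshold.
Defaults follow the common genome-survey convention: mononucleotides ≥ 10
repeats, dinucleotides ≥ 6, tri- through hexanucleotides ≥ 5
(`motif_rules()`). Conventions that matter for reproducibility:

* **Maximality and phase.** A tract is the longest run with period *u*
  that cannot be extended by a single base; it is reported at its leftmost
  phase with any trailing partial unit trimmed, so
  `end − start = unit_length × repeat_count`. A run periodic at several
  unit lengths (a poly-A run is periodic at every *u*) is reported only at
  its shortest primitive unit.
* **Motif classes.** Units are collapsed over cyclic rotation and reverse
  complement: the class label is `X/Y` with `X` the lexicographically
  smallest rotation of the unit or its reverse complement and
  `Y = revcomp(X)`. Self-complementary classes keep that form (`AT/AT`,
  `CG/CG`).
* **Dialect tolerance.** Soft-masked lowercase is uppercased; `N` breaks
  tracts; any other character is a format error. Coordinates are 0-based
  half-open internally and 1-based inclusive in exported tables and GFF3.
* **Scope.** Only perfect simple tracts are reported; compound or
  interrupted repeats are not merged. Mean interlocus distance is defined
  as assembly length ÷ locus count, the convention under which a
  genome-wide survey's locus count and spacing are mutually consistent,
  rather than the mean of adjacent gaps.

The test suite checks the scanner against a brute-force oracle (every
start × every primitive unit) on random sequences up to 2 kb, and checks
that motif-class counts are invariant under reverse-complementing the
input.

## Diversity statistics

All statistics are computed from **band-based allele frequencies**
(`allele_frequencies()`): each accession contributes one count per
distinct band it carries at a locus — two counts for a two-band dikaryon,
one for a single-band strain — and missing accessions leave the
denominator. This matches how such collections are scored and avoids
assuming that a single band means two identical allele copies.

For frequencies $p_j$ at one locus:

* $\mathrm{PIC} = 1 - \sum_j p_j^2 - \sum_{j<k} 2 p_j^2 p_k^2$ (Botstein's
  multi-allele form; the package computes the pair sum as
  $(\sum p^2)^2 - \sum p^4$).
* $Ne = 1 / \sum_j p_j^2$, $He = 1 - \sum_j p_j^2$,
  $I = -\sum_j p_j \ln p_j$ (nats).

$He$ is deliberately the **plain** Nei gene diversity, not the
$2N/(2N-1)$ small-sample-corrected version: under the plain estimator the
identity $He = 1 - 1/Ne$ holds exactly, and published tables of this kind
satisfy it row by row (up to 3-decimal rounding of both columns, a bound
of $5\times10^{-4}(1 + 1/Ne^2)$ per row — the regression fixture in the
tests uses exactly that propagated bound). `he_from_ne()` exposes the
identity for consistency checks against independently reported values.
Provable inequalities ($\mathrm{PIC} \le He$, $Ne \le Na$,
$I \le \ln Na$) are property-tested on random frequency vectors;
$He \le 1 - 1/Na$ is *not* asserted because it is false in general.

`diversity_table()` mirrors the conventional layout: one row per locus,
a totals row (column sums) and a means row (totals ÷ locus count);
`write_diversity_table()` prints statistics at 3 decimals and mean Na at
2.

## Similarity, UPGMA and cuts

`simple_matching()` computes, for each accession pair, the fraction of
band columns on which they agree, counting both shared presences and
shared absences — the coefficient traditionally used for dominant-scored
band data. Columns of a marker missing in either accession of a pair are
excluded pairwise, so one failed amplification does not discard an
accession. The open question of whether to match on band columns or on
per-locus allele-set identity is resolved toward band columns, consistent
with the 0/1 scoring that also drives fingerprints and core selection.

`upgma()` is implemented in the package rather than delegated, for two
reproducibility reasons: (i) the merge-height convention is the
UPGMA-averaged distance itself (not halved), so a node at height $h$ joins
clusters at similarity $1 - h$ and dendrograms read directly on the
similarity scale used for threshold cuts; (ii) ties are resolved
deterministically — among equally close pairs, the pair whose sorted
(smallest-leaf-label, smallest-leaf-label) pair is lexicographically
smallest merges first — so runs are bit-reproducible regardless of input
order. `stats::hclust(method = "average")` serves as an independent
cophenetic oracle in the tests. Newick export rescales `ape`'s
half-height edge lengths back to merge-distance units, so leaf-to-root
depth equals the root merge distance.

`cut_at_similarity(tree, t)` unions the leaves of every merge at height
$\le 1 - t$ (with a $10^{-9}$ tolerance against floating-point noise in
averaged distances) and numbers groups by first accession in input order.
At $t = 1$ only exact duplicates share a group; at $t = 0$ everything
does; group counts are monotone in $t$.

## Core selection

`select_core()` implements the maximization (M) strategy objective —
retain every allele class with as few accessions as possible — as a
deterministic greedy set cover: repeatedly pick the accession covering the
most not-yet-covered classes, breaking ties by larger total band count and
then input order. Greedy was chosen over the unpublished details of
PowerCore's "advanced M" search because the objective (100% class
retention, minimal redundancy) is identical, the result is
bit-reproducible, and the classical $(1 + \ln d)$ approximation guarantee
(with $d$ the largest per-accession class count) is checked empirically
against exhaustive minimum covers on small instances. If `target_size`
exceeds the cover, selection continues by maximizing the running Shannon
diversity of within-core band counts, so extra picks balance class
representation. Quantitative traits, if supplied, are quartile-discretized
and appended as extra coverage columns. `compare_baselines()` contrasts
the core's (full) coverage with the Monte-Carlo mean coverage of uniform
random subsets of the same size.

Note that the minimum cover size is data-dependent: under the default
synthetic profile (115 allele classes, 57 accessions) roughly 30+
accessions are needed for full coverage, so a published 24-member core
from a specific collection is a property of that collection's redundancy
structure, not an algorithmic constant.

## Molecular identity codes

A molecular ID is `fingerprint-traitcode-supplementarycode`. The
fingerprint is the accession's raw 0/1 band row in marker display order
then ascending allele size — kept as text for human readability, and
identical in length (total allele-class count) across a collection.
Because the original collection-specific encoding rules are not public,
the codebook is user-supplied configuration with a shipped default (color
as trait; origin region and cultivation type as supplementary codes);
codes must not contain the `-` separator. `qr_payload()` appends a
2-character mod-36 checksum so scanned IDs are self-validating; the raw
payload is recovered by dropping the last two characters, and payloads
beyond the 2953-character barcode capacity raise an error suggesting
base-36 compaction. `detect_duplicates()` partitions accessions by
identical fingerprint (or full payload); fingerprint-identical groups
whose payloads differ are flagged `metadata_distinct` — strains separable
only through their metadata, the practically important duplicate class.

## Synthetic data and what it does (not) show

The generators define the conditions under which the pipeline is scored.

`simulate_genome()` plants specified perfect repeats into an i.i.d.
background at a chosen GC content, then iteratively rescans and
point-mutates the background (never the planted spans) until the only
above-threshold tracts are the planted ones — so the truth catalog is
recovered exactly and mining recall/precision can be asserted at 1.

`simulate_population()` emulates a 57-accession collection typed at 15
multi-allelic loci: per-locus allele counts default to
(5, 9, 5, 6, 7, 4, 9, 8, 11, 10, 7, 9, 17, 5, 3) — 115 classes in total —
with 5 groups, expected within-group simple-matching similarity 0.90 and
between-group 0.72, chosen so that a cut at 0.76 separates the groups and
pairwise similarities span roughly 0.70–1.00. The generative model is a
three-level mutation hierarchy: per locus, an allele-frequency vector from
a symmetric Dirichlet (concentration 3 — even enough that all classes are
realized in a collection of 57, while still variable); an ancestral allele
pair; group prototypes derived by resampling each slot with probability
$\phi$; accessions derived from their group prototype with slot
resampling probability $\theta$. $\theta$ and $\phi$ are calibrated by
root-finding on the *exact* expected simple-matching coefficient — a band
column disagrees iff its allele lies in the symmetric difference of the
two band sets, and that expectation is enumerable over prototype pairs
(`expected_matching_similarity()`). A cruder independent-column-flip
approximation was rejected because it miscalibrates the band-set
expectation. Two variance controls make the planted structure reliably
recoverable: slot mutations are drawn in exact (round-balanced) counts
rather than independently, and prototype sets are redrawn (up to 200
tries) until their conditional expected within/between similarities sit
within 0.02 of the targets; the generator's contract is ±0.03, and it
errors if even ±0.03 is unreachable — which genuinely happens for coarse
profiles (few band columns and many groups), where a single slot change
moves a pair's similarity by several hundredths. Any allele class never
drawn is patched into one accession so the band matrix always has exactly
$\sum Na$ columns, and the stored truth includes group labels, the
calibrated rates, and both slot-level and band-level (what the
band-counting estimator sees) frequency vectors.

What this emulates: collection dimensions, allele-count profile, group
separation and similarity range, brown/white trait structure
(`simulate_traits()` assigns white to 18/57 by default, concentrated in
the group closest in size). What it does not: real electrophoresis
artifacts (stutter, null alleles, ±1 bp sizing noise), linkage between
loci, within-group pedigree structure, or the *absolute* diversity levels
of any particular collection — Dirichlet-even frequencies give higher
He/PIC than strongly skewed real panels, so passing tests demonstrate
correct computation and recovery of planted structure, not that any real
collection has these statistics.

Problem sizes in the tests — 57 × 15 populations, genomes up to 20 kb,
exhaustive covers on ≤ 14 accessions, 20-seed recovery loops — were
chosen so each oracle (brute-force scan, exhaustive cover, closed-form
expectation) is exact and the whole suite runs in about a minute.

## Pipeline and reproducibility

`run_pipeline()` executes mine → stats → cluster → core → id in
dependency order, failing with a stage-named error, and writes a JSON
manifest echoing parameters and md5 checksums of every output; the same
config and seed reproduce identical checksums. All randomness (generators,
baselines) flows from explicit seeds. The pipeline and generator defaults
(similarity cut 0.76, thresholds above) are configuration, not constants,
and are echoed in the manifest.

## Known limitations

* Allele sizes are binned to integer bp with no ±1 bp fuzzy merging;
  capillary sizing is treated as exact.
* Missing data are excluded per-locus from frequency denominators and
  pairwise from similarity, not imputed; a pair with no comparable
  columns is an error rather than a guess.
* The greedy core is near-optimal, not provably minimal, beyond the
  instance sizes where exhaustive search is feasible.
* `detect_duplicates()` finds exact band-profile identity only; near
  duplicates (one band apart) are left to the similarity matrix.
* F-statistics, Hardy–Weinberg tests and linkage disequilibrium are out
  of scope, as are primer design and figure rendering.
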