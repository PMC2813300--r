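---
title: "Mapping focal amplifications and nominating driver genes: methods"
author: "ampliconmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping focal amplifications and nominating driver genes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliconmap)
```

This vignette is the package's own account of the methods it
implements: the models and their assumptions, the parameters that
matter, what the synthetic-data generators do and do not emulate, and
the numerical and design choices made where the problem left them
open.

## The analysis problem

Recurrent focal DNA amplifications are a classic route to oncogene
activation. Within an amplified segment, several genes are typically
over-expressed by gene dosage alone; the analytical task is to
(i) locate the recurrent amplicon precisely enough that its gene
content is enumerable, and (ii) separate *driver* genes — whose
over-expression is consistent and strong wherever the amplicon occurs
— from *bystanders* that merely ride along. The package implements
this end to end for array-CGH log2-ratio profiles plus expression,
RT-qPCR and immunohistochemistry (IHC) readouts, with the 3q26.33 /
SOX2 locus of lung squamous cell carcinoma as the running example and
default parameterization.

## Copy-number calling and frequency maps

Copy-number states are pure per-clone thresholds on the log2 ratio:
`amp` above `amp_min`, `gain` in (`gain_min`, `amp_min`], `loss` at or
below `loss_max`, `neutral` otherwise, `missing` for masked values.
There is deliberately **no segmentation or smoothing** (no CBS, no
HMM): the calling convention the package encodes is per-clone, and a
`max_gap_clones` merge parameter (default 0) covers the one situation
— tiling arrays — where a single noisy clone can interrupt an
amplicon run.

Parameters, units and defaults:

* `amp_min = 1.0` log2 (tumor/reference ratio > 2) — the standard
  high-level amplification cutoff for dedicated arrays; `1.5` is the
  conventional alternate preset for whole-genome platforms.
* `gain_min = +0.25`, `loss_max = −0.25` log2 — single-copy bounds.
  These are the usual aCGH conventions rather than universal
  constants, which is why they are explicit fields of
  `call_thresholds()`.

The binned aberration-frequency map divides each chromosome into
`bin_size` windows (default 2 Mb, the conventional reporting interval)
and counts **tumors, not clones**: a tumor contributes at most one
occurrence per bin per state, and the denominator is the number of
tumors with at least one informative clone in the bin. This makes the
map robust to uneven clone density. A bin with no informative clone is
reported `NA`, never 0 — absence of evidence is not a 0% frequency.
For the gain track, an amplified clone also counts as gained (an
amplification *is* a copy-number increase). Frequencies are
non-increasing in their defining threshold; the test suite asserts
this on random cohorts and checks the whole map against a brute-force
enumeration.

## Amplicon extraction and the consensus region

On tiling profiles, an amplicon is a maximal run of consecutive
`amp`-state clones; the segment runs from the start of its first clone
to the end of its last, so boundary error is bounded by one clone
spacing. The **consensus region** (minimal common region) is the
interval intersection over tumors of the union of each tumor's
segments, computed by coverage arithmetic on `GRanges`. When the
strict intersection is empty, the widest maximal-support region is
returned with its actual support — the fallback is reported, never
silently substituted. Ties between equally supported regions resolve
to the widest, then the first in genomic order.

Coordinates: BED files on disk are 0-based half-open; in memory the
package uses `GenomicRanges` (1-based closed), the Bioconductor
convention, converting at the I/O boundary; human-readable reports use
Mb. Widths and overlap semantics are identical under both
conventions, and a gene exactly abutting a region boundary is
excluded, as the half-open convention requires.

The packaged gene annotation (`inst/extdata/genes_3q26_synthetic.bed`)
is a **synthetic** fixture: nine RefSeq-style genes placed at
plausible positions inside the 181.9–184.6 Mb interval plus two
outside flankers. Eight of the nine symbols are unambiguous; the
ninth (MCCC1) is an assumption, documented here, since published gene
counts for this interval do not name all members explicitly.

## Driver nomination from RT-qPCR

Fold changes divide each tumor's linear-scale quantity by the
**geometric mean** of the reference tumors (tumors without copy-number
change at the locus). The geometric mean is the right average for
ratio-scale qPCR quantities; an arithmetic option is provided because
the choice is a convention, not a theorem. Two recurrence rules are
then applied over the amplified tumors, both of the k-of-n form with
defaults k = 4, n = 5: fold > 2 (recurrent) and fold > 5 (strong).
The rules are independent counts — the package reports both numbers
per gene rather than a single collapsed label — and classification is
monotone in the thresholds, which the suite asserts.

## Differential signatures

Signatures are defined by per-gene Welch two-sample t tests (unequal
variances; vectorized, validated against `stats::t.test`),
Benjamini–Hochberg adjustment across genes, and membership when
adjusted p < `alpha` (default 0.05) **and** |log2 fold change| ≥
`min_abs_lfc` (default 1). Direction follows the sign of the mean
difference. Welch-plus-BH was chosen as a transparent, assumption-light
derivation; all three knobs are arguments, and moderated-variance
(empirical Bayes) testing is intentionally out of scope. Degenerate
inputs: a zero-variance gene with zero mean difference gets t = 0,
p = 1; groups of fewer than two samples are an error.

## Overlap and enrichment statistics

List overlaps use the exact hypergeometric upper tail
(`stats::phyper`), never a normal approximation, and the universe is
always an explicit argument — implied universes are the commonest way
to overstate an overlap. Both overlap fractions (of A and of B) are
reported because which denominator a quoted percentage used is often
ambiguous.

The enrichment statistic is the weighted Kolmogorov–Smirnov running
sum: hits add `|s_i|^p / N_R`, misses subtract `1/(N − |S|)`, and ES
is the signed maximum-magnitude deviation. Default weight `p = 1`;
`p = 0` (classic KS) is exposed and used by the brute-force oracle
tests. Numerical choices worth recording:

* With `p = 0` the running sum is rational, and the maximum positive
  and negative deviations can tie **exactly**; the extremum is then
  chosen as the earliest position within 1e−12 of the maximum, making
  the sign deterministic and identical between the exported
  running-sum implementation and the O(|S|) hit-walk used inside
  permutation loops (the two are cross-checked on random instances,
  and against fgsea's statistic).
* If all weights in the set are zero (all-zero scores), the increment
  falls back to `1/|S|` rather than dividing by zero.

Permutation calibration: NES divides ES by the mean magnitude of
same-sign permuted scores; the nominal p is the same-sign permutation
tail; the FDR q compares each observed NES against the pooled permuted
NES distribution, normalized per side (the standard multi-set
procedure), clipped to [0, 1]. The scheme is `phenotype` permutation
when the phenotype is two-class with at least 7 samples per class
(label exchangeability is then a reasonable null and preserves
gene–gene correlation), otherwise `geneset` permutation; `auto`
records which was used. Continuous phenotypes (e.g. ranking by
correlation with SOX2 expression) use gene-set permutation under
`auto`. Everything is seeded and reproducible bit-for-bit.

Correlated-target recovery operationalizes "significantly correlated"
as per-gene Pearson correlation with the driver profile, BH-adjusted
across all tested targets at α = 0.05, with a sign constraint
(activated targets must correlate positively, repressed negatively).
The published analyses this mirrors quote only set-level FDRs, so the
per-gene rule is a documented package choice, not a reproduction.

The 16-entry cancer gene panel is literature-curated, shipped as
static packaged data, and excluded from every statistic.

## IHC scoring

The qualitative rule "stronger nuclear staining in a higher proportion
of cells than normal epithelium" is operationalized as the H-score:
nuclear intensity (0–3) × percent positive nuclei (0–100), range
0–300. The reference is 90 — intensity 3 in 30% of cells, the normal
bronchial pattern — and the comparison is **strict**, so a tumor
indistinguishable from normal is not called activated. A 0–3
intensity scale is assumed (the number of levels is a convention that
published scoring tables rarely state). Strong exclusively
cytoplasmic staining (cytoplasmic 3, nuclear 0) is its own category
and, having H-score 0, can never be called activated. Cohort
percentages are rounded to integers, so the three categories can sum
to 100 ± rounding.

## What the generators emulate — and what they do not

Each generator is a pure function of (parameters, seed), restores the
caller's RNG state, and returns its ground truth so every downstream
expectation is computable without re-reading the data.

* `make_cgh_cohort()` — 26 tumors over a 214-clone chromosome-3 map:
  5 carry a focal 3q26.33 amplicon (mean log2 2.2, comfortably above
  the 1.0 calling threshold) containing the 181.9–184.6 Mb interval,
  11 more carry a broad 3q26-qter gain (0.45), and 16 of 26 (~60%)
  carry a 3p loss at 8–10 Mb (−0.8). Clone noise is Gaussian,
  sd 0.1 log2. Category **counts are fixed by the design**; only
  carrier identity and noise depend on the seed, so the headline
  counts are seed-robust by construction.
* `make_tiling_cohort()` — abutting 50 kb clones over 177–186 Mb;
  five default amplicon intervals all contain 181.9–184.6 Mb with
  differing outer limits, and their boundaries sit on the clone grid,
  so recovery is exact and the intersection is exactly 2.7 Mb.
* `make_expression_dataset()` — 2000 genes × (20 tumors + 10
  normals), baseline N(8, 1) log2: 100 up / 100 down DE genes
  (±2), a 50-gene co-activated module (+1.5), SOX2 itself (+2), and
  60 + 30 target genes generated as ±0.8 × SOX2 + N(0, 0.5).
* `make_qpcr_fixture()` — nine genes × (5 amplified + 2 gained + 2
  reference tumors) with designed fold changes and mild log-normal
  noise (sd 0.04 log2); the margins between designed values and the
  2- and 5-fold rules are several noise standard deviations, so the
  truth labels are stable across seeds.
* `make_ihc_fixture()` — 51 cases: 34 above the reference, 5
  exclusively cytoplasmic, 12 normal-like, shuffled by seed.

Several defaults intentionally mirror published cohort compositions
(5/26 amplified, 34/51 activated, and so on) so that truth-recovery
tests double as worked examples. This circularity is deliberate and
worth stating plainly: passing them shows the pipeline recovers what
was embedded, not that it would reproduce any external cohort. The
generators also idealize aggressively — Gaussian noise on the log2
scale, no dye bias, no spatial artifacts, no batch effects, no probe
cross-hybridization, uniform clone density, a single contiguous
amplicon per tumor — so performance on real arrays will be worse than
on these fixtures, and the boundary-recovery guarantee (one clone
spacing) holds only while noise stays well below the amplification
threshold (the suite verifies sd ≤ 0.2 against mean 2.2).

## Problem sizes and verification

The test suite runs the statistical engines against independent
oracles at sizes chosen to finish in minutes on a single core while
still being decisive: exhaustive hypergeometric enumeration on
universes up to 12; 1000 random ES instances against a brute-force
running sum; permutation-p uniformity at 1000 sets × 1000 gene-set
permutations (Kolmogorov–Smirnov goodness of fit); 100 boundary-
recovery replicates; 20-replicate null-FDR simulations. The
acceptance script reruns the headline quantities from scratch in a
few seconds.

## Known limitations

No ploidy or purity correction, no allele-specific copy number, no
segmentation — profiles from noisy platforms should be segmented
upstream if per-clone thresholds are inadequate. The signature
derivation is a transparent stand-in, not a reproduction of any
specific published pipeline. GEO/SOFT and CEL parsing, Excel I/O and
live database queries are out of scope; inputs are plain BED / TSV /
GMT / JSON.
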