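---
title: "Peak fates, sibling groups and expression categories: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak fates, sibling groups and expression categories: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakfates)
```

## The problem

SWI/SNF (BAF) chromatin-remodeling complexes are assembled combinatorially
from mutually exclusive subunit families; the catalytic ATPase position is
filled by exactly one of two paralogs, BRG1 (SMARCA4) or BRM (SMARCA2).
When one sibling is depleted (e.g. by shRNA), the remaining complex can
lose occupancy at a site, retain it, or newly gain it — and the
transcriptional consequence at a target gene can be cooperative,
antagonistic, or only visible when both siblings are removed. peakfates
implements the analysis that connects these layers:

1. **Occupancy fates.** Each control-condition peak of a subunit is
   classified *lost* (no overlapping peak call of the same subunit after
   knockdown) or *retained/gained*. Gained and retained are deliberately
   pooled: a call appearing only after knockdown cannot be distinguished
   from a quantitative change that crosses the peak-calling threshold.
2. **Sibling groups.** Regions that lost subunit A are cross-classified
   by the fate of sibling B *in the same knockdown*: Group 1 (A lost,
   B lost) and Group 2 (A lost, B retained/gained); symmetrically Group 3
   and Group 4 for lost-B regions. Regions where the sibling never had a
   peak are reported separately as `sibling_absent` and excluded from the
   numbered groups — absence is not loss.
3. **Direct targets.** Each peak is assigned the gene whose TSS is
   nearest its midpoint (strand ignored, no distance cap, exact ties
   broken by the lexicographically smallest gene id so output is
   machine-independent).
4. **Expression categories.** Genes significant in *both* single
   knockdowns (BH q <= `fdr`, no fold-change cutoff) are placed in a
   quadrant by their fold-change signs: both up, both down, or the two
   discordant (antagonistic) quadrants.
5. **Rescue.** For each categorized gene the rescue index
   `1 - |lfc_double| / mean(|lfc_A|, |lfc_B|)` measures how far the
   double knockdown returns expression to baseline: 1 is complete rescue,
   0 none, negative values exaggeration. The mean (not max) of the single
   magnitudes makes the index symmetric in the two subunits.
6. **Statistics.** Per-group fold changes are tested against no change
   with a one-sample Wilcoxon signed-rank test (the hypothesis "no change
   in expression" for one set of fold changes is a signed-rank design; a
   two-sample rank-sum mode against a reference gene set is provided for
   sensitivity). Association between group membership and
   differential-expression status is a 2x2 Pearson chi-square, df 1, no
   continuity correction (a correction is available by flag). Multiple
   testing uses Benjamini-Hochberg throughout.

## Coordinate and overlap conventions

All user-facing coordinates are BED-style, 0-based half-open; internally
intervals live in `GRanges`. Co-location everywhere means *any overlap*
(at least one shared base) — no reciprocal-fraction thresholds, matching
standard blacklist-filtering practice. Chromosome names are matched as
exact strings. Strand is ignored for peaks; TSS strand is used only to
orient metaprofiles.

Recursive merging replaces any two same-chromosome intervals whose gap
(`next.start − prev.end`) is at most `merge_gap` (default 500 bp) by
their span, repeated to the fixpoint; the result is the unique transitive
closure and the operation is idempotent. We read "within 500 bp" as an
inclusive bound (gap <= 500); the choice is a package decision, and the
test suite pins it against an independent pairwise-closure oracle.

## The DE layer

`simple_de()` is deliberately plain: median-of-ratios size factors
(geometric-mean reference over genes with all-positive counts), log2 fold
change of normalized group means with pseudocount 0.5, a pooled-variance
two-sample t statistic per gene on log2 normalized counts, and BH
q-values. It exists so synthetic end-to-end runs have a self-contained DE
step; for real data the pipeline reads externally produced DE tables
(`read_de_table()`), and numerical agreement with shrinkage-based tools
such as DESeq2 is explicitly not a goal — downstream logic consumes only
(log2 fold change, q-value). Genes with zero counts in every sample are
excluded; a gene with zero pooled variance gets p = 1 when the group
means agree and p = 0 when they differ, and rows with missing values are
kept but flagged untestable.

## Signal model

Coverage is piecewise-constant over half-open intervals (bedGraph);
uncovered bases read 0. Metaprofiles average per-base signal in bins
around anchors (peak midpoints or TSS), default half-window 2000 bp and
bin size 10 bp. The bin size follows the usual track-generation setting;
the window half-width is a package default, since profile figures rarely
state one. Anchors closer than the window to a contig edge are
zero-padded and counted. TSS profiles stratify genes into expression
tertiles by rank (ties broken by gene id) and are strand-oriented: the
bin vector of a minus-strand gene is reversed before averaging. The
150-bp fragment extension is a property of track *generation* — the
synthetic emitter honors it by widening plateaus — and is never
re-applied at read time.

## What the synthetic generator emulates

`generate_truth()` builds evenly spaced peak loci shared by the two
siblings (subunit B offset by 60 bp so the siblings overlap without being
identical) and plants, by exact-count assignment rather than coin flips:

* loss fractions 0.40 (subunit A, BRG1-like) and 0.70 (subunit B,
  BRM-like) of each subunit's control peaks;
* among lost regions, a 0.6 sibling-lost fraction and a 0.05
  sibling-absent fraction (package choices — the real data determine
  these, but the classifier must handle all three outcomes);
* quadrant classes of exactly 89 / 111 / 115 / 116 genes plus 100
  redundant (double-knockdown-only) genes, each linked to a locus of the
  matching group so every affected gene is a direct target: antagonistic
  genes sit at sibling-lost loci with opposite-sign fold changes
  (|lfc| ~ N(1.5, 0.3), floored at 0.5) and near-zero double-knockdown
  residuals (sd 0.1); concordant genes get same-sign fold changes with a
  1.15-fold slight exaggeration in the double knockdown; redundant genes
  are affected only in the double.

Counts are negative-binomial (dispersion 0.01, baseline means log-normal
with median 500 and sdlog 0.8, per-sample depth factors 0.7–1.3, 3
replicates per condition) — a low-variability cell-line regime chosen
once from a power consideration: with a 3-vs-3 pooled t-test the planted
|lfc| = 1.5 effects must be recoverable with high probability or the
planted class counts could not be meaningfully compared. Peak boundary
jitter (uniform within ±`jitter_bp` per side) is the occupancy noise
knob; 0 is the noiseless limit, 50 bp the standard noisy setting. Decoy
peaks inside planted blacklist regions give the blacklist stage something
to remove.

What the generator does *not* emulate: read-level noise, irregular peak
spacing and width distributions, antibody-efficiency differences between
subunits, co-dependence between occupancy loss and expression effect
size, and DESeq2's dispersion shrinkage. A passing recovery suite
therefore demonstrates that the classification, categorization and
rescue logic are correct and noise-tolerant at the planted effect sizes,
not that the pipeline's statistical power matches any particular real
dataset.

## Numerical choices

* Exact Wilcoxon signed-rank p-values are computed by dynamic programming
  over the signed-rank sum distribution (doubled ranks keep tied average
  ranks integral) for n <= 20; beyond that, a normal approximation with
  tie and continuity corrections. Exact zeros are dropped and reported;
  an all-zero input returns p = 1 with an undefined-statistic flag.
* The chi-square test refuses tables with a zero margin rather than
  returning NaN.
* Degenerate inputs: an empty blacklist is the identity; an empty TSS set
  assigns nothing and warns; an empty anchor list is an error; empty peak
  files parse to empty sets.
* All randomness flows from one seed; synthetic emitters draw from
  deterministic per-artifact seed streams, so emitted files are
  byte-identical across runs, and the generator restores the caller's RNG
  state.

## Problem sizes

The default study-scale configuration is 2000 shared loci and 1000 genes
on two chromosomes — large enough that planted fractions are realized to
two decimals and category recovery tolerances are tight, small enough
that a full synthetic run (generation, occupancy classification, DE
integration, statistics, profiles) takes seconds. Tests use further
scaled-down configurations (120–400 loci) with proportionally scaled
class counts.

## Known limitations

* Fate classification is presence/absence of peak calls, as in the
  source analysis; no quantitative differential-binding statistic is
  attempted.
* Nearest-gene assignment uses TSS-to-midpoint distance with no cap;
  genes far from any peak on a gene-poor chromosome will still be called
  targets of distant peaks.
* The rescue index is undefined for genes absent from the double-knockdown
  table (dropped with a warning) and unstable when both single-knockdown
  fold changes are tiny — by construction it is only computed for genes
  significant in both single knockdowns.
* `simple_de()` with 2–3 replicates has limited power at small effect
  sizes; it is plumbing for synthetic runs, not a DE method.

## A worked example

```{r example, eval = FALSE}
report <- run_full(list(
  outdir = "pf_run",
  analysis = list(fdr = 0.05, merge_gap = 500, seed = 1),
  synthetic = list(seed = 1, n_peaks = 2000, n_genes = 1000,
                   de_mode = "counts", jitter_bp = 50)))
print(report)
```

The report records per-stage counts (peaks in and out of each filter,
fates, groups, categories, test results, rescue medians) and, for
synthetic runs, recovery metrics against the planted truth; everything is
also written as TSVs plus `report.json` under `outdir`.
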