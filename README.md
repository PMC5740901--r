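# peakfates

Occupancy-fate and expression-category analysis for mutually exclusive
chromatin-remodeler subunits.

SWI/SNF (BAF) complexes carry exactly one of two paralogous ATPase
subunits, BRG1 (SMARCA4) or BRM (SMARCA2). Depleting one sibling can make
the other lose occupancy at a site, retain it, or gain it — and the
transcriptional consequence can be cooperative, antagonistic, or only
visible in a double knockdown. `peakfates` implements the full analysis
that links these layers from standard genomics files (narrowPeak/BED peak
calls, a blacklist, a chromatin-state segmentation, TSS annotation,
bedGraph coverage, and per-contrast differential-expression tables):

* **Peak processing** — blacklist filtering (any-overlap) and recursive
  merging of peaks within a gap (default 500 bp) to its transitive
  closure; BED conventions (0-based, half-open) throughout, `GRanges`
  internally.
* **Fate classification** — each control peak of a subunit is `lost` or
  `retained_gained` by overlap against the same subunit's peaks after
  knockdown.
* **Sibling groups** — lost regions are cross-classified by the sibling's
  fate in the *same* knockdown: Group 1 (lose BRG1, lose BRM), Group 2
  (lose BRG1, keep/gain BRM), Groups 3/4 the mirror image for lost BRM
  regions; sibling-absent regions are reported separately.
* **Direct targets and categories** — peaks are assigned their
  nearest-TSS gene; genes significant (BH q ≤ 0.05, no fold-change
  cutoff) in *both* single knockdowns fall into four quadrants: Both Up,
  Both Down, BRG1-Up/BRM-Down, BRG1-Down/BRM-Up; genes significant only
  in the double knockdown form the redundant class.
* **Rescue** — for each doubly regulated gene the rescue index
  `1 − |lfc_double| / mean(|lfc_BRG1|, |lfc_BRM|)` quantifies how far the
  double knockdown returns expression to baseline (1 = full rescue,
  negative = exaggeration).
* **Statistics** — exact one-sample Wilcoxon signed-rank test of
  per-group fold changes against no change (full sign-enumeration null up
  to n = 20), 2×2 Pearson chi-square for enrichment of expression change
  among group-associated genes, Benjamini–Hochberg adjustment.
* **Signal** — bedGraph coverage tracks, per-region means and track
  correlations, binned metaprofiles at peak midpoints and at TSS
  stratified by expression tertile (strand-oriented), and group-vs-group
  cofactor comparisons.
* **Synthetic data with planted truth** — a generator that plants loss
  fractions, group labels, gene classes and fold changes by exact-count
  assignment, emits all the file formats above, and scores pipeline
  outputs against the truth, so every stage is verifiable end to end.

## Worked example

```r
library(peakfates)

report <- run_full(list(
  outdir = "pf_run",
  analysis = list(fdr = 0.05, merge_gap = 500, seed = 5),
  synthetic = list(seed = 5, n_peaks = 600, n_genes = 400,
                   quadrant_counts = c(both_up = 20, both_down = 24,
                                       a_up_b_down = 26, a_down_b_up = 28),
                   n_redundant = 30, de_mode = "direct")))
print(report)
#> peakfates run report (version 0.1.0)
#>   fates: A lost 232/579 (0.40), B lost 412/588 (0.70)
#>   categories: a_down_b_up=28, a_up_b_down=26, both_down=24, both_up=20
#>   regulated in both singles: 98; double-only: 30; affected total: 128 of 400 measured
#>   recovery: fate_accuracy_a=1.000, lost_fraction_a=0.401, ...
#>     category_accuracy=1.000, rescue_median_by_class.a_down_b_up=0.946, ...
```

Reading the output: 40% of subunit-A control peaks and 70% of subunit-B
control peaks are lost after their own knockdown (the planted fractions);
the four expression quadrants come back at exactly their planted sizes;
antagonistic genes (the `a_down_b_up` / `a_up_b_down` classes) show
median rescue indices near 1 in the double knockdown, while concordant
classes show slight exaggeration (negative index). On synthetic runs the
report also carries recovery metrics against the planted truth — all 1.0
in the noiseless limit.

Individual stages are plain functions (`read_peaks()`,
`filter_blacklist()`, `recursive_merge()`, `classify_fate()`,
`cross_classify()`, `nearest_gene()`, `quadrant_categorize()`,
`rescue_analysis()`, `wilcoxon_no_change()`, `chi_square_membership()`,
`profile_at_points()`, ...), and a thin CLI over them ships at
`inst/cli/peakfates.R` (subcommands `simulate`, `merge-peaks`,
`classify-fates`, `cross-classify`, `assign-genes`, `categorize`,
`rescue`, `profile`, `run-all`).

See `vignettes/peak-fate-analysis.Rmd` for the model, conventions,
parameter defaults and the synthetic generator's scope.

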