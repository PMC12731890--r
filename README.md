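# polarmeth

Discovery of **polar marginal** DNA methylation markers from Illumina-style
Beta-value matrices.

## What problem this solves

Cell mixtures — vascular tissue containing both endothelial cells and
infiltrating leukocytes, for instance — leave mixed DNA. To tell which cell
population a DNA molecule came from, a probabilistic methylation profile is
not enough: a single molecule is either methylated at a CpG or not. What
works are loci whose methylation Beta value (the fraction of methylated
cytosines, in [0, 1]) is **stably extreme in opposite directions** in the
two populations. `polarmeth` finds such loci from Beta matrices with paired
detection p-values, for any two (or more) groups of cell types.

The method is deliberately threshold- and set-based, with no test
statistics. Writing L(t) and H(t) for the loci that are strictly below the
low cutoff (resp. strictly above the high cutoff) in *every* passing
replicate of cell type t:

* a locus is **polar marginal** for a pair of cell types a, b if it lies in
  (L(a) ∩ H(b)) ∪ (H(a) ∩ L(b));
* the **intergroup markers** between groups A and B are
  (∩<sub>t∈A</sub> H(t) ∩ ∩<sub>t∈B</sub> L(t)) ∪
  (∩<sub>t∈A</sub> L(t) ∩ ∩<sub>t∈B</sub> H(t)),
  labeled by the group in which they are methylated.

Default cutoffs: 0.1/0.9 for within-group comparisons (stringent), 0.2/0.8
for the between-group marker search (relaxed). Measurements with detection
p ≥ 0.05 are masked first; a locus dropped in one replicate is rescued by
the remaining replicates of that cell type.

The package also ships a curated 47-locus endothelial/leukocyte reference
panel (`ec_lc_marker_panel()`), a probe-manifest annotation module
(promoter/TSS, CpG island/shore/shelf, enhancer summaries), a joint
quantile-normalization batch-effect check, and a seeded synthetic
two-platform generator with planted ground truth for validation.

## Worked example

Simulate a two-platform study (5 endothelial-like cell types on a
450K-like array, 11 leukocyte-like types on a 27K-like array, 47 planted
markers) and run the whole pipeline:

```r
library(polarmeth)

sim <- generate_synthetic(synthetic_design(dropout_rate = 0, seed = 7))
res <- run_full_pipeline(pipeline_config(
  sim$platform_a, sim$platform_b, sim$sheet, "report",
  manifest = sim$manifest, norm_check = TRUE))

table(res$markers$direction)
#> ECs_HIGH LCs_HIGH
#>       34       13

identical(sort(res$markers$probe_id), sort(sim$ledger$intergroup$probe_id))
#> [1] TRUE
```

All 47 planted markers are recovered with their directions: 34 loci
methylated in every EC-like type and demethylated in every LC-like type,
13 the other way around. The report directory holds the marker table,
per-group pairwise polar counts and category heatmap CSVs, the
marginal-overlap summary, the annotation summary, the normalization
comparison and a plain-text run manifest; reruns are byte-identical.

The packaged reference panel summarizes like this:

```r
summarize_annotations(ec_lc_marker_panel())[, 1:8]
#>   direction n_markers n_tss n_body_only n_island n_shore n_shelf n_enhancer
#> 1   EC_HIGH        34    13           6        1       3       2          1
#> 2   LC_HIGH        13     6           4        5       2       1          1
```

Only 1 of the 34 EC-methylated loci sits in a CpG island versus 5 of the
13 LC-methylated ones — island methylation is the rarer, more informative
event — and each direction contains exactly one enhancer locus.

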