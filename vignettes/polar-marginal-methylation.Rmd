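---
title: "Polar marginal filtering for methylation marker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polar marginal filtering for methylation marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarmeth)
```

## The problem and the model

Methylation microarrays report, for each CpG locus and each DNA sample, a
*Beta value*: the estimated fraction of methylated cytosines at that locus,
a number in [0, 1]. When the question is "which cell type did this DNA
molecule come from?", a probabilistic methylation profile is of limited
use — a single molecule is either methylated at a locus or it is not. What
helps is a locus whose Beta is *extreme* in every sample of one cell
population and extreme *in the opposite direction* in the other: then the
methylation state of that single locus is close to a deterministic label.

`polarmeth` implements this marginal-filtering logic as a deterministic,
threshold-based set-algebra pipeline. There is no parametric model, no test
statistic and no FDR machinery — deliberately. The procedure is:

1. **Cleaning.** Every measurement with detection p-value ≥ 0.05 is masked
   (strictly `p < 0.05` survives). A locus dropped in one replicate can be
   rescued by the remaining replicates of the same cell type
   (`min_passing_replicates`, default 1).
2. **Marginal classification.** A Beta strictly below the low cutoff is
   `LOW` (stably demethylated), strictly above the high cutoff `HIGH`
   (stably methylated), otherwise `INTERMEDIATE`; missing values are
   `UNEVALUABLE`. Boundary values are intermediate by construction, so no
   tie-breaking is ever needed.
3. **Stability across replicates.** A locus enters a cell type's stable
   LOW set only if *every* passing replicate is LOW (analogously HIGH).
4. **Polarity.** For two cell types *a*, *b*, the polar marginal loci are
   `(a.low ∩ b.high) ∪ (a.high ∩ b.low)`. Within a group, a locus is
   *distinctive* if at least one pair of cell types is polar at it.
5. **Intergroup markers.** With `A_low` the intersection of the LOW sets
   of *all* group-A cell types (similarly `A_high`, `B_low`, `B_high`),
   the markers are `(A_high ∩ B_low) ∪ (A_low ∩ B_high)`, each labeled by
   the group in which it is methylated.

The motivating application is distinguishing endothelial-cell (EC) from
leukocyte (LC) DNA: a 47-locus reference panel of this kind (34 EC-methylated,
13 LC-methylated loci, with gene, island and enhancer annotations) ships with
the package as `ec_lc_marker_panel()`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p_threshold` | 0.05 | detection p-value cutoff, strict `<` |
| `min_passing_replicates` | 1 | replicates needed for a locus to stay evaluable per cell type |
| intragroup cutoffs | 0.1 / 0.9 | stringent marginal boundaries for within-group comparisons |
| intergroup cutoffs | 0.2 / 0.8 | relaxed boundaries for the between-group marker search |
| `aggregate_first` | `FALSE` | classify the replicate mean instead of every replicate |

The stringent pair keeps within-group lists short (only the most clearly
polar loci); the relaxed pair yields a more extended marker list between
groups, where unanimity across every cell type of both groups is already a
strong filter. Both are always overridable.

Two readings of "stable across replicates" are defensible: intersecting
per-replicate marginal sets (every replicate must be marginal) or
thresholding the replicate mean. The per-replicate intersection is the
stricter reading and is the default; `aggregate_first = TRUE` switches to
the mean-based reading. On tight data the two agree almost everywhere; they
diverge exactly at loci with one discordant replicate.

## Cross-platform harmonization and the normalization check

When the two groups were measured on different array generations (e.g. a
450K-like and a 27K-like platform), the intergroup stage runs on the
intersection of the probe sets (`intersect_platforms()`,
`combine_platforms()`), while each within-group analysis uses its
platform's full probe set.

Because the platforms differ, one may worry about batch effects.
`compare_with_without_normalization()` recomputes the marker set after
joint quantile normalization of the platform-concatenated matrix and
reports both sets with their differences — it makes no automatic choice.
The normalization itself is the per-rank-mean convention: every column is
mapped onto the average empirical distribution, tied values receive the
mean of the reference values at their tied ranks, missing values are
skipped and unequal column sizes are matched by linear interpolation. The
map is idempotent and preserves within-column ranks.

Two caveats are worth knowing. First, quantile normalization can only
*remove* a monotone distributional difference; when columns differ by a
pure shift it restores the planted truth and typically *expands* the
marker list. Second — and less obviously — when the two groups carry
different *proportions* of extreme loci (e.g. 34 markers methylated in one
group versus 13 in the other), forcing all columns onto a common
distribution moves rank-boundary loci across the cutoffs and can *shrink*
the marker set. This is a genuine property of joint quantile normalization
under composition differences, not an implementation artifact, and it is
one reason a threshold-based analysis may legitimately prefer original,
unnormalized values: thresholding at fixed Beta cutoffs does not require
the two platforms' distributions to be equalized.

## The synthetic generator

`generate_synthetic()` emulates the structure of a two-platform,
two-group methylome study so that every stage is testable without
downloads, and records the exact planted truth in a ledger:

* **Structure.** 5 EC-like cell types on a 5,000-locus 450K-like platform
  and 11 LC-like types on a 1,200-locus 27K-like platform, 1,000 shared
  loci, 3–6 replicates per type.
* **Signal.** Each (locus, cell type) has an intended category; values are
  drawn from Beta distributions with means 0.05 / 0.5 / 0.95 and
  concentration 600. That concentration corresponds to a replicate SD of
  about 0.009 near Beta = 0.05 — the low technical variance arrays show at
  the extremes — and makes ≥ 99% of intended-LOW draws fall below 0.2.
* **Planted architecture.** 34 + 13 intergroup markers on shared loci and
  31 / 57 within-group polar pairs; the remaining loci are background:
  70% marginal with a 5:1 LOW:HIGH imbalance, of which 90% (LOW) / 60%
  (HIGH) are marginal in both groups and the rest in one group only.
* **Dropout.** Each measurement fails detection with probability 0.05
  (passing p-values uniform on [0, 0.05), failing ones on [0.05, 1]).

What the generator does *not* emulate: probe-type chemistry bias, the
heavy-tailed, sometimes trimodal Beta distributions of real intermediate
loci, spatial/chip batch structure, and cross-reactive probes. Passing the
recovery tests therefore shows the *set algebra* is correct under the
stated noise model — it does not certify performance on real arrays, where
cutoff placement absorbs most of the extra messiness.

## Numerical and degenerate-input choices

* All set outputs are sorted lexicographically by probe ID; results are
  invariant to sample-column and cell-type enumeration order, and the full
  pipeline is byte-deterministic (no randomness outside the generator).
* A cell type with zero passing replicates at a locus contributes nothing
  — the locus is unevaluable for that type, which excludes it from the
  type's stable sets (and hence from any marker requiring that type).
* Quantile-normalization idempotence is exact on complete matrices; with
  missing values the interpolation step makes it exact only up to the
  interpolation grid, so the idempotence guarantee is stated for complete
  columns.
* Probe IDs are opaque strings matched exactly (no `cg` prefix
  assumption); coordinates are 1-based and strand is ignored throughout.

## A worked example

```{r example, eval = FALSE}
sim <- generate_synthetic(synthetic_design(dropout_rate = 0, seed = 7))
out <- file.path(tempdir(), "report")
res <- run_full_pipeline(pipeline_config(
  sim$platform_a, sim$platform_b, sim$sheet, out,
  manifest = sim$manifest, norm_check = TRUE))
table(res$markers$direction)
#> ECs_HIGH LCs_HIGH
#>       34       13
identical(sort(res$markers$probe_id), sort(sim$ledger$intergroup$probe_id))
#> [1] TRUE
```

The annotation summary of the packaged reference panel:

```{r panel}
summarize_annotations(ec_lc_marker_panel())[, 1:8]
```

The island and enhancer columns (1/34 and 5/13 in CpG islands; one
enhancer locus per direction) are asserted in the test suite. The
promoter (TSS) counts use an any-gene-match rule — a locus annotated
`TSS200`/`TSS1500` for *any* of its genes counts once — and are reported
as computed; under multi-gene annotations no single matching rule is
canonical, so they are deliberately not pinned to any external figure.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on generated data at
desk scale, sizes chosen to exercise every code path while keeping runs
short: oracle-equivalence on 200 random datasets of 30–120 loci × up to
~25 samples against a brute-force per-locus scan; exact planted-marker
recovery on the full default design across 20 seeds; the overlap-fraction
check on a 10,000-shared-locus design; end-to-end determinism on a
~1,000-locus bundle. Real studies (hundreds of thousands of probes) run
through the identical code path; all operations are vectorized per cell
type and scale linearly in loci × samples.

## Known limitations

* Threshold-based discovery has no error control: a marker list's
  reliability rests on replicate unanimity and cutoff placement, not on a
  sampling model.
* Unanimity across *all* cell types of both groups makes the intergroup
  list sensitive to a single aberrant cell type or low-quality replicate
  series; `min_passing_replicates` mitigates dropout but not systematic
  bias.
* Cross-platform intersection restricts the search space to probes present
  on the smaller platform.
* The package starts from Beta values; raw-intensity (IDAT) preprocessing
  and probe-level QC are upstream concerns.
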