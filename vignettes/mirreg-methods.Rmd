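---
title: "Methods: integrated miRNA-mRNA regulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA-mRNA regulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirreg)
library(dplyr)
```

## The problem

In a small paired tumor/normal expression study — the motivating design is
six patients, each contributing a tumor and an adjacent-normal sample
profiled on both an mRNA and a miRNA array — we want to know which miRNAs
plausibly drive which transcript changes. mirreg implements the full chain:
paired differential expression, a per-miRNA *regulation value*, sign-based
classification of differentially expressed genes against their net miRNA
regulation, target-predictor set intersection, promoter CpG-density classes,
hypergeometric term enrichment, and delta-delta-Ct qPCR analysis. A
synthetic-data generator plants known regulatory structure so every stage
can be validated end to end without any external download.

## Differential expression with six pairs

Raw intensities are filtered to features detected in at least one sample,
log2-transformed and median-centered per array (`detection_filter()`,
`log2_median_center()`). Because six pairs are too few for significance
alone to be trusted, two layers are reported distinctly and never merged:

1. **Consistent direction** (`consistent_direction()`): a feature is `up`
   only if tumor − normal is positive in *every* pair, `down` only if
   negative in every pair. An exact-zero difference breaks consistency —
   the wording "consistently up- or down-regulated" is read strictly.
2. **Paired SAM-style statistic** (`diff_expression()`):
   `d = mean(delta) / (se(delta) + s0)`. The fudge factor `s0` is the 5th
   percentile of the feature-wise standard errors — a deliberate
   simplification of the original coefficient-of-variation minimization,
   chosen because it is transparent, monotone and adequate at this scale;
   the percentile is configurable (`sam_config()`). With `s0 = 0`, `d` is
   the one-sample t statistic on the paired differences.

Significance comes from sign-flip permutations of the per-patient delta
vectors. With `n` pairs there are `2^n` sign patterns; whenever all of them
fit inside the permutation budget (64 at `n = 6`, well under the default
1000) the exhaustive set is used, making the result seed-independent. The
q-value of a feature is the median across permutations of the count of null
`|d|` values at least as large as its observed `|d|`, divided by the number
of observed `|d|` at least as large, capped at 1 and monotonized so q never
decreases as `|d|` increases. Degenerate features (zero mean and zero
scatter) get `d = 0`; a constant nonzero delta with zero scatter is
maximally significant. On complete-null data (1000 features, 6 pairs) the
fraction of `q < 0.1` calls averages far below 0.1 across seeds — the
estimator is conservative, which is the right failure mode for a marker
screen.

Probe-to-gene collapsing is intentionally *not* performed: features stay at
probe level through differential analysis, and gene-level joins use
any-probe semantics, because no defensible collapse rule is implied by the
design.

## Regulation values and the three-class partition

For each *variable* miRNA (the consistent-direction list — using only
FDR-significant miRNAs would usually leave a single regulator, which cannot
classify hundreds of genes), the regulation value is

```
r = delta_e / t_expressed
```

where `delta_e` is the miRNA's mean per-pair log2 change and `t_expressed`
its number of predicted targets among *expressed* (detection-filtered, not
merely differential) genes. A gene's regulation value `R_g` is the sum of
`r` over all its variable regulators; genes with no such regulator have a
null `R_g`. Classification (`classify_gene()`) is purely sign-based:

* `others` — `R_g` null, exactly zero, or within `epsilon` of zero
  (default `epsilon = 0`: only no-regulator or exact cancellation);
* `anti_correlated` — sign of `R_g` opposite to the gene's own direction
  (the miRNA-repression signature);
* `correlated` — signs agree.

Because only signs matter, rescaling every `delta_e` by a positive constant
leaves the partition unchanged — a property the tests assert. The summary
(`classification_summary()`) reports per class the up/down counts and their
percentages of all up- and all down-regulated genes, rounded half-up to two
decimals as report tables conventionally print them (`percent_of()`; base
R's round-half-even would disagree on values like 4.475).

## Target maps, overlap, CpG classes, enrichment, qPCR

**Target maps** are sets of unique (miRNA, gene) pairs per predictor;
identifiers are normalized (miRNA names lower-cased, gene symbols
upper-cased — mature-miRNA capitalization is inconsistent across sources).
`pair_overlap()` counts shared pairs between predictors and reports each
side's percentage.

**Promoter CpG classes** use the established windowed criteria: sliding a
500-bp window (step 1 bp), a promoter is HCG if any window has GC fraction
≥ 0.55 *and* CpG observed/expected ratio ≥ 0.75, LCG if no window reaches
O/E 0.48, ICG otherwise, with `O/E = (#CpG × length) / (#C × #G)` and N
bases excluded from all counts and the effective length. The thresholds are
the cited method's published values, restated here because the analysis text
cites the method without numbers; all are configurable (`cpg_config()`).
One documented oddity: the source text's parenthetical glosses attach
"intermediate" to LCG and "low" to ICG; the acronym meanings (L = low,
I = intermediate) are implemented.

**Enrichment** (`enrich()`) is the standard hypergeometric upper tail with
Benjamini–Hochberg adjustment, reporting the C/O/E/R/rawP/adjP record per
term and flagging `adjP < 0.001` by default. The reference universe is the
set of measured genes carrying at least one annotation term — a choice that
must be made explicitly because web enrichment services rarely state
theirs; consequently absolute p-values depend on it, while `R = O/E` is
robust and is what the package treats as the comparable statistic. Flat
annotation is assumed (no ontology-graph propagation).

**qPCR** uses the Livak `2^(-ddCt)` convention: `dCt = Ct_target −
Ct_reference` (U6 snRNA for miRNA, GAPDH for mRNA), `ddCt = dCt_case −
dCt_control`. Technical replicates are averaged before `dCt`; when case
records lack matched pairs, the control reference is the mean control
`dCt` (the serum-panel convention against cancer-free donors). Group tests
are paired or Welch t-tests; an all-zero paired difference vector is
degenerate and reported as `t = 0, p = 1` with a warning rather than an
error.

## What the synthetic generator emulates

`generate_bundle()` produces the study conditions every test runs under:
6 patient pairs, 2000 genes, 150 miRNAs, baseline log2 intensities
N(8, 2), Gaussian log2 noise sd 0.1, planted consistent shifts of
magnitude 2 (jittered ±25%) for 3%/6% of genes (up/down) and 8%/8% of
miRNAs, 2% of genes planted below the detection floor in every sample, and
a planted bipartite repression network: each variable miRNA draws 3–8
targets and shifts each by `-repression_effect × shift / t` (repression 2
by default), so planted targets are anti-correlated with their regulators
by construction. Truth tables are derived from the realized edges and
written separately; the pipeline never reads them.

Two generator choices deserve explanation:

* **Planted features occupy the upper intensity stratum** (baseline +3.5
  to +5.5 log2 over the bulk). This mirrors the empirical observation that
  miRNA-regulated genes tend to be highly expressed, and it pins each
  array's median to the unshifted features: per-array median centering then
  cancels exactly across a pair, so at `noise_sd = 0` null features have
  deltas of exactly zero and recovery of the planted sets is exact. Without
  this, asymmetric planted shifts would drag column medians apart and
  median centering would inject a constant, consistently signed
  pseudo-delta into every null feature.
* **Decoy edges** from non-variable miRNAs are included in the target map;
  they carry no expression signal and exercise the restriction and join
  logic.

What the generator does *not* emulate: platform-specific intensity
distributions, probe-sequence effects, correlated noise across features,
partial detection patterns, or genes regulated by a mixture of planted and
unplanted miRNAs. Passing recovery tests therefore demonstrates the
pipeline's correctness on data satisfying its own model assumptions, not
performance on any particular array platform.

`generate_promoters()` constructs sequences per CpG class from weighted
dinucleotide draws (CpG-rich for HCG; CpG-present but AT-rich for ICG;
CpG-free — every C-G adjacency broken — for LCG) and verifies each against
the classifier before emitting it. `generate_annotation()` plants one term
drawing half its members from the planted up-regulated genes.

## Numerical choices and degenerate inputs

* Percent reporting: half-up rounding to two decimals everywhere.
* Ties in the direction filter: exact-zero per-pair delta ⇒ `none`.
* `epsilon` for the null band of `R_g`: 0 exactly, configurable.
* Permutation q monotonization: running maximum along decreasing `|d|`
  (conservative direction).
* Counting `|d_null| ≥ |d_obs|` uses exact strict-rank arithmetic
  (`findInterval(..., left.open = TRUE)`), safe for ties and infinities.
* `cpg_oe_ratio` is 0 by convention when a window lacks C or G; windows
  with effective length < 2 are skipped; sequences shorter than the window
  are classified as a single window with a message.
* Degenerate paired t (all differences zero): `t = 0, p = 1`, warning.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run at 400–2000 genes, 40–150 miRNAs,
6 pairs, exhaustive 64-pattern permutation sets, a 20-replicate null
calibration at 1000 features, a 3-seed noisy-recovery panel, and 60
constructed promoters — sizes chosen so the full chain, including its
brute-force oracles, exercises every code path at desk scale.

## Known limitations

* The consistent-direction filter admits ~3% of pure-noise features per
  direction at 6 pairs (2 × 0.5^6); it is a screening filter, not an error
  rate guarantee — which is exactly why the permutation FDR layer is
  reported alongside it.
* `t_expressed` is computed once against the detection-filtered gene set of
  the dataset, not per comparison.
* Enrichment p-values depend on the configurable universe definition; only
  the ratio `R` should be compared across tools.
* No amplification-efficiency correction in qPCR; fold changes assume
  perfect doubling per cycle.
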