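---
title: "Methods: stage-resolved follicle transcriptome dynamics and cell dialogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-resolved follicle transcriptome dynamics and cell dialogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(follicledyn)
```

`follicledyn` analyzes replicated, stage-resolved bulk RNA-seq of
developing ovarian follicles: oocytes (OC) across nine stages (T1, T2,
T3a, T3b, T4, T5a, T5b, T6, T7), granulosa cells (GC) from T2 onward, and
cumulus cells (CC) in the antral stages T6–T7. This vignette documents the
models and rules each stage implements, the tunable parameters and their
defaults, the numerical choices made where the design was genuinely open,
and what the synthetic-data tests do and do not establish about real data.

## Preprocessing

Expression arrives as a genes × samples FPKM matrix with per-sample
metadata (cell type, stage, replicate). Two operations precede everything
else:

* **Low-expression filter.** A gene is dropped when its FPKM is below
  `min_fpkm` (default 1) in *every* sample; one sample at or above the
  floor keeps it. The boundary is inclusive on the keep side — removal
  requires strict `FPKM < 1` everywhere — which is the literal reading of
  "below 1 in all samples were filtered". The filter is idempotent and
  monotone in the threshold.
* **Replicate averaging.** Per gene, cell type and stage, the arithmetic
  mean of replicate FPKM, with stages ordered by the configured series.
  The stage series is configuration (`default_stage_series()`), not a
  hard-coded universe, so other stage layouts and cell types reuse the
  machinery unchanged.

Transcriptome correlations (`pairwise_correlation`) are Pearson on
log2(FPKM + 1) by default. The log transform is our choice — FPKM is
strongly heteroscedastic and log correlation is the field standard — and a
raw mode is kept for exactness checks. Two profiles are inner-joined on
gene symbol before correlating (the only assumption-free treatment of
non-shared genes) and the join size is attached to the result so silent
shrinkage is visible.

## Differential expression

The DEG criterion is a *rule*, not an engine: significant when
`FC >= 2` or `FC <= 0.5` and `P < 0.05`. We implement the rule over a
transparent test rather than a specific quantifier's internals:

* **Fold change** is `(mean_b + c) / (mean_a + c)` on replicate-mean FPKM
  with pseudocount `c = 0.01`, the smallest stable choice at FPKM scale;
  it is recorded in every result object.
* **P-value** is a two-sided Welch t-test on log2(FPKM + 1) across
  replicates (vectorized; cross-checked against `stats::t.test` in the
  test suite). P-values are deliberately *not* multiplicity-adjusted —
  the criterion is a raw P < 0.05 — though a Benjamini–Hochberg flag
  exists (`adjust = TRUE`, off by default).
* **Degenerate groups.** With a single replicate in either group no
  t-test exists; p is set to 0 so the fold-change rule alone decides, and
  the result is flagged (`single_replicate` attribute, logged by the
  pipeline). When both groups have zero variance, p is 1 for equal means
  and 0 otherwise.
* **Orientation.** FC is group_b over group_a: the later stage in
  adjacent-stage comparisons, the first-named (numerator) cell type in
  cross-cell-type comparisons. Swapping the groups inverts FC and swaps
  UP/DOWN (exactly so at pseudocount 0).

Stage-specific DEGs at a target comparison subtract the union of
significant genes of every *other* comparison in the same scan. Whether
cross-cell-type DEGs should also be subtracted is not decidable from the
analysis description we follow; we restrict to the same scan and expose an
`extra` argument for callers who want the wider union. The pivot split
assigns a gene to `before` when its mean log2(FPKM + 1) over stages
strictly before the pivot exceeds the mean from the pivot onward — a
deliberate strict inequality so the two sets partition the input.

## Temporal profile clustering

The clustering follows the short time-series expression miner scheme:

1. **Model profiles.** All `(2c + 1)^(S - 1)` integer delta sequences over
   the S-stage series with per-transition change in [−c, c], flat profile
   dropped. Defaults `c = 2`, `m = 50` (the analysis this package
   re-implements reports 50 clusters; c is not recoverable from it and is
   exposed as configuration).
2. **Selection.** `m` profiles by greedy max–min under the distance
   1 − Pearson(value vectors). Randomized first picks would make runs
   incomparable, so the first pick is deterministic: the profile with the
   largest absolute final value, ties broken by lexicographically smallest
   delta sequence; the same tie-break applies at every step. Greedy
   max–min spreads the selected set but is *not* a global optimizer of the
   minimum pairwise distance (verified on the n = 4, c = 1 space, where
   the global optimum is strictly better); we keep greedy because it is
   the scheme's standard, deterministic and fast, and the tests verify its
   step-invariant exactly.
3. **Assignment.** Genes as log2(FPKM + 1) anchored at the first stage,
   assigned to the profile with maximal Pearson correlation; ties to the
   lowest profile id; zero-variance genes excluded with a flag rather than
   silently dropped.
4. **Significance.** The null permutes each gene's stage order
   independently in every iteration and re-assigns. A profile's raw p is
   the add-one-smoothed fraction of permutations whose count reaches the
   observed count, then Bonferroni-corrected across the m profiles.
   **Resolution matters here:** the smallest attainable corrected p is
   `m / (n_perm + 1)`, so with m = 50 profiles a run needs
   `n_perm >= 1000` before anything *can* clear α = 0.05. The
   spec-conventional default of 500 permutations is kept for
   compatibility, but recovery analyses in this package use
   `n_perm = 2000` (resolution 0.025); calibration checks are one-sided
   and unaffected.
5. **Categories.** A significant profile with all deltas ≥ 0 (one
   positive) is continuously up; mirrored for down; other significant
   profiles fluctuate; everything else is non-significant. Gene-level
   category fractions are taken over all clustered genes and sum to 1.

## Dialog inference

A gene is *expressed* in a cell type when its replicate-mean FPKM reaches
`threshold = 5` at one or more stages. For every database pair and ordered
cell-type combination (within-type included), an edge exists iff the
ligand passes in the source and the receptor in the target. Per cell type
and role, an expressed pair-member gene is HOMOLOGOUS when all its dialogs
stay within the cell type, HETEROLOGOUS when all leave it, HYBRID with
both, and NONE when expressed but partnerless everywhere — the four
categories partition expressed pair-member genes. Gene symbols are
compared uppercased with original case preserved in outputs, since
database/table case mismatches are the dominant practical failure. Pair
sets between cell types (union of both directions) feed exact Venn counts.
A per-stage expression mode exists but is off by default, keeping the
across-stages rule as the faithful default.

## Maternal-effect genes, imprinting, methylation

The maternal-effect rule on an embryo series with MII first: reference
FPKM strictly above `ref_min = 2` and at least one later stage strictly
below `ratio = 0.5` of the reference (both strict: literal reading of
"larger than 2" and "less than half"). A zero reference yields an infinite
ratio and is never flagged. The four-group clustering of flagged genes is
k-means on per-gene standardized log2(FPKM + 1) profiles — the original
analysis says only "unsupervised clustering"; k-means with a fixed seed,
`nstart = 10`, and labels C1..Ck ordered by descending cluster size is
chosen for determinism and reproducibility.

Imprinted-gene status per (gene, stage) is SILENT below `silent_max = 1`
FPKM, HIGH at or above `high_min = 5`, MILD between. These two cut points
are *not* stated by the analysis we re-implement; they align with its own
FPKM conventions (filter at 1, dialog threshold at 5) and are echoed in
every report so downstream users see them.

Promoter methylation is the mean CpG level within the closed interval
±`window = 1000` bp of the TSS, strand-independent (a symmetric window
makes strand irrelevant; positions are 0-based). Overlap assignment runs
through IRanges; the tests verify it against an independent O(n·m)
interval scan.

## The synthetic-data generator

`synth_config()` fixes the study conditions the tests run under; its
defaults were set once, from the conditions the validation plan states,
and are not tuned per run:

* three replicates per (cell type, stage); 200 background genes; baseline
  expression N(3, 1.5²) on the log2(FPKM + 1) scale; replicate noise
  N(0, 0.1²) on the same scale. Noise lives on the analysis scale so
  planted effect sizes are exact where the pipeline measures them;
  FPKM = max(2^x − 1, 0).
* a planted DEG burst between T3b and T4: 10 up + 10 down at
  |log2FC| = 2 in each of OC and GC, applied from T4 onward. Planted DEG
  genes get a baseline floor of 2 log2-units so a −2 shift never collapses
  to zero FPKM — without the floor, exact zero-noise recovery would be
  impossible for down-shifted genes near zero.
* optional planted temporal classes (monotone up/down, a down–up–down
  fluctuating template, flat), 10 imprinted genes silent in OC
  (FPKM ≈ 0.07) but expressed in GC/CC, planted ligand categories (5 per
  category per cell type) with CC dialogs constructed as a subset of the
  OC–GC dialogs, 30 planted maternal-effect genes decaying at the 2-cell
  stage with margin (reference in [5, 100], decay factor ≤ 0.3), and CpGs
  placed inside and outside non-overlapping ±1 kb promoter windows with
  recorded in-window means.

Every planted structure is recovered by its pipeline stage exactly at zero
noise and with high probability at the default noise level; the truth is
emitted with every dataset (`truth.json` on disk).

**What the generator does not emulate:** count-level sampling noise
(FPKM is generated directly), gene–gene correlation, library-size and
batch effects, dropout, or realistic gene counts. Passing the planted
tests shows the *rules and algorithms* are implemented correctly and are
calibrated under their stated noise model — not that the thresholds are
optimal for any particular real dataset.

## Problem sizes and runtime choices

The validation suite scales its simulations to desk size as a package
design choice: 200-gene expression matrices, 100-instance oracle sweeps,
200 permutations for the noise-calibration bound and 2000 for recovery
(see the resolution argument above), and pipeline determinism checks at
`n_perm = 100`, `profile_m = 10`. The nine-stage profile space at c = 2
(390,625 candidates) is enumerated exactly; greedy selection of 50
profiles takes a few seconds.

## Known limitations

* The Welch-on-log test is not a count-based GLM; with 2–3 replicates its
  p-values are coarse, and the DEG rule leans on the fold-change arm. This
  mirrors the rule-first definition it implements.
* Permutation significance is bounded by `m / (n_perm + 1)`; small
  permutation budgets silently cap attainable significance (documented
  above, asserted in tests).
* Dialog inference is presence/absence at a threshold; it scores no
  communication probability and uses no pathway prior.
* The maternal-effect four-group labels depend on k-means initialization
  policy; with the fixed seed and size-ordered relabeling they are
  deterministic, but they are not a model-based clustering.
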