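---
title: "Identifying core higher-alcohol-producing bacteria: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying core higher-alcohol-producing bacteria: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huangjiucore)
```

## The scientific problem

During the 10-day fermentation of northern-style Huangjiu (a Chinese grain
wine brewed from broomcorn millet with a wheat-Qu starter), higher alcohols
(HAs; fusel alcohols with more than two carbons, e.g. 2-methyl-1-propanol,
3-methyl-1-butanol, phenethyl alcohol) accumulate and shape both flavor and
hangover. Yeasts are the canonical HA producers, but the bacterial
consortium carried by the open-environment starter may also contribute.
`huangjiucore` implements a desk-scale version of the analysis that screens
for *functional core HA-producing bacterial genera* from paired
genus-abundance and GC-MS concentration data:

1. internal-standard semiquantification of HAs,
2. alpha-diversity summaries of the community,
3. genus–HA Pearson correlation networks with Benjamini–Hochberg FDR
   control,
4. a two-way orthogonal PLS (O2PLS) decomposition with a permutation null
   for variable selection, and
5. a two-criterion core filter (top-quintile abundance + correlation with
   stably detected HAs).

Raw sequence processing (QC, merging, OTU clustering, taxonomy) is out of
scope: the package starts from genus-level abundance tables.

## Semiquantification

Concentrations come from single-point internal-standard semiquantification,

$$C = d \, \frac{A_c}{A_{is}} \, C_{is},$$

with $A_c$, $A_{is}$ the analyte and internal-standard (2-octanol) peak
areas, $C_{is}$ the in-vial internal-standard concentration and $d$ the
vial dilution factor. With the study's vial recipe (0.5 mL sample brought
to 6.0 mL, spiked with 60 µL of 8800 µg/L 2-octanol) the in-vial standard
is $8800 \times 60 \times 10^{-3} / 6.0 = 88$ µg/L and $d = 6.0/0.5 = 12$.
The published relation prints the constant 12 without derivation; we
interpret it as this vial dilution factor, and both quantities are
configuration fields (`quant_config()`), never hard-coded, so other
interpretations can be expressed.

Replicate-level concentrations are summarized per sampling day as mean ±
standard error over the *detected* replicates; a day is "not detected" (ND)
only when all replicates are ND. ND is always an explicit mask, never a
zero — a compound below the method's detection capability is a different
observation from a measured zero. Downstream stages decide how NDs enter
computation (see below).

Summary statistics mirror the study's reporting: per-day totals over
detected compounds, per-compound detection counts with a *stable* flag
(detected in ≥ 5 of the 6 days; the threshold counts day-level summaries,
not individual replicates, matching the granularity of the published
table), a strict > 1000 µg/L "high content" filter, and an
annotation-driven classifier for straight-chain saturated alkan-1-ols. The
classifier is table-driven (a packaged annotation of all 23 compounds with
chemistry flags) rather than name-parsing, because suffix heuristics
misclassify unsaturated or branched "-1-ol" names such as
9,12-octadecadien-1-ol.

```{r table1}
t1 <- ha_table1()
total_concentration(t1, 10)          # ug/L on the final day
classify_alkanols(t1)
```

## Diversity summaries

The Simpson index is reported in its dominance form $\sum_i p_i^2$, so
that larger values mean lower diversity (the direction used in the study);
the Gini–Simpson complement is available via `complement = TRUE`. Richness
uses the bias-corrected Chao1,
$S_{obs} + F_1(F_1-1) / (2(F_2+1))$,
which stays defined when no doubletons exist; the classical
$S_{obs} + F_1^2/(2F_2)$ form is optional. Both are one-line formulas, but
the package computes them explicitly because the variants matter
(dominance vs complement; +1 correction vs classical); the test suite
cross-checks both against `vegan`.

Genus aggregation sums rows within identical rank labels, pooling
unclassified lineages under the deepest named ancestor with a
`norank_<rank>_<name>` label (e.g. `norank_f_Erysipelotrichaceae`), and
conserves each sample's total abundance exactly.

## Correlation networks

Genus–HA (and genus–genus) association uses the sample Pearson coefficient
with two-sided p-values from the $t$ distribution on $n-2$ degrees of
freedom, adjusted across the full pair set by Benjamini–Hochberg
(`stats::p.adjust`). Defaults follow the study: cutoff 0.05 on both the raw
and adjusted p-value; $|r| > 0.95$ sets a *robust* flag but is deliberately
not a filter, since correlations can be significant without clearing that
bar. Two choices the source analysis leaves open are exposed as
configuration:

* `nd_policy` — ND concentrations enter correlation as 0 (default:
  absence of a compound is biological signal) or are dropped pairwise;
* `sample_matching` — correlate at replicate level ($n = 18$ in the study
  design; default) or on day means ($n = 6$).

Zero-variance features yield no edges and a warning rather than an error,
and isolated nodes are retained in the network metadata so figures can show
unconnected genera.

## O2PLS

O2PLS decomposes paired matrices $X$ (samples × genera) and $Y$ (samples ×
HAs) into joint covarying parts, block-specific ("orthogonal") parts, and
residuals:

$$X = T W^\top + T_\perp P_{\perp,x}^\top + E, \qquad
  Y = U C^\top + U_\perp P_{\perp,y}^\top + F .$$

Preprocessing follows the published recipe: both blocks are mean-centered
by feature, the HA block is scaled to unit variance per feature, and each
block is scaled to a total sum of squares of 1 so that neither block's
scale dominates; a plain per-column z-score mode is available as an
alternative. Joint loadings are initialized from the leading singular
triplets of $X^\top Y$; each orthogonal component extracts the dominant
direction of the joint-score-predicted-but-loading-orthogonal part of its
block and deflates; joint parts are then recomputed on the deflated
blocks, and the inner relation $B$ regresses $U$ on $T$. The fitted model
satisfies $T^\top T_\perp = 0$, $U^\top U_\perp = 0$ and exact
sum-of-squares bookkeeping, which the tests verify on random fits; with no
orthogonal components the fit reduces to PLS-SVD and is checked against a
brute-force eigendecomposition oracle.

The component numbers are nowhere fixed by the source analysis; package
defaults are $n = 2$ joint and one orthogonal component per block, all
settable. The packaged demonstration scenario uses $n = 5$ joint
components because its planted cross-covariance (five independent
producer→HA channels) has joint rank 5; with $n = 2$ only the two leading
covariance directions are recovered and about a fifth of the planted
producers are missed.

### Permutation null

Influential variables are found by reshuffling the rows of $Y$ (breaking
the X–Y sample linkage while preserving each block's internal structure —
the minimal null consistent with a "reshuffled datasets" design),
refitting 1000 times, and pooling the permuted joint loadings per
component into an empirical null after aligning each permuted component's
sign to the observed loading vector (dot-product convention). Pooling
across variables is used rather than per-variable nulls because at
$\alpha/2 = 0.025$ a per-variable null from 1000 permutations would rest
on 25 order statistics. A variable is significant when its observed
loading falls outside the $\alpha/2$ and $1-\alpha/2$ pooled quantiles
(inclusive type-7 convention) in *any* joint component.

One consequence worth stating precisely: the per-component quantile test
is calibrated (under independent blocks the flagged fraction matches
$\alpha$ to Monte-Carlo error, which the acceptance suite measures with
$n = 1$), but the any-component union at $n$ components has per-variable
level close to $1 - (1-\alpha)^n$ — about 0.10 at $n = 2$,
$\alpha = 0.05$. Users wanting family-level $\alpha$ across components
should divide $\alpha$ by $n$.

## Core selection

A genus is called functional core when it passes all enabled gates:

1. membership in the permutation-significant pool (toggleable; the source
   analysis applies the printed criteria to that pool),
2. abundance in the top 20% — operationalized as mean relative abundance
   across all samples, with a ceiling cut so the stratum is never empty and
   lexicographic tie-breaking, and
3. at least one significant correlation (adjusted p when the association
   stage used FDR, raw p otherwise) with a *stable* HA. One stable partner
   suffices; requiring all partners stable is stricter than the stated
   criterion.

The report carries the full evidence trail per core genus: abundance rank,
significance, and every supporting edge with $r$, $p$, $q$. Enlarging any
gate (larger top fraction, higher p cutoff, lower detection threshold)
provably never shrinks the core, which the tests assert.

## The synthetic generator

Because the study's raw abundance tables are not published, the package
ships a generator (`sim_config()`, `simulate_dataset()`) that emulates the
study design and plants a recoverable ground truth:

* 6 sampling days (0–10, step 2) × 3 parallel replicates = 18 samples,
  labelled `D{day}R{rep}`; replicates share the day's expected value and
  differ only by noise;
* one dominant genus held at a configurable share of the community
  (default 0.5, emulating the observed *Lactococcus* dominance), a long
  tail of minor background genera (i.i.d. log-normal levels around a
  constant, median 0.8% with sdlog 0.5), and `n_producers` planted
  producers following smooth succession-like trajectories (logistic growth
  or Gaussian bump, chosen per taxon by seed) whose temporal means sit
  inside the top-20% abundance stratum — the stratum membership is part of
  the scenario definition, since criterion (2) above is meant to be
  satisfiable by true producers;
* driven HA concentrations linear in producer relative abundance
  (slope `effect_size` × 1000 µg/L per unit abundance), undriven HAs as
  pure noise around ~100 µg/L; all noise is multiplicative, mean-preserving
  log-normal (concentrations are positive and GC-MS error is roughly
  proportional), default relative SD 0.1;
* values below the detection limit (default 0.5 µg/L) recorded as ND at
  generation time — conversion to zero is a downstream decision;
* a peak-area table built by inverting the semiquantification relation, so
  quantification round-trips to the input concentrations within 1e-9.

What the generator does *not* emulate: sequencing count noise
(abundances are continuous proportions, not reads), taxon–taxon ecological
interactions, nonlinear or lagged production kinetics, and chromatographic
artifacts. Passing the end-to-end tests therefore demonstrates that the
pipeline recovers linear producer signal under compositional closure and
multiplicative noise — not that it would be unbiased on real amplicon
data.

One behavior of the real method that the synthetic benchmark does expose:
plain Pearson correlation on relative abundances suffers from
compositional closure, so a background genus whose share is suppressed
when producers bloom can correlate strongly (and "significantly") with the
driven alcohols. The demonstration scenario's residual false-positive rate
(~0.5 genera per run against 5 true producers) is exactly this artifact,
and is the reason compositionality-aware estimators exist; they are out of
scope here because the implemented method is the published one.

## Numerical choices and degenerate inputs

* SVD sign indeterminacy is fixed by forcing the largest-magnitude entry
  of each X-side loading positive (flipping its Y-side partner jointly),
  making fits reproducible bit-for-bit for a given seed.
* Quantile thresholds use R's default inclusive (type-7) convention.
* `top_fraction` uses a ceiling cut and lexicographic tie-breaks;
  `select_core` orders its output by descending mean abundance, then
  lexicographically.
* Readers reject malformed cells with row/column coordinates rather than
  coercing; `"ND"` is the only recognized non-numeric token; thousands
  separators (comma, thin space, no-break space) are stripped.
* Zero-variance columns are an error under variance scaling (the
  transform is undefined) but only a warning-plus-drop in correlation
  (the remaining pairs are still well-defined).
* All-ND compounds, all-zero samples, and timepoints with no replicates
  raise typed errors naming the offending unit.

## Problem sizes used in the packaged checks

The demonstration scenario runs 50 genera × 18 samples × 10 HAs with 1000
permutations, repeated over 20 seeds for the recovery summary; the
permutation-calibration study uses 20 independent-noise datasets of
18 × 40 and 18 × 10 with 200 permutations each; oracle comparisons use
6 × 8 / 6 × 5 random pairs. These sizes make every check a desk-scale
computation while keeping the Monte-Carlo error of the calibration
estimate (binomial SE ≈ 0.007 at 1000 variable decisions) well below the
effects being tested.

## Known limitations

* Pearson-on-compositions closure artifacts, as discussed above.
* The O2PLS permutation null reshuffles whole samples; it does not model
  temporal autocorrelation, so with strongly trending blocks the null is
  optimistic about independence.
* Semiquantification is single-point internal-standard only — no
  calibration curves, no response-factor correction; values are
  comparable within a compound over time, less so across compounds.
* The published genus-scale results (hundreds of genera, the five named
  core bacteria) depend on the study's sequencing data, which are not
  printed; the package reproduces the published concentration-table
  surface exactly and validates the genus-scale machinery on synthetic
  ground truth instead.
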