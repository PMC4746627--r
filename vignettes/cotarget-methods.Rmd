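---
title: "Methods: correlation-based prediction of functional TF targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-based prediction of functional TF targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotarget)
```

## The problem and the model

Transcription factors bind far more loci than they regulate. Given a
compendium of matched ChIP-seq and RNA-seq experiments across `t`
conditions (cell types, or time points), `cotarget` asks, gene by gene,
whether the binding profile co-varies with the expression profile. The
underlying assumption is that functional binding produces a detectable
covariation across conditions — in whichever form: proportional (linear),
saturating or otherwise monotone, or confined to the one condition where
the factor is active. A second assumption is that conditions are
exchangeable under the null: no systematic pairing between binding and
expression beyond the per-gene relation itself. Time-course compendia
violate independence between neighbouring samples, but exchangeability of
the *pairing* is what the permutation null requires, so the method applies
unchanged; outlier-style signals are simply rarer between similar samples.

## From peaks to a binding matrix

Peaks are assigned to genes under seven cumulative regulatory models:
windows of ±1, 5, 10 or 50 kb around the TSS; the nearest TSS; and the 1
or 5 kb TSS window extended by the gene body. Choices made where the rules
were genuinely open:

* "W kb around the TSS" is read symmetrically, giving the half-open
  window `[tss − W, tss + W + 1)`; overlap of a single base suffices, with
  no minimum-overlap fraction.
* The nearest-TSS model assigns each peak to exactly one gene by the
  distance from the peak midpoint `floor((start + end)/2)` to the TSS,
  without a distance cap; equidistant candidates resolve to the
  lexicographically smallest gene id so output is deterministic.
* The TSS of a minus-strand gene is the last base of its annotated span.
* Coordinates are 0-based half-open internally (the BED convention);
  GTF/GFF input is converted on read, and chromosome names match by exact
  string equality.

Binding is quantified either as the peak count per gene and condition or
as the sum of per-peak magnitudes (e.g. narrowPeak signalValue). In
magnitude mode an optional library-size-style scaling divides each
condition's magnitudes by their total and multiplies by the mean total
across conditions. Expression matrices are quantile normalized (the
conventional mean-of-sorted-values transform, with tied entries receiving
the mean of their tied reference values); note that with ties the
transform is exactly idempotent only on tie-free columns.

## The association measures

PC and SC are the absolute Pearson and Spearman correlations, with the
sign of the underlying coefficient retained. Both are undefined on a
constant profile; such genes are flagged invalid for PC/SC and excluded
from those methods' evaluation universes.

CARS targets relations that correlations dilute: a gene bound and
expressed (or bound and silenced) in one or few conditions only. Each
vector is scaled by its maximum — making the score invariant to positive
rescaling of either assay — and median-centered, so the typical condition
sits at the origin and a condition-specific event becomes a geometric
outlier. The per-point score is the product of

* the **ratio statistic** `r_i`, the point's distance from the origin
  divided by the mean distance of the other `t − 1` points (leave-one-out,
  so an extreme outlier does not inflate its own denominator; if that mean
  is zero the ratio is defined as 0), and
* an **angular penalty** `max(0, 1 − a/c)` decaying linearly from 1 on a
  diagonal to 0 at angular distance `c`, applied to the nearer branch of
  `y = x` for the positive score and of `y = −x` for the negative score.

The gene's CARS score is the maximum penalized score over points and
directions; its sign records which diagonal won (ties resolve `+` before
`−`, then the lowest condition index). Genes with a constant profile in
one dimension are *scored, not excluded*: their points lie at angular
distance π/4 from both diagonals and are suppressed by the penalty alone,
which keeps the permutation null honest. Note CARS is a ratio statistic
and is not bounded by 1.

### The penalty half-width `c`

`c` (radians, in `(0, π/4]`) controls how far from a perfect diagonal a
point may deviate and still count. The package default is 0.3; the
supported way to choose it is `calibrate_cars_c()`: binding profiles are
permuted `B + 1` times, the first replicate is scored against the pooled
null of the rest, p-values above 0.5 are rescaled to `(0, 1]`, and the
Kolmogorov–Smirnov statistic against the uniform distribution is
minimized over a candidate grid. Very small `c` collapses most scores to
zero, producing heavy p-value ties and a grossly non-uniform upper tail,
so the criterion genuinely discriminates. The calibration reuses one set
of seeded permutations across the whole grid, making the selection
deterministic given the seed.

### Empirical p-values

Permutation p-values shuffle the condition order of the binding vector
independently per gene, re-score, and pool null scores across genes
(pooling gives resolution `1/(B·G + 1)` rather than `1/(B + 1)`). The
add-one estimator `(1 + #{null ≥ observed}) / (1 + #null)` keeps p
strictly positive. Shuffling binding rather than expression is an
arbitrary but inconsequential choice under the null.

## Thresholds, target sets and evaluation

Evaluation happens on a per-method **universe**: genes with knockdown
differential-expression data intersected with genes the method can score.
The background fraction `f` is the proportion of that universe labelled
functional (positives are genes with knockdown DE p < 0.05 by default).
Two threshold rules:

* **fold-precision** (default fold 1.5): the lowest distinct score whose
  predicted set reaches precision ≥ `fold · f`. Among all qualifying
  cuts this picks the largest set, i.e. maximal recall at the requested
  precision.
* **top-fraction** (default 1 %), for factors without knockdown data:
  the `ceiling(q · N)` highest-scoring genes, with boundary ties all
  included.

The background is computed on each method's own universe by default; the
alternative reading — the DE fraction among genes *bound* in the knockdown
cell type — can be reproduced by evaluating the MB universe. Thresholds
learned on the universe are applied genome-wide, per-method sets are
unioned with per-gene provenance (methods, signs), and enrichment of any
set in the gold standard is the hypergeometric upper tail `P[X ≥ k]` on
the universe. No multiple-testing correction is applied across factors or
methods; the per-set p-values are reported as-is.

## The synthetic benchmark

`generate_compendium()` plants the three relation archetypes the measures
are designed for, each in both signs, plus null genes. Defaults — the
conditions used throughout the package's tests — are 15 conditions and
200 genes: 20 per planted class and 80 null. Binding is Poisson peak
counts (rates per gene and condition up to 8, mimicking promoter-window
counts); expression sits on an RPKM-like 0–8 scale with Gaussian noise of
sd 0.1 clamped at zero. Linear genes are affine in binding (slope ±0.8);
monotone genes follow a cubic transform, chosen convex enough that
Pearson visibly under-performs Spearman; on–off genes are near-silent
everywhere except one designated condition (default the first) where
binding jumps to ≈ 20 counts and expression is jointly elevated or
suppressed. The knockdown gold standard labels functional genes positive
with sensitivity 0.9 and null genes with probability 0.02, and its
knockdown condition is the on–off condition, which gives the
multiple-binding baseline its best case.

What the generator does **not** emulate: peak-calling noise, mappability
and GC artefacts, correlated conditions (replicate or lineage structure),
alternative TSSs, enhancer-mediated long-range regulation, and
compositional coupling between genes. Passing tests therefore demonstrate
that each statistic recovers the relation class it targets under clean,
exchangeable conditions — not that it will attain the same precision on
real compendia.

`generate_genomic_fixture()` writes a GTF plus per-condition BED files
whose windowed re-assignment reproduces a target count matrix exactly,
genes being spaced 500 kb apart so no peak can reach two windows; this
round-trips the whole file-format layer in the integration tests.

## Comparing measures across classes

Raw scores are comparable between PC and SC (both lie in `[0, 1]`) but
not with CARS, an unbounded ratio. Rank- or null-calibrated rescalings do
not help where they would be needed: on near-noiseless planted data PC
and SC both saturate (a linear relation *is* monotone), so any calibrated
scale ties them, while whole-set ranks are distorted by the other planted
classes. The package's benchmark therefore asserts class-specific design
in its well-posed forms: PC exceeds SC on linear genes and SC exceeds PC
on monotone genes (shared scale); on–off genes top CARS's own ranking and
stand higher there than in Pearson's ranking. Each clause holds on a
majority of seeds (empirically 10 of 10 at the default conditions).

## Numerical and implementation notes

* Angular distances satisfy `a⁺ + a⁻ = π/2` exactly (orthogonal
  diagonals); this is asserted to machine tolerance.
* All-zero vectors pass through max-scaling unchanged and score 0.
* The scoring of all genes is vectorized over a genes × conditions
  matrix; permutation nulls exploit the fact that max-scaling, centering
  and ranking commute with within-row permutation, so profiles are
  processed once and only re-indexed per replicate.
* Every stochastic step (simulation, gold-standard labelling,
  permutations, calibration) takes an explicit integer seed and restores
  the caller's RNG state, so the full simulate → map → normalize → score
  → predict → evaluate chain is byte-identical across runs with one seed;
  run provenance (config + package version, deliberately no timestamp) is
  written beside the outputs.
* Problem sizes in the test suite: oracle checks use 1,000 random
  vectors (correlations), exhaustive enumeration up to universes of 12
  genes (hypergeometric), and ≤ 50 genes × ≤ 200 peaks against an
  all-pairs scan (assignment); null-calibration checks use 500 pure-noise
  genes at `t = 12` with 500 permutations; recovery checks use the
  default 200-gene compendium over 10 seeds.

## Limitations

* One TSS per gene record; alternative promoters and enhancer loops are
  out of scope, though the gene-body models recover some proximal signal.
* The evaluation equates "functional target" with differential
  expression upon knockdown — a stringent and somewhat circular proxy
  that misses buffered or redundant regulation.
* With small `t` the permutation null is coarse (`t!` distinct orders);
  empirical p-values below `1/(B·G + 1)` are unattainable by
  construction.
* CARS scores are comparable within a dataset but not across datasets
  with different `t` or degeneracy structure; use empirical p-values for
  cross-dataset statements.
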