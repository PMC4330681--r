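---
title: "Methods: trait, phylogenetic and niche distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait, phylogenetic and niche distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichedist)
```

`nichedist` asks whether species' ecological niche positions, summarized
by indicator values, are better explained by their phylogenetic
relatedness, by the magnitude of their trait differences, or by the
signed direction of those differences.  This vignette records the models,
the parameter choices, and the numerical and design decisions behind each
stage, in the order the pipeline runs them.

## Distance definitions

For a single trait (or indicator) with species values $t_A, t_B$:

* absolute distance $|t_A - t_B|$ — a symmetric, non-negative matrix;
* hierarchical distance $t_A - t_B$ — an anti-symmetric matrix.

Indicators are used on their native printed scales (Ellenberg 0–9, the
phosphorus requirement 0–10) without normalization; each Mantel test
compares distances within a single variable, so scales never mix.  Cells
involving a species with a missing value are `NA`; deletion is
pairwise-complete at vectorization time, so each trait × indicator test
keeps the maximum usable pairs (a `listwise` option drops incomplete
species globally instead, for sensitivity analysis).

## Mantel tests on anti-symmetric matrices

The Mantel statistic is the Pearson correlation of the two matrices'
aligned pair vectors.  Symmetric pairs use the upper triangle.  For
anti-symmetric matrices the upper triangle is *not* label-invariant (the
sign of each entry depends on which species is the row), so signed
matrices are always vectorized over the full off-diagonal: every
unordered pair contributes $+x$ and $-x$, both vectors have exact zero
mean, and the statistic is invariant under joint species relabeling.
This is enforced, not optional.

The null distribution jointly permutes the rows and columns of one
matrix (equivalent in distribution to permuting the other).  The p-value
follows the add-one convention $p = (1 + \#\,\mathrm{extreme}) /
(n_\mathrm{perm} + 1)$ and can never be zero; ties count as extreme,
which is conservative.  Defaults: 999 permutations; one-sided
(*greater*) tails for absolute-distance tests, whose working hypothesis
is a more positive correlation than chance; two-sided tails for
hierarchical tests, where either sign is meaningful.  For $n \le 8$
species `mantel_exact()` enumerates all $n!$ relabelings and serves as
the reference for the Monte-Carlo test.  `NA` masking is re-applied
inside every permutation, and permutations whose masked pair vector is
degenerate (zero variance) are dropped and counted.  No multiplicity
correction is applied across the trait × indicator grid by default —
each cell is reported at raw $\alpha$ — with Holm adjustment available
via `p_adjust = "holm"`.

## Phylogeny

Sequence distances use pairwise deletion: for each pair, columns with a
gap or `N` in either sequence are dropped; the default model is the
uncorrected p-distance (fewest assumptions), with Kimura-2P selectable.
A pair with no comparable columns is an error naming the pair, and a K2P
logarithm of a non-positive argument is an error suggesting the
p-distance.

`neighbor_joining()` is the Saitou–Nei agglomeration with the
rate-corrected criterion $Q_{ij} = (m-2)d_{ij} - r_i - r_j$.  Ties in
the Q-minimum are broken at the lowest (row, column) index pair so runs
are deterministic.  Negative branch-length estimates are clamped to zero
and the clamped total is recorded on the tree (`attr(tree, "clamped")`);
for additive inputs no clamping occurs and the patristic distances of
the result reproduce the input to floating precision.  Bootstrap
supports resample alignment columns with replacement; the support of
each internal split of the point-estimate tree is the percentage of
replicate trees containing it, and replicates with an incomparable pair
are dropped and counted rather than silently imputed.

## Phylogenetic signal (eigenvector regression)

The patristic matrix is double-centered ($-\tfrac12 J D^2 J$) and
eigendecomposed.  Eigenvector columns are unit-norm with a canonical
sign (largest-magnitude loading positive), so the basis is reproducible
up to the inherent sign ambiguity.  Negative-eigenvalue axes are never
retained.  Axis selection uses the broken-stick rule by default: the
leading run of axes whose relative eigenvalue exceeds the expectation
$b_k = \frac1p \sum_{j=k}^{p} 1/j$, stopping at the first failure.  The
literal "exceeds expectation" criterion would retain trailing axes of a
perfectly flat spectrum, which no practitioner intends; the leading-run
form retains nothing in that case and matches common usage.  When
broken-stick retains no axis, the pipeline falls back to the single
leading axis and notes the fallback in the run log.  A `first_k` rule is
available.

Each trait is then regressed (with intercept) on the retained axes over
its non-`NA` species, and the overall regression F with
$(k,\; n-k-1)$ degrees of freedom is reported with its classical
F-distribution p-value.  The F statistic is invariant to affine
transformations of the trait; a constant trait is flagged rather than
tested, and a perfect fit reports $F = \infty$, $p = 0$.  Because the
axes are fixed by the tree and the null traits are i.i.d. normal, the
test is exactly calibrated for white-noise traits — which the test suite
verifies by simulation.

## Trait calculators

All calculators take bench units (cm², g, mm, m, cm³) and return the
conventional reporting units.  Decisions where sources conflict or are
silent:

* **Taproot tissue density** is dry mass / volume (g·cm⁻³): the printed
  units and value range are treated as the operational definition over a
  grammatically ambiguous prose formula that would invert it.
* **Nodule investment** is nodule dry mass per root length (g·m⁻¹),
  the definition consistent with both the reported units and the figure
  axis naming.
* **RLD** computes fine root length as mass × SRL; the prose
  "mass divided by SRL" is dimensionally impossible (g²·m⁻¹) and is read
  as a slip.
* **SRA** has no published formula; roots are treated as cylinders:
  $\mathrm{SRA} = \sum_c \pi\, d_c L_c / \mathrm{mass}$, which implies
  the identity $\mathrm{SRA} = \pi \cdot D \cdot \mathrm{SRL}/10$
  (dm²·g⁻¹) — reassuringly consistent with published mean values of
  $D$, SRL and SRA.
* **depth95** fits an ordinary least-squares line to the five points
  (segment lower boundary, cumulative fine root length including that
  segment), intercept free, and solves for the depth where the line
  reaches 95 % of the total.  An exactly uniform profile yields 95 cm
  analytically, and the statistic is invariant to rescaling all lengths.
  A flat cumulative profile (all roots in the first segment) has zero
  regression slope and is reported as degenerate rather than
  extrapolated.
* **CV** in trait summaries uses the sample (n−1) standard deviation.

## The synthetic-data generator

The generator emulates the study design — 13 species, 6 indicators, 25
traits — and provides ground truth for every stage:

* **Trees**: pure-birth (Yule) with rate 1 per unit time, ultrametric.
* **Traits**: Brownian motion (root 0, increment variance
  $\sigma^2 \times$ branch length; default $\sigma^2 = 1$) for
  phylogenetic signal present, or i.i.d. normal for signal absent.
* **Indicators**: $i = \beta t + \varepsilon$,
  $\varepsilon \sim N(0, \sigma_e^2)$.  `indicator_noise_for_r()`
  converts a target pair-difference correlation $r$ into
  $\sigma_e = \mathrm{sd}(t)\sqrt{1/r^2 - 1}$; the planted-effect checks
  use $r = 0.8$ at 13 species.  With zero noise the hierarchical Mantel
  correlation is exactly $\pm 1$.
* **Missingness**: i.i.d. Bernoulli per cell, refused if a column falls
  below 3 observed species.  The packaged indicator table carries its
  published missing cells verbatim (3, 4, 2 and 1 `NA` in the C, N, P
  and pH columns).
* **Measurement records**: `generate_measurement_records()` inverts the
  trait calculators exactly.  Free bench scales (sample masses) are
  drawn from realistic ranges; everything else is solved.  Two
  consequences of exact invertibility are worth noting.  First, several
  traits are mutually constrained (biomass identities; the SRA–D–SRL
  cylinder identity; a mycorrhization rate must be a fraction over 300
  intersects), so arbitrary 25-column tables are generally infeasible —
  `random_trait_targets()` draws tables that respect the constraints,
  and infeasible inputs are refused with the violated constraint named.
  Second, a 5-point cumulative root profile that is exactly linear
  cannot reach depth95 targets near the top of the published range, so
  profiles are built as a convex blend of a shallow ($u^{0.2}$) and a
  deep ($u^{3}$) shape; the OLS depth95 is then a Möbius function of the
  blend weight and is solved in closed form, covering roughly 80–108 cm.

What the generator does **not** emulate: within-species replication and
measurement error, integer rounding of Ellenberg scores (indicators stay
continuous so planted correlations are preserved; a real Ellenberg table
is ordinal), non-random missingness, correlated trait syndromes, and
non-Brownian evolution (no Ornstein–Uhlenbeck).  Passing tests therefore
demonstrate the correctness and calibration of the machinery, not that
real trait–niche relations behave like the generator.

## Problem sizes and reproducibility

A single master seed drives every stage; the pipeline derives one
sub-seed per Mantel cell from it, so grids are reproducible
cell-for-cell regardless of evaluation order, and two runs with the same
configuration are byte-identical on disk.  The verification battery uses
100 random matrix pairs for the Pearson oracle, 99 999 permutations
against the 120-relabeling exact reference at 5 species, 1000 null
datasets at 7 species for type-I calibration, 500 replicates at 13
species for planted-effect power and for the Brownian-vs-white signal
contrast, and 100 random trees of 5–20 taxa for neighbor-joining
recovery — sizes at which each check is decisive for its question while
the whole battery runs in about a minute.

## Known limitations

* Single-variable distances only: no multi-trait (Gower-type)
  combinations or partial Mantel tests.
* NJ and the distance models are intentionally minimal; likelihood or
  Bayesian phylogenetics is out of scope — supply your own tree where
  that matters.
* The eigenvector-regression signal test inherits the usual PVR caveat
  that results depend on the axis-selection rule; both knobs are
  exposed.
* Mantel tests are known to have modest power against some structured
  alternatives; the package reports raw per-cell p-values by design,
  with Holm adjustment optional.
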