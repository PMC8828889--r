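---
title: "Methods: index-based screening for stress tolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: index-based screening for stress tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csiscreen)
```

## The selection problem

A biparental population of recombinant inbred lines (RILs) is grown for
several years under paired water regimes: non-stress (conventional
irrigation) and terminal drought stress (irrigation withheld before
flowering). Because RILs are near-homozygous, any line can be multiplied
and re-tested, and — when the parents carry complementary favourable
alleles — some lines transgress both parents. The breeder's question is
which lines combine high yield potential (YP, non-stress) with high yield
under stress (YS), across years.

No single index answers this. Productivity-type indices (MP, GMP, HM,
STI) reward joint performance; susceptibility-type indices (SSI, TOL)
separate tolerant from susceptible material but cannot distinguish a
tolerant line from a uniformly low-yielding one. `csiscreen` therefore
(i) computes all nine classical indices, (ii) lets the data say which of
them actually track yield in the trial at hand, and (iii) folds the
informative ones into a single composite score.

## Indices and their algebra

All nine indices are scalar functions of (YP, YS, ȲP, ȲS). Three exact
identities tie them together, and the test suite asserts them on random
inputs:

* HM ≤ GMP ≤ MP with MP·HM = GMP² (the classical mean inequality —
  equality only when YP = YS);
* SSI·(1 − ȲS/ȲP) + YSI = 1 and RSI·(ȲS/ȲP) = YSI (the three ratio
  indices are affine transforms of one another);
* STI·ȲP² = YP·YS and YI·ȲS = YS; hence the mean of YI over the entry
  set defining ȲS is exactly 1.

Because the ratio indices are undefined at YP = 0 they are reported as
missing for such genotypes (with a warning) rather than failing the whole
table; SSI is undefined globally when ȲS = ȲP, which is an error naming
the degenerate denominator.

**Population means.** ȲP and ȲS are arithmetic means over *all* entries —
lines, parents and checks — since all of them appear in the trial and the
headline "total mean" convention includes the checks. An `entry_types`
argument restricts the set (e.g. lines only) for users who prefer the
RIL-only convention; the two differ little when checks are few.

**Scopes.** Indices are computed per year and on yields pooled over
years; pooling is the arithmetic mean of per-year genotype means so that
years weigh equally. Within a year a genotype missing one condition is
dropped from that year's table with a warning; in the pooled scope it is
kept as long as each condition was observed in at least one year (the
pooled value then averages the available years).

## The composite selection index

For each index *j*, Pearson correlations r(YP, index_j) and
r(YS, index_j) are computed over genotypes, with two-sided p-values from
t = r√(n−2)/√(1−r²) on n−2 degrees of freedom. Two-sided is the standard
reading when a significance threshold is quoted without sidedness; a
one-sided gate would only ever admit more indices of the expected sign.
An index significant under **both** regimes at level α (default 0.05) is
a *significant index*; the composite score of genotype *i* over the
selected set is

CSI_i = ½ ( Σ_j r_YP,j · index_ij + Σ_j r_YS,j · index_ij ).

Design choices worth stating:

* **Signs are retained.** The formula implies that an index negatively
  correlated with yield in both regimes would enter with negative weight;
  the gate is on significance, not sign. In practice the selected indices
  are positively correlated; a `require_positive` flag restricts to that
  case explicitly (default off).
* **Per-scope weights.** CSI for a year uses that year's correlations;
  pooled CSI uses pooled correlations. Weights are not transferred across
  scopes, because which indices are informative genuinely changes with
  stress severity (in a severe year TOL and MP can track YP only).
* **No multiple-testing correction** across the nine indices: the gate is
  a descriptive screen, the indices are strongly mutually correlated, and
  correcting would only shrink an already-conservative both-regimes
  intersection.
* **Checks are included** in the correlation computation by default (they
  are ordinary entries of the table), excludable via `entry_types`.
* CSI has units of the index mixture and is meaningful only for ranking
  within a scope; rankings break exact ties lexicographically by genotype
  id so output is deterministic.

## Biplot engine

All views are rank-2 truncations of the SVD of the column-centered (and
optionally column-standardized) two-way table X = UDV′.

* **Preprocessing.** Genotype-by-trait (GT) tables mix units (t/ha,
  ratios, squared ratios), so they are standardized per column by
  default; genotype-by-environment (GGE) tables are in one unit and are
  centered only (sd-scaling available as an option).
* **Partitioning.** Tester-focused (column-metric preserving) assigns the
  singular values to the tester coordinates (VD; genotypes get U): tester
  vector lengths are then proportional to column sds and cosines of
  tester angles approximate inter-column correlations, which is the right
  metric for comparing indices and for the ideal-index view. Symmetric
  partitioning splits the singular values (UD^½, VD^½) and is used for
  the which-won-where polygon. The product of row and column coordinate
  matrices — and hence every inner-product-based reading — is identical
  across partitionings; tests assert this invariance and full-rank
  reconstruction of the processed matrix to 1e-9.
* **Sign convention.** The SVD sign ambiguity is fixed by making the
  largest-magnitude tester loading on each axis positive.
* **Which-won-where.** The convex hull of genotype points is taken
  counter-clockwise; the perpendicular from the origin to each hull edge
  is a sector boundary, and the winner of a sector is its hull vertex.
  This construction is equivalent to assigning each tester to the
  genotype maximizing the inner product with the tester vector, and the
  implementation is tested against that brute-force rule on hundreds of
  random configurations. Boundaries are half-open: a tester exactly on a
  boundary joins the counter-clockwise sector. Collinear genotype
  configurations are rejected (degenerate polygon).
* **Ideal tester.** The mean of the tester vectors, normalized to the
  length of the longest tester vector: maximally representative at
  maximal discrimination. Testers are ranked by ascending distance to it.
* Coordinates, sector maps and rankings are exported as data; `plot()`
  methods render them with base graphics but figure appearance is not
  part of any tested contract (published biplots from dedicated software
  can differ by rotation, reflection or overall scale).

## The synthetic trial generator

`sim_spec()` / `simulate_ril_trial()` emulate the statistical structure
of a three-year RIL drought trial; they make no attempt to emulate field
layout (augmented block design, spatial trend) — plot error is a single
Gaussian term on the (genotype, year, condition) mean.

The model: each line inherits each of 20 independent loci from either
parent with probability ½ (fully homozygous, no linkage map — sufficient
for transgressive-segregation structure; QTL mapping is out of scope).
Non-stress genetic value g^P is the sum of inherited effects; the stress
genetic value is g^S = μ_g + ρ_g(g^P − μ_g) + √(1−ρ_g²)·h with h matched
to the genetic sd, so the regimes share mean and variance and correlate
at ρ_g. Yields are

* non-stress: μ_P + τ_y + g^P + G×E + e,
* stress: (1 − δ_y)(μ_P + τ_y + g^S) + G×E + e,

truncated at zero (with a reported count — under a severe δ ≈ 0.9 season
negative draws do occur). The stress factor multiplies the genetic + year
component, not the noise, so δ_y is recoverable from population mean
reductions — the property the parameter-recovery tests exercise.

Default values and their rationale:

| parameter | default | why |
|---|---|---|
| n_lines / checks | 152 + 5 (2 parents, 3 checks) | the trial size being emulated |
| δ per year | 0.89, 0.58, 0.35 | severe / moderate / mild drought seasons |
| μ_P, τ_y | 4.0; 0.79, −0.20, −0.55 t/ha | non-stress season means ≈ 4.8/3.8/3.5, pooled means ≈ 4.0 (non-stress) and ≈ 1.4 (stress) t/ha |
| allele effect, split | ±0.15 t/ha, 12/8 | parents diverge by 1.2 t/ha, genetic sd ≈ 0.67 t/ha, transgression in both directions |
| ρ_g | 0.7 | stress and potential yield share most but not all genetics |
| sd(G×E), sd(e) | 0.2, 0.3 t/ha | ≈ 10% CV on non-stress plot means |

What passing tests on simulated data do **not** show: robustness to
non-Gaussian error, spatial autocorrelation, epistasis or linkage,
genotype-specific stress response curves, or missing-data patterns of
real trials. The generator exists to give every downstream operation a
known truth, not to certify field performance.

### Numerical conventions

* Simulated yields are emitted at fixed 1e-10 precision so that a line
  reconstituting a parental genotype ties the parent's yield exactly;
  combined with strict-inequality detection and a 1e-9 tolerance on the
  ground-truth flags, "detected segregants = true transgressives" is an
  exact identity in the zero-noise limit, for any seed.
* Transgression is strict: a line equal to the better parent is not a
  positive segregant.
* All randomness flows through a single integer seed in the spec;
  identical spec + seed gives a byte-identical table.

## Problem sizes in the test suite

The suite validates identities on 1,000 random yield pairs, the
which-won-where/inner-product equivalence on 200 random configurations,
p-values against a numerically integrated t density for n ≤ 30, and
parameter recovery on the full default population (157 entries × 6
environments) over 20 seeds — sizes at which every property is stable
while the whole suite runs in seconds.

## Known limitations

* CSI is a within-trial ranking device; its scale is not comparable
  across trials and no standard error accompanies it.
* The significance gate inherits the usual fragility of p-value
  thresholds near α; with few genotypes the selected index set can change
  between years (this is visible, by design, in the per-scope reports).
* The biplot views are rank-2 summaries; when PC1+PC2 explain a small
  share of the variation the which-won-where reading is unreliable, so
  the explained-variance shares are always part of the output.
* Detection of transgressive segregants compares observed means, not
  genetic values; with noisy data it under-detects when intersecting
  across all environments (the conservative direction).
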