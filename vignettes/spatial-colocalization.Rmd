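---
title: "Methods: spatial co-localization of cell types on spot lattices and in images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial co-localization of cell types on spot lattices and in images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialcoloc)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the parameters that matter, and the design
choices made where the underlying method left the design open. It states no
empirical result that the test suite does not itself compute.

## 1. The problem

Spot-resolved transcriptomics assigns each capture spot on a tissue section
a vector of UMI counts. A biological question of the form "do endothelial
cells and exhausted CD8+ T cells occupy the same neighborhoods?" becomes,
after per-spot cell-type scoring, a question about the spatial arrangement
of two binary labels on a lattice. This package implements that chain —
score, threshold, label, count joins, calibrate a null — plus the
image-domain analogue: Manders' colocalization coefficients for two-channel
immunofluorescence.

## 2. Spot scoring: single-sample enrichment

`ssgsea_score()` ranks the spot's genes by descending expression (ties
broken by the stable input order, for determinism) and walks the ranking
accumulating two empirical CDFs: the in-set CDF, whose step at an in-set
gene at position $i$ of $N$ is $w_i^{\alpha} / \sum_{j \in S} w_j^{\alpha}$
with rank weight $w_i = N - i + 1$, and the out-of-set CDF with uniform
steps $1/(N - |S|)$. The score is
$\sum_{i=1}^{N} \left[ P_{\text{in}}(i) - P_{\text{out}}(i) \right]$:
positive when the set concentrates at the top of the ranking. At
$\alpha = 0$ this reduces to the unweighted Kolmogorov-style running sum.

Two properties carry the testing weight:

* **Rank invariance.** The score depends on expression only through ranks,
  so any strictly monotone transform of the spot's profile leaves it
  unchanged. This also means within-sample thresholding (below) is immune
  to per-spot monotone normalization choices.
* **Oracle equivalence.** A brute-force loop implementation in the test
  helpers recomputes the running sum independently; the vectorized
  implementation must agree to 1e-12 on randomized instances of up to 10
  genes, including ties.

**Parameters.** `alpha` defaults to 0.25, a conventional mild weighting; no
cross-sample normalization of scores is applied. The scores are consumed
only within one sample by a quantile rule, which is invariant to any common
monotone rescaling, so the normalization question (which the underlying
method leaves open) is moot for the downstream statistic; the option
surface still exposes `alpha` rather than hard-coding it.

## 3. Positivity: the strict top-quartile rule

`call_positivity()` computes, per cell type, the nearest-rank quantile of
the scores across all spots of the sample (default `quantile = 0.75`, i.e.
the value at position $\lceil 0.75\,n \rceil$ of the sorted scores) and
calls a spot positive when its score is **strictly greater** than that
threshold. Consequences, all tested:

* with all-distinct scores and $n$ divisible by 4, exactly $n/4$ spots are
  positive per type;
* a constant score column yields zero positives (the strict reading);
* ties at the boundary reduce, never increase, the positive count;
* a spot can be positive for several types at once — the co-positivity the
  parity rule exists to resolve.

The phrase "greater than the top 25%" admits a second reading ("greater
than the 25th percentile"); the top-quartile reading is adopted because the
rule defines *positive expression* of a focal cell type, which a
75%-of-spots call would not. Thresholds are computed per sample and never
pooled: pooling would let one sample's score scale move another sample's
calls.

## 4. Parity assignment

For a pair (A, B), spots positive for only one member keep that label,
spots positive for neither are background (BG), and co-positive spots are
assigned by the parity of $x + y$: even sites get A (by default), odd
sites B. This is a deterministic checkerboard; the `even_gets` option
(seedable at the pipeline level) chooses which type takes even parity, and
swapping it together with the pair order leaves $|z|$ unchanged (tested).
Since shifting either coordinate by one flips every site's parity, the
0-based origin is part of the contract: `read_coords()` normalizes
coordinates by subtracting the per-axis minimum and records the offset in
the grid and the run report.

## 5. Join counts and their nulls

On the adjacency graph (rook 4-neighborhood by default; queen 8-neighborhood
by flag) the statistic is the number of edges joining an A spot to a B spot.
Same-label joins measure self-aggregation and are not part of the reported
quantity; BG-touching edges never count, but BG spots stay in the lattice
and participate in permutation — the sites exist regardless of positivity,
and removing them would change the null in an uncontrolled way. (A
positive-only permutation variant is deliberately not offered until a use
case defines its meaning.)

**Permutation null** (`permutation_null()`): the label multiset is permuted
uniformly over all spots; mean, SD and a two-sided add-one p-value
$(1 + \#\{|J^{*} - \bar{J}| \ge |J_{\text{obs}} - \bar{J}|\})/(n_{\text{perm}} + 1)$
are returned. The add-one estimator avoids zero p-values at finite
$n_{\text{perm}}$ and makes the test slightly conservative.

**Analytic null** (`analytic_null()`): under sampling without replacement
of $n_A$ A's and $n_B$ B's among $n$ spots with $m$ edges,

$$E[J] = \frac{2 m\, n_A n_B}{n(n-1)}.$$

For the variance, $E[J^2]$ sums $P(\text{both edges are A–B})$ over ordered
edge pairs in three classes: identical edges ($m$ terms, probability
$2 n_A n_B / n(n-1)$), pairs sharing one vertex
($2\sum_v \binom{d_v}{2}$ terms, probability
$n_A n_B (n_A + n_B - 2) / n(n-1)(n-2)$ — the shared vertex carries one
color, the two others the opposite color), and disjoint pairs (probability
$4 n_A(n_A-1) n_B(n_B-1) / n(n-1)(n-2)(n-3)$). The derivation is trusted
only through its verification: the test suite enumerates **all**
distinguishable labelings on every grid with at most 9 spots and requires
the analytic mean and SD to match exact enumeration to 1e-10, and the
permutation mean to land within 3 Monte-Carlo SE at $n_{\text{perm}} = 10{,}000$.

**z-score and significance.** $z = (J_{\text{obs}} - E[J])/\text{sd}[J]$;
$z > 0$ is spatial aggregation of the pair, $z < 0$ dispersion, and
significance is $|z| \ge 3$ (two-sided, honoring the "+3" convention in the
positive direction). No multiple-testing correction is applied across pairs
because the source convention applies none; with $\binom{k}{2}$ pairs a
user should interpret borderline $|z|$ accordingly. When the null is
degenerate — a type absent, or every permutation yielding the same count
(e.g. a 1x2 grid with one A and one B) — the result object is flagged
not-computable with the reason attached; it is never reported as $z = 0$.

**Calibration.** Under random labeling on a 20x20 rook grid with
$n_A = n_B = 100$ and 200 background spots, the permutation test at
$\alpha = 0.05$ rejects in 5% $\pm$ 2% of 500 seeded simulations (tested
with $n_{\text{perm}} = 199$, where the add-one p-value has granularity
exactly 1/200 and $\alpha = 0.05$ is attainable; the discreteness of the
join count makes the test mildly conservative, which the band absorbs).

## 6. Manders' colocalization coefficients

`manders()` computes intensity-weighted overlap fractions: with masks
$M_A, M_B$,

$$M_1 = \frac{\sum_{i \in M_A \cap M_B} A_i}{\sum_{i \in M_A} A_i}, \qquad
  M_2 = \frac{\sum_{i \in M_A \cap M_B} B_i}{\sum_{i \in M_B} B_i}.$$

Sums are of intensities, not pixel counts — the literal reading of the
$\sum_i \text{CD8}_i$ notation — so multiplying one channel by a positive
constant changes neither coefficient (tested), and swapping the channel
roles exchanges $M_1$ and $M_2$ exactly (tested). A zero denominator
produces a flagged not-computable coefficient, never $0/0 \to 0$.
`coefficient_to_percent()` renders $100\,m$ at one decimal (0.074 → 7.4),
matching how such coefficients are quoted in prose.
`mcc_timecourse()` summarizes grouped images (n, mean, SD per group, SD
not-computable at $n = 1$) and deliberately performs no hypothesis testing.

**Thresholding.** The original image analysis applies an unnamed automatic
threshold; this package defaults to Otsu's method per channel (256-bin
histogram, between-class variance maximized over bin edges, degenerate
constant images rejected) with a fixed-threshold alternative, because Otsu
is deterministic and parameter-free. No background subtraction and no
Costes randomization are performed — neither is described for the original
analysis, and inventing preprocessing would change the statistic.

## 7. The synthetic-data generator: what it emulates, what it does not

The generator exists so that every downstream stage has ground truth.
Its defaults are fixed once, not tuned to tests.

* **Lattices** are full rectangular grids, 0-based, square geometry only;
  hexagonal capture geometries are out of scope (square keeps the
  exact-enumeration oracles tractable).
* **Abundance fields**: `aggregated` superimposes isotropic Gaussian blobs
  (default 3 blobs, $\sigma = 2$ lattice units — the width at which a 20x20
  grid holds distinct blobs of ~50-100 spots) on a 1% uniform baseline;
  an aggregated *pair* shares the same blob centers, so the two types
  co-localize. `dispersed` places the two types on disjoint column halves
  with uniform(0.5, 1) abundance inside — disjoint support makes the
  expected z-sign unambiguous rather than merely probable. `random` is
  i.i.d. uniform, the calibration null.
* **Expression**: marker genes draw negative-binomial counts with mean
  $\mu = \text{baseline} \times (1 + \text{effect} \times a)$, abundance
  $a$ rescaled to $[0,1]$, and variance $\mu + \mu^2/\phi$. Defaults
  baseline 2, effect 5, dispersion $\phi = 2$: a typical over-dispersed
  UMI regime where a fully positive spot's markers sit at 6x baseline —
  strong but not separable without aggregation over the marker set.
  Library-size variation, doublets and deconvolution mixtures are
  deliberately not simulated; a green recovery test shows the scoring
  chain detects additive abundance signal, not that it survives
  platform-specific artifacts.
* **Image pairs**: three disjoint pixel regions (overlap, A-only, B-only)
  on a zero background, with region sizes scaled so each channel's
  per-pixel level is near-constant across its support and the overlap
  region carries exactly the requested intensity fraction. At zero noise,
  recovery through `manders()` with the support masks is exact by
  construction; with 5% relative Gaussian noise and Otsu masks, mean
  absolute recovery error stays well under 0.05 (tested). Because the
  ideal mask of a channel is its support, a shared pixel has positive
  intensity in both channels; requesting `frac_a_in_b > 0` together with
  `frac_b_in_a = 0` is geometrically infeasible and rejected. The
  constant-level construction is what real micrographs are not: no
  gradients, no point-spread blur, no autofluorescence — the recovery
  test validates the estimator, not image restoration.

Every generator requires an explicit seed and restores the caller's RNG
state; identical seeds give bit-identical output (tested).

## 8. Numerical and degenerate-input policy

* Nearest-rank quantiles, never interpolated: interpolation would make the
  threshold depend on a convention rather than on an observed score.
* Stable tie-breaking everywhere a ranking occurs (input gene order).
* Degenerate conditions are first-class results or typed errors, never
  silent defaults: empty gene-set intersection, sets covering all measured
  genes, constant images under Otsu, zero-intensity channels, degenerate
  permutation nulls.
* p-values use the add-one estimator; z-scores are never computed with a
  zero SD.
* Coordinates are validated as integers; duplicate ids or coordinates are
  rejected at read time, and origin normalization is recorded because
  parity depends on it.

## 9. Open choices resolved here

* **Config format** is JSON rather than YAML (one fewer parser; identical
  structure), with unknown keys rejected so typos fail instead of silently
  using defaults.
* **Channel images** travel as plain-text PGM (P2, 16-bit maxval) or CSV
  matrices. The analysis is agnostic to the container; a text format keeps
  the package free of binary I/O dependencies and every fixture
  human-readable.
* **Adjacency default rook**: the minimal contiguity scheme, hence the
  most conservative join count; queen is one flag away and shares all
  oracles.
* **One- vs two-sided z**: the source quotes a "+3" cutoff for calling
  aggregation; this package tests $|z| \ge 3$ two-sided so dispersion is
  reportable at the same evidentiary bar, and records the convention in
  the result object.

## 10. Known limitations

Partial lattices are supported in adjacency construction but the analytic
variance assumes only the given edge set (it is exact for any graph, as the
enumeration tests show — the limitation is interpretive: on a ragged tissue
boundary, rook adjacency under-connects edge spots). Scores are not
comparable across samples by design. The permutation engine is quadratic in
nothing worse than edges x permutations but is pure R; very large lattices
(>100k spots) would want a compiled path. The image stage assumes aligned,
equally-sized channels and performs no registration.
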