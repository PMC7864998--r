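---
title: "Quantifying ground-truth ambiguity with T-REX: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ground-truth ambiguity with T-REX: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trex)
```

## The problem

Expert annotators disagree about pixel-wise labels on medical images, and a
segmentation model trained on several annotators' labels learns from that
disagreement. T-REX makes the resulting behavior inspectable by treating
the model as one more grader: all pairwise distances among graders and
model are computed per scan, summarized, embedded, and tested. The package
is built around four-compartment retinal OCT B-scans — vitreous, retina,
choroid, and sclera, separated top-to-bottom by the ILM, CCi, and CSI
boundary lines — but nothing in the machinery is specific to OCT beyond the
four-code label alphabet.

## Label maps and boundary geometry

A label map is an integer matrix of codes 0–3 with row 0 at the image top.
When gradings arrive as three boundary lines per column,
`lines_to_labelmap()` rasterizes them with half-open intervals: a pixel at
row $r$ in column $c$ is vitreous iff $r < \mathrm{ilm}[c]$, retina iff
$\mathrm{ilm}[c] \le r < \mathrm{cci}[c]$, and so on. The boundary row thus
belongs to the compartment *below* the line. Either convention is
defensible — an annotation tool's drawn line is one pixel wide and some
compartment must absorb it — but the choice must be fixed and shared by all
gradings, otherwise every boundary contributes a spurious one-pixel band to
every distance. Boundaries may touch (a zero-height compartment);
ensemble construction warns when a map lacks a compartment entirely, since
the analysis is designed for scans displaying all four.

Validation is strict and early: crossing boundaries name the first
offending column, PNG files with codes outside 0–3 name the offending
values, and incomplete scan-by-grading designs name the missing cell.
Paletted PNGs are decoded by palette *index*, not by displayed color, so
recolored exports remain readable.

## The Hamming distance and its scopes

For same-shape maps the overall distance is the fraction of pixels labeled
differently — one minus pixel accuracy — and a genuine metric, which is what
justifies embedding it with metric MDS. Per-compartment distances compare
binary membership maps but keep the full-image denominator $HW$. This is a
deliberate property, not a bug: it makes per-compartment values
commensurable (they sum to exactly twice the overall distance, since a
differing pixel flips two membership maps) at the cost of *not* normalizing
by compartment size, so a thin choroid yields smaller per-compartment
distances than a thick one for the same boundary error. The test suite
checks the metric axioms, the factor-two identity, and invariance under a
shared pixel permutation on randomized maps.

For zero-noise flat-boundary gradings with per-boundary offsets whose
shifted bands do not overlap, the overall distance has the closed form
$\sum_i |\Delta\text{offset}_i| / H$; this analytic law ties the metric
code to the synthetic generator in the tests.

## Metric MDS

`mds_embed()` initializes with Torgerson classical scaling
(`stats::cmdscale`) and refines with SMACOF-style stress majorization
(Guttman transform, unit weights), a deterministic scheme that never
increases stress — avoiding random restarts and their irreproducibility.
Iteration stops when the relative stress change falls below $10^{-9}$ or at
300 iterations. The reported diagnostic is Kruskal raw stress
$\sqrt{\sum_{i<j}(d_{ij}-\delta_{ij})^2 / \sum_{i<j} d_{ij}^2}$. For
distance matrices realizable in the plane the classical start is already
essentially exact (final stress $< 10^{-6}$); for generic 4-point matrices
stress is positive and the contract is stress minimization, not exact
recovery. An embedding is defined only up to rigid motions, so coordinates
are canonicalized — centroid at the origin, first grading on the
non-negative x-axis, second grading with non-negative y — making outputs
comparable across runs and platforms.

## The permutation test

All inter-grader distances at one scope are pooled into group A, all
grader-model distances into group B (with 3 graders and 200 scans, 600
values each). Distance distributions are skewed, so instead of a t-test the
package uses an unpaired Monte-Carlo permutation test on the difference of
group means: pooled values are re-split at random into the original group
sizes; one-sided p-values use the add-one estimator
$(\#\{T^* \ge T_{\mathrm{obs}}\}+1)/(B+1)$ (ties count as exceedances,
with a tiny relative tolerance so floating-point noise cannot un-tie exact
ties), and the two-sided value is $\min(1,\,2\min(p_\ell, p_u))$. Under
this convention the smallest attainable two-sided p with $B = 99{,}999$
resamples is exactly $2\times10^{-5}$ — the value reported when not a
single resample reaches the observed separation. The 99% confidence
interval for p is a Clopper–Pearson interval on the smaller tail's
exceedance proportion, doubled and clipped to $[0,1]$; this is a
convention choice (interval recipes differ across implementations) and is
asserted only to contain the p-value and the attainable floor.
`exhaustive_permutation_test()` enumerates all $\binom{n_A+n_B}{n_A}$
splits (without the add-one correction, since enumeration is exact) and
serves as the oracle: Monte-Carlo p-values must agree within binomial
error, and the type-I error at $\alpha = 0.05$ is calibrated on 2,000
simulated exchangeable datasets. The test permutes individual distances,
ignoring their within-scan dependence, and no multiple-testing correction
is applied across the five scopes — both deliberate mirrors of the
procedure the package implements. Quartiles and boxplot whiskers follow
the strict-inequality 1.5·IQR rule (whiskers extend to the last datum
strictly inside each fence; for degenerate data with no such datum the
whisker falls back to the quartile, so constant data produce no outliers).

## The synthetic study

The generator is first-class code, not a fixture: it defines the
conditions under which the pipeline's claims are exercised. A scene is a
four-layer geometry with boundary centerlines displaced by a smooth
sinusoid of random phase per scan (all three boundaries undulate together,
as retinal layers do). A simulated grader adds a systematic per-boundary
row bias plus smooth noise — white Gaussian column noise, moving-average
filtered over a correlation length and rescaled to the target standard
deviation — then rounds to integer rows (annotation lines are
pixel-accurate), clips, and restores ordering. The model is a weighted
consensus of the graders' boundaries. One top-level seed drives everything
through stable per-scan/per-grader sub-seeding, so adding a grader never
perturbs existing gradings.

Defaults define the package's reference study: a 512 × 512 grid, 200
scans, centerlines at rows 120/280/360, undulation amplitude 15 rows over
2 periods; graders `g1`/`g2`/`g3` with CSI biases +6/−1.5/−6 rows and
small opposing CCi biases, noise s.d. 1.5 rows with correlation length 32
columns; model weights (0.35, 0.5, 0.15). These were chosen once so that
the ensemble reproduces what a multi-grader OCT panel looks like in
practice: mean inter-grader overall Hamming distance near 2%, disagreement
concentrated at the choroid–sclera interface, vitreous and retina scopes
well under 1%, a most-similar and a most-different grader pair, and a
model that is closer to every grader than the graders are to each other.
What the simulator does *not* emulate: OCT speckle or intensity texture,
pathology, scan-to-scan anatomical variation beyond the undulation phase,
or grader behavior richer than bias-plus-smooth-noise. Passing tests
therefore demonstrate the correctness and sensitivity of the measurement
pipeline — planted bias structure is recovered in the distance ranking, the
MDS layout, and the permutation floor — not that any particular clinical
dataset behaves this way.

Training-set augmentation mirrors each item about the vertical axis
(column reversal — the interpretation of "vertical mirroring" that maps
plausible retinal anatomy to plausible anatomy) and adds one copy rotated
by a uniform angle in ±8°, tripling the set (675 → 2025). Label maps
rotate with nearest-neighbour sampling and edge-clamp fill, because no
background class exists to fill corners and the four-code alphabet must
be preserved; intensity images use bilinear sampling.

## Reporting

`trex()` returns everything computed from one distance table; reports
write each figure next to a value-identical CSV or JSON twin — figures are
decoration, the text files are the contract, and reruns with identical
inputs and seed are byte-identical. Heatmap-table percentages are rounded
to two decimals only at rendering; distances are stored as fractions
throughout. The neural-recording heatmap orders scans as given (grouped by
eye when a scan-to-eye mapping is supplied), draws inter-grader rows above
grader-model rows with a separating rule, and fixes its color scale at the
99th percentile of plotted values so outliers cannot wash out the scale.

## Problem sizes and numerical choices

The test suite exercises the full pipeline on scenes from 48 × 48 × 3
scans up to 512 × 512, with 99,999-resample permutation runs reserved for
the dedicated floor check and 199–999 resamples elsewhere; the
parameter-recovery scenes use 128 × 128 grids with 6–8 scans, which is
ample to detect ±4-row planted biases. Degenerate inputs are defined, not
rejected: identical gradings yield all-zero distances, a permutation p of
1 (every resample ties), and an MDS embedding collapsed at the origin with
zero stress; two-grader ensembles without a model skip the permutation
stage with an explicit notice.

## Known limitations

Per-compartment distances are not normalized by compartment size (see
above). The permutation test treats the 3N pooled distances as
exchangeable units although distances within one scan are correlated; p
at the floor is robust to this, borderline p-values should be read with
care. MDS stress has no reference value for real grader panels, so
embeddings are judged qualitatively. Label maps are analysed at their
stored size; no resampling between annotation and analysis grids is
performed, because label interpolation is representation-dependent and
best done by the producer of the maps.
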