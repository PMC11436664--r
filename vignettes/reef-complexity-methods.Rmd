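---
title: "Quantifying the structural complexity of artificial reef designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the structural complexity of artificial reef designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefcomplexity)
```

## The problem

Artificial reefs are deployed for habitat protection, biomass production
and biodiversity enhancement, and ecological theory consistently links
the diversity and abundance of the communities they attract to the
structural complexity of the habitat. Yet reef modules are usually
designed empirically and judged by eye. Because modern modules exist as
3D CAD models (STL) before they are cast or printed, their structure can
be quantified *before immersion*. This package implements such a
pre-immersion assessment: six complexity metrics computed from the
triangulated surface, a summary Complexity Index, and a statistical
pipeline that turns a collection of candidate designs into quantitative
design targets.

## The six metrics

Let the model be a triangle mesh with surface area $A$, enclosed volume
$V$, and convex hull (the smallest convex solid containing it) with area
$A_h$ and volume $V_h$.

**Geometric complexity** describes the global shape:

* **Convexity** $C = (V_h - V) / V_h$ — the fraction of the hull volume
  accessible to mobile organisms. A filled convex solid scores 0; an
  empty frame approaches 1.
* **Packing** $P = A_h / A$ — how folded the surface is relative to the
  minimal convex envelope. A cube scores 1; heavily folded surfaces
  score far below 1. Open shells, whose two sides both contribute to
  $A$, can exceed 1 and are flagged rather than rejected.
* **Fractal dimension** $D$ — the Minkowski–Bouligand (box-counting)
  dimension of a surface point cloud: the slope of $\log N(s)$ against
  $\log(1/s)$, where $N(s)$ is the number of occupied cells of an
  axis-aligned grid with cell size $s$. It measures how the surface
  fills space across scales: $D \approx 2$ for smooth surfaces, rising
  toward 3 for space-filling structures.

**Informational complexity** describes the heterogeneity of the surface
elements through the distribution of unit surface normals, read as an
ecological community: orientation classes are "species" and their
sampled frequencies are "abundances".

* **Orientation richness** $R = S / n$ — distinct quantized normals per
  sampled normal (componentwise rounding to 2 decimals by default).
  Flat-faced moulds have a handful of orientations among many samples
  ($R \to 0$); organic printed surfaces have nearly all normals
  distinct ($R \to 1$).
* **Orientation diversity** $H = -\sum_i p_i \ln p_i$ — Shannon entropy
  (nats) of the normal distribution over an equal-area partition of the
  unit sphere (320 subdivided-icosahedron cells by default).
* **Orientation evenness** $J = H / \ln S$ — Pielou's equitability over
  the occupied cells, with $J = 1$ by convention when $S = 1$ (a single
  orientation is trivially even).

The two families deliberately use different category systems. Richness
counts distinct *exact* orientations, so it runs on the quantized raw
normals; entropy over raw unique vectors would grow without bound with
the sample size, so $H$ and $J$ run on the fixed sphere partition. Both
distributions, and the modes used, are recorded in each record's
diagnostics.

After the variable transforms $P_t = 1 - P$, $D_t = D - 2$, $H_t = H$
(chosen so all six metrics vary over comparable ranges; alternative
schemes are pluggable and provenance-stamped), the **Complexity Index**
is the plain sum

$$\mathrm{CI} = C + P_t + D_t + R + H_t + J .$$

```{r one-model}
rec <- evaluate_model(generate(shape_spec("menger", level = 2)),
                      resolution = 7700, seed = 1)
rec
```

## Sampling resolution

All surface quantities are computed from an area-weighted stratified
point sample at a stated resolution, 1 point/cm² by default — fine
enough to resolve the micro-habitat scales relevant to benthic
macro-fauna and mobile fish while keeping the box-count affordable.
Allocation is largest-remainder per face, so each face receives within
one point of `area * resolution` and the total is exactly the rounded
expectation; every point carries its face's unit normal; a seed makes
the sample (and everything downstream) reproducible. STL files carry no
units: coordinates are interpreted as centimetres, with `unit_scale`
available for models authored in other units.

## Numerical choices in the metric core

**Mesh hygiene.** Stored STL facet normals are discarded and recomputed
from the vertex winding. Vertices are merged within an absolute `1e-8`
tolerance; faces with area below `1e-12` of the total are dropped and
counted. If more than 10% of adjacent-face windings disagree, the
winding is repaired by propagation from the largest face and the global
orientation is fixed by the sign of the enclosed volume.

**Volume.** Watertight meshes (every edge shared by exactly two
consistently oriented faces) get the divergence-theorem volume. Open
meshes have no enclosed volume; a voxel flood-fill volume (cells not
reachable from outside, i.e. shell plus enclosed pockets, at 1/50 of the
smallest bounding-box edge by default) is reported instead and the
record is flagged. Convexity computed from a fallback volume inherits
the flag.

**Convex hull.** A quickhull implementation over the vertex set, with a
tolerance of `1e-10` times the bounding-box diagonal; collinear and
coplanar inputs are rejected as degenerate geometry.

**Box counting.** The grid is anchored at the bounding-box minimum
corner; points on the upper boundary are clamped into the last cell.
Box sizes form a ratio-2 geometric series from the largest bounding-box
edge down to twice the mean point spacing, and the dimension is the OLS
slope over all supplied scales with the fit's $R^2$ attached. Two
caveats matter in practice and are why `size_range` is exposed:

* At coarse scales the object is covered by a handful of boxes and the
  count is saturated or edge-biased: for a cube surface the exact count
  on an aligned grid is $6k^2 - 12k + 8$ at $k$ boxes per edge, so the
  local slope is $2 + 2/k$, and OLS over the full automatic range
  overestimates $D$ for smooth surfaces. Restricting the fit to scales
  with $k \gtrsim 16$ bounds that bias by 0.05. Diagnosing the scaling
  regime with the returned $R^2$ and refitting within it is standard
  box-counting practice.
* Averaging over the 8 half-cell grid offsets (`offsets = TRUE`) is
  available; it reduces lattice-alignment noise at fine scales but
  inflates coarse-scale counts (an offset grid needs an extra layer of
  cells), so it is off by default and only sensible together with an
  explicit fine-scale `size_range`.

The validation suite pins both regimes: planar and linear lattices give
exactly 2.000 and 1.000 on the automatic range; a dense cube sample
gives $2.00 \pm 0.05$ on the $k = 16\ldots256$ window; a level-2 Menger
sponge surface sampled at $10^5$ points gives
$D = 2.75 \approx \log 20 / \log 3$ on the automatic range.

## The statistical pipeline

**MFA.** The six metrics enter a grouped multiple factor analysis with
groups `{C, P_t, D_t}` (geometric) and `{R, H_t, J}` (informational).
Every variable is centred and scaled by its population standard
deviation (denominator $n$); each group's variables are divided by
$\sqrt{\lambda_1}$ of that group's own standardized PCA so neither
family can dominate the first global axis; the weighted matrix is
decomposed by SVD. The Complexity Index is a *supplementary* variable:
it is projected by correlation onto the dimension scores and — by
construction and by test — never changes an eigenvalue, score or
loading. Eigenvector signs are arbitrary, so they are fixed
deterministically and independently of the supplementary variable: on
each dimension the variable with the largest squared loading loads
positively. On the reference table this orients Dim.1 so CI correlates
positively (r = 0.92) and Dim.2 so evenness loads positively.

**Dimension retention.** The Karlis–Saporta–Spinaki rule retains
dimensions with eigenvalue at least $1 + 2\sqrt{(p-1)/(n-1)}$ (2.03 for
20 models and 6 variables). It is applied to the per-dimension sums of
the two groups' separate PCA eigenvalues, which live on the scale the
threshold assumes (each group's spectrum sums to 3). Because the
ordination plane needs two dimensions, a minimum of two is enforced and
flagged whenever the rule alone retains fewer.

**Clustering.** Ward linkage (`ward.D2`) on Euclidean distances between
dimension scores, cut at $k = 3$ clusters to match the three design
purposes. By default the clustering uses all dimensions kept by the MFA
(up to five) rather than only the KSP-retained plane — the convention
of the standard HCPC tooling, and the choice under which the reference
table's clusters coincide exactly with the design purposes (all
bio-mimicry designs together, and PROT4 — a massive protection module
with production-like packing — joining the production cluster). Pass
`n_dims = 2` to cluster on the retained plane only. Cluster labels are
renumbered by first appearance and row-order ties are broken
lexicographically, so the result is deterministic. Clusters are
described by v-tests on the scaled metrics (and CI):
$v = (\bar{x}_c - \bar{x}) / \sqrt{(s^2/n_c)\,(N-n_c)/(N-1)}$ with
population variance $s^2$, $|v| \ge 1.96$ marking a characterising
variable; singleton clusters report `NA`.

**Complexity Target Points.** In the Dim.1 × Dim.2 plane, each model's
distance from the origin is computed (identical to the distance from
the centroid, since scores are centred); the threshold is the mean
distance over models with positive Dim.1 (the "more complex than
average" half); the selected set is every model with positive Dim.1 at
or beyond the threshold, ties included. The CTPs are the per-metric
mean and sample (n−1) standard deviation over that set — the profile a
new design should meet or surpass.

```{r pipeline}
tab <- fixture_table1()
res <- mfa(tab)
res$inertia_pct[1:2]
select_ctp(tab, use_printed_distances = TRUE)
```

The selection can run either from freshly computed MFA scores or from
the score and distance columns bundled with the reference table
(`use_printed_distances = TRUE`). The bundled table stores all values
at 3-decimal precision; recomputing the ordination from those rounded
inputs reproduces the bundled Dim.1 ordering and cluster structure, but
individual scores shift by a few percent, enough to move one model
(BIOM7) marginally across the distance threshold. The printed-distance
path is therefore the reference path for reproducing the bundled
targets, and the recomputed path is the one to use on new data.

## The synthetic shape families

The reef models the method was developed on are proprietary, so the
package validates its metric core against parametric shapes with known
properties: `cube` and `icosphere` (convex: $C = 0$, $P = 1$,
$D \to 2$), `open_box` (deliberately non-watertight, exercises the
fallback volume and the $P > 1$ flag), `menger` (levels 1–3; volume
$(20/27)^L$ and face counts come from an independent combinatorial
occupancy oracle, giving exact $C$ and $P$ references and the asymptotic
$D = \log 20 / \log 3 \approx 2.727$), `perforated_shell` (a voxelized
hollow box with through-holes, oracle-driven references) and
`rough_sphere` (icosphere with seeded i.i.d. radial vertex displacement;
no analytic reference, used for monotonicity checks — more displacement
must not lower estimated $D$).

These shapes emulate the *range* of the metrics (filled vs hollow,
smooth vs folded, few vs many orientations), not real reef geometry:
they have exactly flat faces, axis-aligned features and perfect
symmetries that real CAD models lack. Passing the shape oracles
demonstrates the estimators are correct, not that any particular reef
scores well; the pipeline-level checks on the bundled 20-model table
cover the realistic end of the data.

## Problem sizes and runtimes

The test suite keeps every mesh at desk scale: Menger level 2 (2 112
faces, ~10⁵ sample points) is the largest routine fixture, and the
densest computation is the cube dimension check (~1.4 million points
over five scales, a few seconds). The full suite runs in under a
minute; `scripts/acceptance.R` recomputes the ordination quantities
from the bundled table in under a second.

## Known limitations

* Convexity counts sealed internal voids as solid (divergence-theorem
  volume); they become "accessible" only through the voxel fallback of
  an open mesh. For reef modules — which are built to be entered — this
  matches the ecological reading, but it is a modelling choice.
* The box-counting estimate depends on the chosen scale window whenever
  the object is not an ideal fractal; the automatic window is a
  reasonable default, the $R^2$ diagnostic and `size_range` are the
  user's tools, and single-grid estimates on strongly axis-aligned
  geometry carry alignment noise that the rigid-motion tests quantify.
* Orientation metrics depend on the quantization (decimals, cell
  count); values are comparable only at matching settings, which is why
  every record carries them in its diagnostics.
* Mesh repair is limited to vertex merging, degenerate-face removal and
  winding reorientation; self-intersecting or non-manifold inputs are
  reported as non-watertight rather than fixed.
* The CTPs summarise the most complex *available* designs; they are
  relative targets within a candidate set, not absolute ecological
  optima, and post-immersion data is the only way to validate them.
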