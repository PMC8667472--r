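---
title: "Methods: canopy features and effective LAI from row-crop LiDAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy features and effective LAI from row-crop LiDAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caplidar)
```

## The estimation problem

Leaf area index (LAI) — one-sided leaf area per unit ground area — is a
central trait in sorghum and maize breeding trials, but direct measurement
is destructive and slow. Optical instruments instead infer an *effective*
LAI from the canopy gap fraction; under the assumption of non-random
foliage placement, the two are related through a clumping index
$\Omega \in (0, 1]$:

$$\mathrm{LAI}_{\mathrm{eff}} = \Omega \cdot \mathrm{LAI}.$$

Discrete-return LiDAR flown (or driven) over a trial produces a 3D point
cloud whose geometry carries the same information: the fraction of pulses
that reach the soil measures the gap fraction, and the distribution of
vegetation returns measures canopy structure. `caplidar` turns such point
clouds into per-plot features and fits regression models mapping those
features to ground-reference effective LAI.

## Pipeline stages and their conventions

### Terrain

The digital terrain model (DTM) is built once from a bare-earth acquisition
made before planting and reused for every canopy epoch — agricultural
fields do not change elevation over a season. Each cell of a regular grid
takes the **minimum** $z$ of the points inside it; the minimum is robust to
low residual vegetation and debris, which only ever bias other aggregators
upward. Empty cells are filled from the nearest populated cell. The default
cell size is 0.25 m so that ~0.76 m row spacing is resolved; both cell size
and the fill rule are deliberate engineering choices, exposed as arguments,
since neither is dictated by the physics.

Heights are normalized as $h = z - \mathrm{DTM}(x, y)$. Points with
$h < 0.10$ m are classed as ground and excluded from all vegetation
statistics; $h = 0.10$ m exactly is vegetation (the rule is *strictly less
than* 10 cm). Points falling outside the DTM extent clamp to the nearest
cell rather than erroring, because plot polygons routinely extend slightly
past the bare-earth flight footprint.

### The eight features

For each region (a plot or two-row block, clipped with an
*inclusive* point-in-polygon test so boundary returns are never silently
dropped):

* **LPI** $= N_{\mathrm{ground}} / (N_{\mathrm{ground}} +
  N_{\mathrm{veg}})$, the laser penetration index. All returns count; the
  simulated sensors operate in single-return mode, so no per-return
  weighting is defined.
* **Height mean, standard deviation (n−1), adjusted Fisher–Pearson
  skewness, third quartile** (type-7 linear-interpolation percentile) of
  vegetation heights. The coefficient of variation and maximum height are
  computed and reported alongside but are *not* model inputs.
* **VCI**, the vertical complexity index: normalized Shannon entropy of the
  height histogram, $-\sum_i p_i \ln p_i / \ln(HB)$, with bins of 0.10 m
  spanning from the ground threshold to the maximum height and
  $0 \ln 0 := 0$. The bin width is not physically constrained; 0.10 m
  matches the ground-rule scale and is configurable.
* **Hull volume**: the volume of the 3D convex hull of the vegetation
  points. No qhull binding is available in this stack, so the package
  carries its own incremental (beneath–beyond) hull; it is validated
  against closed forms and an external qhull implementation in the tests.
* **CAP**, described next.

Skewness needs at least 3 points; regions below that are flagged `missing`
and excluded from modelling rather than imputed.

### Clusters' Area Plane (CAP)

CAP summarizes the *horizontal* organization of the canopy at a reference
height. A slice of half-thickness 4 cm is taken at the 0.75 quantile of
vegetation heights (lower quartiles tend to contain too few returns in
dense row crops to be usable); the sliced points, projected to the plane,
are clustered by region growing: each point links to its $k$ nearest
neighbors within a radius, the neighbor relation is symmetrized, and
clusters sharing points are joined until nothing changes. The
implementation performs that iterative joining with union-find over the
neighbor edges, which reaches the identical fixed point (connected
components of the symmetrized neighbor graph) in one pass. With
$k \ge n - 1$ the construction degenerates to plain radius-graph connected
components, which is what the test oracle exploits.

Each cluster's area $A_i$ is the area of the 2D convex hull of its member
points — a deterministic choice; an alpha shape would hug concave blobs
more tightly but introduces its own free parameter. CAP is the sum of the
$A_i$ that exceed an area threshold:

$$\mathrm{CAP} = \sum_{i : A_i > \tau} A_i.$$

The radius (0.10 m), $k$ (10) and $\tau$ (0.01 m²) are user-defined by
nature; the defaults suit row crops at the simulated densities. The slice
quantile is taken over *vegetation* heights, consistent with ground returns
being excluded everywhere else. CAP is non-increasing in $\tau$, and an
empty slice gives CAP = 0 rather than an error. Note that cluster hulls may
overlap, so CAP is not bounded by the hull area of the whole slice.

### Regression protocol

Eight features (LPI, height mean/sd/skewness/Q3, VCI, hull volume, CAP)
predict ground-reference effective LAI. Records are split **by variety**:
75% of genotypes (rounded) to training, the rest to test, both replicates
of a genotype always on the same side — replicates are near-duplicates and
splitting them would leak. Three families are fitted:

* **SMLR** — bidirectional stepwise OLS on the raw feature scale, entry and
  removal both at $\alpha = 0.05$ by partial-F p-value. Stepping stops
  early once the fit is numerically exact (residual SS below
  $10^{-12}\,SS_{tot}$), where partial-F statistics stop meaning anything.
* **PLSR** — standardized partial least squares; the component count
  maximizes the pooled 10-fold cross-validated R² on the training set. At
  full rank PLSR reproduces OLS, which the tests assert against `lm()`.
* **SVR** — $\epsilon$-SVR with linear, polynomial, RBF and sigmoid
  kernels, inputs standardized, hyperparameters grid-searched over
  $C \in \{0.1, 1, 10, 100\}$, $\gamma \in \{1/p, 0.01, 0.1, 1\}$,
  $\epsilon \in \{0.01, 0.1, 0.5\}$, degree $\in \{2, 3\}$, scored by
  pooled 10-fold CV R².

CV scoring pools the out-of-fold predictions into a single R² rather than
averaging per-fold R² values: with ~12-record folds the per-fold statistic
is wildly unstable. Test-set R² ($1 - SS_{res}/SS_{tot}$) and RMSE are the
headline metrics; a zero-variance test target yields R² = 0 by convention
with a warning. Both CV and test R² are reported, since published summaries
do not always say which is which.

### Feature importance

The leave-one-out weight of a feature under a reference model (SVR-RBF by
default, the strongest family) is

$$w = 1 - R^2_{\mathrm{new}} / R^2_{\mathrm{original}},$$

where $R^2_{\mathrm{new}}$ comes from refitting the *entire* protocol —
same variety split, same CV folds, same grid — without that feature.
Pinning the split and grid by seed means the weight isolates the feature's
removal. Weights are at most 1, zero for irrelevant features, and may be
negative when removal helps; negative weights are reported, not clipped.
The companion correlation matrix shows absolute Pearson correlations on a
0–1 scale; correlations involving a zero-variance column are reported as 0
with a warning.

## What the synthetic generator emulates

No field data ships with the package; a generator produces scenes with the
statistical structure the pipeline assumes:

* **Geometry** — rectangular plots of 2 rows at 0.76 m spacing, plants
  placed along rows at densities of ~200,000 (sorghum preset) or ~75,000
  (maize preset) plants/hectare; plots tiled on a grid with 1 m alleys.
* **Physics** — single-return pulses at nadir. Each pulse over a plot
  returns from the soil with probability
  $T = \exp(-G\,\Omega\,\mathrm{LAI})$ (Beer–Lambert transmittance,
  extinction $G = 0.5$ by default) and otherwise from the canopy, at a
  height drawn from a configurable vertical profile (uniform, triangular
  or Beta(2,2) between base and top) and laterally jittered
  ($\sigma = 0.1$ m) around a random stem. Ranging noise is Gaussian with
  $\sigma_z = 0.01$ m.
* **Truth** — each variety draws one effective LAI uniformly from a
  configured range (0.5–6 for a sorghum-like trial, 0.5–5 maize-like),
  shared by its two replicates; $\mathrm{LAI}_{\mathrm{eff}} =
  \Omega \cdot \mathrm{LAI}$ is the definition of truth, not re-derived
  from foliage geometry. Canopy top height grows with LAI
  ($0.4 + 0.35 \cdot \mathrm{LAI}$ m by default) so height features carry
  signal as they do in a growing crop.
* **Pulse densities** — presets at 70, 500 and 1,400 points/m² span the
  sparse-UAV to ground-vehicle range.

What it does **not** emulate: multiple returns, within-canopy multiple
scattering, intensity/radiometry, wind-induced artifacts, occlusion between
neighboring plots, leaf-angle distributions (clumping enters only as the
scalar $\Omega$), and spatially correlated soil roughness. Consequently a
passing pipeline demonstrates that the *software* recovers the generative
relationship it was pointed at — it does not certify field accuracy, where
gap-fraction references and LiDAR disagree for reasons outside this model
(instrument height, canopy penetration limits at high density, and so on).

## Problem sizes used in the checks

The package's own end-to-end check generates a 160-plot study (80 varieties
× 2 replicates) at the 500 points/m² preset with $\sigma_z = 0.01$ m —
roughly 350,000 canopy returns — and requires SVR-RBF held-out R² ≥ 0.8
plus LPI retained by SMLR; with LPI measuring transmittance directly and
heights loosely tracking LAI, recovery well above that bound is expected.
The sparsest preset (70 points/m²) is deliberately not used for the CAP-
bearing end-to-end check: a ±4 cm slice of such a cloud holds on the order
of ten points per plot, no cluster reaches the area threshold at the
default radius, and CAP degenerates to a constant 0 — the same inadequate-
sample behavior reported for lower height quartiles. That degeneracy is a
property of the feature at sparse densities, worth knowing before choosing
acquisition parameters. The repeated-seed
importance check (100 independent splits) runs on a directly generated
feature table with a reduced SVR grid ($C \in \{1, 10\}$, $\gamma = 1/p$,
$\epsilon = 0.1$): the leave-one-out procedure is identical and the grid is
part of its configuration; the reduced grid keeps 900 grid-searched refits
affordable while leaving the ranking question untouched.

## Numerical choices and degenerate inputs

* Quantiles everywhere are type-7 (linear interpolation), R's default.
* Skewness of a constant sample is 0 by convention; fewer than 3
  vegetation points marks the record missing.
* VCI with fewer than 2 bins (vertical extent below one bin width) is an
  error, surfaced as a missing record at extraction level.
* Hull volume of coplanar/collinear sets is 0 with a warning, not an
  error; the incremental hull uses a relative tolerance of $10^{-9}$ times
  the bounding-box extent for visibility tests.
* Clustering ties (a point equidistant from two clusters) are resolved by
  the union of *all* qualifying neighbor edges, so the result is
  order-independent by construction.
* The LAS writer quantizes coordinates to a 1 mm scale; CSV and ASCII PLY
  round-trip at full double precision.
* Empty regions, bare-ground regions (LPI = 1) and fully closed canopies
  (LPI = 0) are all representable and tested.

## Known limitations

* The region-growing defaults (radius, $k$, area threshold) are tuned to
  row-crop slice densities; forest-scale data would need different values.
* The hand-rolled 3D hull is $O(nh)$ per region; it is comfortable at
  breeding-trial densities (hundreds to thousands of vegetation points per
  plot) but not designed for multi-million-point regions.
* SMLR inherits the usual caveats of stepwise selection: p-values after
  selection are optimistic, and collinear features (height mean/sd/Q3
  correlate above 0.9 here) make the retained subset unstable between
  splits. It is included as a baseline family, not a recommendation.
* CRS handling is out of scope: all inputs must already share one
  projected metric frame.
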