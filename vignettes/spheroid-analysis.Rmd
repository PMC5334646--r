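---
title: "Multiscale analysis of nuclei-stained spheroids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale analysis of nuclei-stained spheroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidr)
```

`spheroidr` turns a 3D light-sheet stack of a nuclei-stained, optically
cleared spheroid into per-cell measurements at three scales: the single
nucleus (morphology, intensity), the cell neighbourhood (graph-based local
density), and the whole aggregate (alpha-shape geometry, radial
organization). This vignette explains the models behind each stage, the
parameters that matter, the numerical conventions, and what the synthetic
phantom tests do and do not establish.

## The image model and pre-processing

Stacks arrive with a finer lateral than axial pitch (e.g. 0.325 µm vs
1.29 µm on a typical 20× light-sheet setup). `prepare_image()` makes voxels
isotropic by linearly interpolating planes along Z — the cheapest scheme
consistent with band-limited data — and then downscales by local-mean
(block-average) resampling, which suppresses aliasing without an extra
filter pass. With the default `ImageScalingFactor = 0.5` the working voxel
is 0.65 µm; **all voxel-valued parameters below are in this downscaled
space**. Intensities are min–max normalized to [0, 1] at this point, which
makes all later thresholds scale-free: a global affine rescale of the raw
data changes nothing downstream.

## Initial segmentation

The foreground mask separates nucleus-containing regions from background:

1. Gaussian smoothing with `NucleiFilterRange = 3` (interpreted as a kernel
   of truncation radius 3 voxels with σ = 1.5, the radius/2 convention of
   the platform the approach originated on).
2. `t_global`: Otsu's threshold of the smoothed image — the global
   background level. A constant image has no Otsu split; it yields an empty
   mask with a warning.
3. Per sectional plane along X, Y and Z, a local threshold
   `t_local = m_local + γ · t_global`, with `m_local` the mean over a
   25 × 25 window (`NucleiThresholdRange`, mirror padding) and
   `γ = 0.25` (`NucleiBackgroundFactor`). This is the simplest form in
   which γ scales only the background term; it is a package choice, exposed
   in the configuration, because the published description names the
   ingredients but not the formula.
4. The three per-axis binary stacks are AND-ed, and enclosed background
   cavities (6-connected complement components not touching the image
   border) smaller than 250 voxels are filled.

## Marker detection: the multiscale LoG

Nuclei are bright blobs; in the inverted image `f_i = 1 - f` they are dark
basins. The detector computes the scale-normalized Laplacian of Gaussian

σ³ · ∇²(g_σ ∗ f_i),

as a separable convolution, and takes the voxel-wise maximum over a set of
scales. For the σ³ normalization the centre response of a solid ball of
radius R is proportional to R³ σ⁻⁵ exp(−R²/2σ²) · σ³, which is maximized at
**σ = R/√2**; the package therefore spans its `n_scales = 5` scales
uniformly over [r_min/√2, r_max/√2] with the measured nucleus radius bounds
r_min = 3, r_max = 6 voxels. Two consequences of σ³ normalization are worth
knowing: the frequently quoted blob relation σ = R/√3 belongs to σ²
(γ = 1) normalization, not σ³; and the peak response grows linearly with
blob radius rather than being scale-invariant, so larger nuclei respond
more strongly. Neither matters for marker detection, which looks for
spatially separated maxima, but both are verified by a numerical σ-sweep in
the test suite.

Markers are the extended maxima of the response — regional maxima of the
h-maxima transform with h equal to 2% of the response dynamic range (the
depth parameter is not part of the published description; 2% is the package
default and configurable) — intersected with the foreground mask, merged by
dilation with a 2-voxel ball (`NucleiSeedDilation`), and labelled with
26-connectivity.

## Watershed decomposition

A marker-controlled immersion watershed floods `f_i` from the markers in
ascending intensity with 6-connected flooding. The priority queue is
ordered by (intensity, insertion counter), which makes the result
bit-reproducible; voxels where two basins meet become watershed lines
(label 0). Because immersion does not stop at nucleus borders, the
partition is multiplied by the foreground mask, and objects outside the
[250, 42,500]-voxel gates are removed (`NucleiMinCount`, `NucleiMaxCount`).
The lower gate is about a quarter of the mean nucleus volume; the upper
gate removes merged clusters. Labels are compacted to 1..n.

## Per-nucleus features

`extract_features()` returns one row per nucleus: volume (voxels and µm³),
centroid and intensity-weighted centroid, mean/min/max distance of *all*
object voxels to the centroid (the all-voxel convention is a package
decision; a surface-voxel variant would differ slightly), surface voxel
count (6-neighbour definition), bounding box, principal axes from a PCA of
the voxel coordinates with peak-to-peak extents of the projections, and
intensity statistics on the [0, 1]-normalized stack. Degenerate objects
(single voxels, planes) get zero-variance axes with extent 0 and a
completed orthonormal basis.

## Spheroid geometry: alpha shape and NDS

Spurious detections far from the aggregate are removed first: all centroids
within 20 voxels (`OutlierDistanceThreshold`) are connected and only the
largest component is kept. The spheroid solid is then the **alpha shape**
of the centroids: the tetrahedra of the 3D Delaunay triangulation whose
circumradius is below α = 90 voxels. This convention (one of several
equivalent alpha-complex formulations) has the two stated limits — the
shape converges to the point set as α → 0 and to the convex hull as
α → ∞ — and makes volume and surface area direct sums over kept tetrahedra
and boundary faces. If the kept complex splits into several face-connected
components the largest-volume one is retained with a warning.

The Delaunay triangulation is a from-scratch incremental Bowyer–Watson
implementation (no computational-geometry library exists in the supported
R stack). It uses double-precision orientation/insphere predicates with
relative tolerances; exactly degenerate inputs (co-spherical grids,
coplanar point sets) should be jittered, and the graph/geometry builders
expose a `jitter` argument that applies a seeded 10⁻⁶-voxel perturbation.
The implementation is cross-checked in the tests against closed forms
(regular tetrahedron, convex-hull limits, ball volumes) and against an
independent Delaunay oracle.

Each nucleus's depth is its minimum Euclidean distance to the boundary
triangle mesh (point-to-triangle distance, not a rasterized distance
transform — a deliberate choice that avoids grid quantization), and the
**normalized distance to the surface** is NDS = depth / max(depth): 0 at
the surface, 1 at the deepest point of the dataset. Normalizing by the
dataset maximum rather than by the distance to the shape centroid respects
non-spherical aggregates.

## Cell graphs and local density

The proximity cell graph (PCG) joins centroid pairs strictly closer than
40 voxels (`EdgeDistanceThreshold`); ties at exactly the threshold are
excluded. The Delaunay cell graph (DCG) additionally requires a Delaunay
edge, and is a subset of the PCG at equal threshold. Edge weights are
Euclidean distances. The PCG vertex degree counts the neighbours within
one "unit volume" — 65,450 µm³ by convention — and is interpreted as the
local cell density; dividing by the unit volume and scaling by 10⁹
converts to cells/mm³ (35 and 70 cells/u.v. correspond to ~5 × 10⁵ and
~1 × 10⁶ cells/mm³). The printed unit volume is treated as an opaque,
configurable constant: a sphere of radius 25 µm has exactly this volume,
while the 40-voxel threshold at 0.65 µm/voxel is 26 µm; the package does
not attempt to reconcile the two.

A graph edge effect matters for interpretation: vertices shallower than
one edge threshold lose part of their neighbourhood outside the surface,
so radial density profiles always rise over roughly the first
`threshold / radius` of NDS. Real spheroids (radius ≈ 300 voxels) are flat
beyond NDS ≈ 0.1; desk-scale analogues must use shapes several times
larger than the threshold, which the tests do.

## Radial profiles, regions and the RCP null model

`radial_profile()` bins a per-nucleus feature into equal-width NDS bins
(default 20) with per-bin mean and standard error.
`summarize_regions()` labels nuclei as surface ([0, 0.1) NDS), outer and
core, with the outer/core boundary at 0.75 NDS for medium and 0.5 NDS for
large spheroids; the mean radius is the maximum depth in µm and the outer
thickness is `core_cut × mean_radius` — the depth of the outer/core
boundary below the surface (0.75 × 191.3 µm = 143.5 µm;
0.5 × 213.7 µm = 106.85 µm, which reports as 106.8 µm because the stored
double sits marginally below the rounding boundary). Reported µm values
use half-away-from-zero rounding to one decimal. The outer-region *volume*
is provided under a concentric-shrinkage convention (shape volume ×
[(1−0.1)³ − (1−core_cut)³]) and is documented as a convention only — no
single shell model reproduces previously published outer-volume figures,
so the field is informative, not authoritative. The region cuts themselves
are user decisions; `suggest_transition()` offers a second-difference
change-point heuristic but is deliberately not authoritative.

The **random cell position (RCP) model** asks whether a dataset's spatial
organization could arise by chance: cells are placed uniformly inside the
alpha shape as non-overlapping spheres of the median nucleus radius
(~6 voxels for real data; pipelines derive it from the segmented volumes),
matched in count to the dataset, with 10 Monte Carlo replicates by
default. Sampling is exact: a tetrahedron is drawn with probability
proportional to its volume and a point uniformly within it, so no
point-in-shape rejection is needed; the non-overlap constraint is enforced
by rejection with a spatial hash grid and a 10,000-rejection feasibility
limit (random sequential packing jams near 38% fill, and the generators
refuse clearly infeasible requests up front).

When comparing a real profile with its RCP ensemble at desk scale, note
that the alpha shape of n points is slightly smaller than the true
occupied region (a convex-hull deficit shrinking as n grows), so RCP
replicates sit at a few percent higher density than the real pattern.
`rcp_step_test()` therefore measures the *step* of the (real − RCP)
difference curve across a candidate layer boundary, in units of its
standard error, which cancels this global offset; layered phantoms show
the step at many standard errors while matched uniform phantoms do not.

## Dataset-level analyses

`cluster_datasets()` partitions datasets by cell number and spheroid
volume using PAM with squared Euclidean distance on z-scored features
(raw scales differ by orders of magnitude, and the published account does
not state a scaling; z-scoring is the package's choice). For n ≤ 20 the
medoid set is found by exhaustive search — deterministic and globally
optimal — with `cluster::pam()` for larger inputs; group labels are
relabelled in order of increasing medoid cell number.
`fit_volume_cell_line()` is ordinary least squares of volume on cell
number with broom-style `tidy()`/`glance()` methods.

## Evaluation

`match_centroids()` implements a greedy one-pass matcher: ground-truth
centroids in ascending index order claim their nearest unmatched
segmentation centroid within a 12-voxel spherical neighbourhood (ties at
equal distance go to the lower index); FP = N_SC − TP and FN = N_GT − TP.
The greedy order can differ from a globally optimal assignment on rare tie
configurations; the tests verify agreement on the canonical cases. Recall,
precision and the F score (harmonic mean) are reported unrounded, with
undefined ratios returned as `NA` rather than 0.

## The synthetic phantom: what it emulates

`generate_phantom()` places nucleus centres in a ball (uniformly, or with
a two-layer concentric density when `layering` is set) under a pairwise
non-overlap constraint, renders each nucleus as a solid sphere with a
radial intensity falloff, blurs with a 1-voxel Gaussian as a PSF
surrogate, and adds background and Gaussian noise before 16-bit
quantization. The defaults are chosen to match the statistics of real
cleared-spheroid data: ~200 nuclei with radii 4.5–7.5 voxels — median
radius 6 voxels and median volume ≈ 905 voxels ≈ 250 µm³ at 0.65 µm pitch,
consistent with reported median nucleus volumes — packed at ~27% effective
fill in a radius-56-voxel ball, which corresponds to ~10⁶ cells/mm³, the
dense end of the observed range. A uniform 3–6-voxel radius range would
put a third of the population below the 250-voxel volume gate and is
therefore not a faithful volume distribution (3 and 6 voxels are the
seed-detection scale bounds, not population quantiles).

What a green phantom test establishes: that the implementation chain —
thresholding, LoG, watershed, gates, matching — recovers dense, noisy,
size- and intensity-heterogeneous spherical nuclei with F ≥ 0.85 (measured
≈ 0.99). What it does not establish: performance on real optics
(attenuation with depth, anisotropic PSF, scattering, clearing artifacts),
non-convex or mitotic nuclei, or chromatin texture; the phantom
deliberately contains none of these.

## Numerical conventions and degenerate inputs

* Arrays are `dim = c(y, x, z)`; exported coordinates are 0-based
  `(x, y, z)` voxel coordinates.
* Connectivity: 26 for components and markers, 6 for watershed flooding
  and hole filling; mirror padding for all filters.
* Otsu on a constant image → +∞ threshold, empty mask, warning.
* Watershed ties → (intensity, insertion index) queue; bit-reproducible.
* Delaunay on degenerate inputs → error with guidance to jitter.
* Packing requests beyond the ~38% jamming limit → immediate error.
* All stochastic stages consume R's RNG; `set.seed()` makes phantom
  generation, RCP sampling and the full pipeline reproducible.

## Known limitations

* The watershed loads whole stacks in memory; there is no tiling.
* Baseline TIFF only (uncompressed, single-sample, 8/16-bit).
* The alpha-shape predicates are double precision with tolerances, not
  exact arithmetic; pathological inputs need jitter.
* The greedy matcher is order-dependent on exact-tie configurations.
* The RCP feasibility guard is a heuristic bound, not a proof; requests
  near the jamming limit may still fail after many rejections.
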