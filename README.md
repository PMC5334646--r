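# spheroidr

Multiscale image analysis for nuclei-stained multicellular spheroids in R.

Multicellular spheroids grown in 3D culture are a standard *in vitro* model
for tissue architecture, drug response and tumour biology. Light-sheet
microscopy of optically cleared spheroids yields 3D stacks in which every
nucleus is visible — tens of thousands per specimen — but turning those
stacks into per-cell measurements requires segmenting densely packed,
apparently touching nuclei and then quantifying each cell's neighbourhood
and position inside the aggregate. `spheroidr` implements that whole chain
for users who want to go from a TIFF stack to per-nucleus tables, spheroid
geometry and spatial statistics without leaving R.

## What it computes

* **Pre-processing** — anisotropic stacks are resampled to isotropic voxels
  (linear plane interpolation) and downscaled by local-mean resampling
  (default factor 0.5; with a 0.325 µm lateral pitch the working voxel is
  0.65 µm).
* **Nuclei segmentation** — local adaptive thresholding per sectional plane
  along X, Y and Z with threshold `t_local = m_local + γ·t_global`
  (`t_global` from Otsu, γ = 0.25), hole filling; marker detection by a
  multiscale Laplacian-of-Gaussian filter, `σ³·∇²(g_σ * f_i)`, maximized
  over scales spanning nucleus radii 3–6 voxels; marker-controlled
  immersion watershed; volume gates at 250 and 42,500 voxels.
* **Per-nucleus features** — volume, centroids, distance-to-centroid
  statistics, surface voxels, bounding box, PCA axes/extents, intensity
  statistics.
* **Spheroid geometry** — outlier removal by proximity-graph components
  (20 voxels), Edelsbrunner alpha shape of the centroids (α = 90 voxels;
  tetrahedra kept when circumradius < α), solid volume, surface area, and
  each nucleus's normalized distance to the surface
  (NDS = depth / max depth; 0 at the surface, 1 at the deepest point).
* **Cell graphs** — proximity cell graph (PCG: edges strictly below a
  40-voxel threshold) and Delaunay cell graph (DCG: Delaunay edges below
  the same threshold; always a subset of the PCG). The PCG degree is the
  local cell density in cells per unit volume (65,450 µm³), convertible to
  cells/mm³.
* **Spatial analysis** — radial density profiles over NDS, surface/outer/
  core region summaries (outer thickness = core cut × mean radius), the
  random-cell-position (RCP) null model (non-overlapping spheres placed
  uniformly inside the alpha shape, 10 Monte Carlo replicates), PAM
  clustering of datasets by cell number and volume, and the linear
  volume–cell-number fit.
* **Evaluation** — greedy centroid matching within a 12-voxel neighbourhood
  and recall / precision / F score.
* **Synthetic phantoms** — `generate_phantom()` builds noisy, packed
  spheroid stacks with exact ground truth so every stage is testable
  without microscopy data.

The heavy numerics (separable 3D filters, connected components,
morphological reconstruction, seeded watershed, incremental 3D Delaunay
triangulation, point-to-mesh distances, sphere packing) are implemented in
C++ via Rcpp.

## Worked example

```r
library(spheroidr)

ph  <- generate_phantom(phantom_spec(seed = 1))   # ~200 nuclei, ground truth
img <- prepare_image(ph$stack, z_scaling_factor = 1, image_scaling_factor = 1)
seg <- segment(img)
seg
#> <label_image> 137 x 137 x 137 (y,x,z), 195 objects, 0.65 um/voxel

tidy(evaluate_segmentation(ph$centroids, seg))
#> # A tibble: 1 x 9
#>      tp    fp    fn  n_gt  n_sc match_radius recall precision f_score
#>   <int> <int> <int> <int> <int>        <dbl>  <dbl>     <dbl>   <dbl>
#> 1   195     0     5   200   195           12  0.975         1   0.987

features <- extract_features(seg, img)
pts      <- remove_outliers(features[, c("x", "y", "z")])
surface  <- build_alpha_shape(pts, alpha = 90, pitch = img$pitch)
features <- add_nds(features, surface)
pcg      <- build_pcg(features[, c("x", "y", "z")], threshold = 40,
                      pitch = img$pitch)
dens     <- density_features(pcg)
mean(dens$degree)
#> [1] 49.6     # cells per unit volume; ~7.6e5 cells/mm^3

profile <- radial_profile(dens$degree, features$nds)
autoplot(profile)   # mean density vs normalized depth, SE ribbon
```

195 of the 200 simulated nuclei are recovered with no false positives
(F = 0.987); the mean proximity-graph degree of ~50 neighbours per unit
volume corresponds to ~7.6 × 10⁵ cells/mm³, inside the range reported for
real breast-carcinoma spheroids. `run_pipeline()` chains all stages,
writes labels, feature CSVs, a PLY surface mesh, GraphML graphs, profiles
and a JSON manifest, and `inst/cli/spheroidr.R` exposes the same stages as
shell subcommands (`simulate`, `segment`, `run`, `evaluate`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline analysis from scratch: it simulates a
default phantom, runs the full segmentation, geometry, graph and RCP
null-model chain, logs the detection quality and density summaries, and
writes the machine-readable report to `--out`.

See the vignette (`vignettes/spheroid-analysis.Rmd`) for the model
assumptions, parameter choices and known limitations.
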