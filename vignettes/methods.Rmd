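---
title: "Methods: fusion, mixing diagnostics and yield estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusion, mixing diagnostics and yield estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionyield)
```

# The problem

A plot-scale analyst wants a fine-resolution (30 m) NDVI image on a date
when only a coarse-resolution (240/480 m) image exists. Spatiotemporal
fusion predicts it from one fine *reference* image at t1 plus coarse
images at t1 and the target date t2. Two questions then dominate
practice, and this package is built to study both on scenes with known
truth: *which reference date* should be used, and *how badly do mixed
coarse pixels* — pixels whose footprint blends a plot with its
surroundings — degrade the result for a given plot?

# Grid model and alignment contract

A raster (`grid_raster`) is a matrix on a square-pixel planar grid,
pixel-corner origin at the north-west, rows increasing southward — the
ordinary north-up raster convention. Fusion and the mixing index require
the coarse grid to be *exactly* the fine grid coarsened by an integer
ratio (8 for 240 m / 30 m, 16 for 480 m / 30 m);
`resample_to_integer_grid()` (nearest-neighbor; the choice of kernel is
deliberately the simplest defensible one, and no other kernel is
offered) is the sanctioned path for off-grid inputs. The coarse sensor's
footprint is modeled as the unweighted block mean (`block_aggregate()`);
no point-spread function is attempted. NDVI pixels with a zero
denominator become nodata rather than 0, since 0/0 reflectance carries
no information.

Because no GeoTIFF reader exists in the supported dependency set, raster
I/O uses the ESRI ASCII grid dialect — plain text, lossless at 17
significant digits, readable by any GIS. Plot polygons are GeoJSON;
membership uses the even-odd rule, so holes (a road strip crossing a
plot) and multi-part plots (a plot split into sections by that road)
need no special casing.

# The fusion algorithm

`fsdaf_fuse()` composes six steps. The step list is fixed; the internal
math of each step involves choices the algorithm's general description
leaves open, resolved here as follows and covered by oracle tests:

1. **Delineation** (`delineate()`): crop to the region's bounding box
   snapped outward to whole coarse pixels; exterior cells are kept as
   context and flagged.
2. **Coarse change**: `delta_c = coarse_t2 - coarse_t1`.
3. **Temporal prediction** (`classify_fine()` +
   `temporal_prediction()`): one-dimensional k-means (seeded, 10
   restarts, classes relabeled by increasing center, so the result is
   deterministic) partitions the fine reference into `n_classes` covers;
   per-coarse-pixel class fractions form the linear system
   `F · delta_class ≈ delta_c`, solved by ordinary least squares with no
   nonnegativity constraint. A rank-deficient `F` falls back to ridge
   regularization (lambda = 1e-6) with a warning. The residual is kept in
   *change space*: `residual = delta_c - block_agg(tp_fine - fine_t1)`.
   The equivalent *level-space* form `coarse_t2 - block_agg(tp_fine)`
   coincides with it whenever the coarse image is the block mean of the
   fine image, but differs when the two sensors disagree radiometrically;
   the change-space form was chosen because it makes the no-change
   identity exact regardless of sensor bias: if the coarse scene does not
   change, the fusion returns the reference image bit for bit.
4. **Spatial prediction** (`tps_prediction()`): a classic thin-plate
   spline (kernel r² log r plus affine part, coordinates rescaled by the
   median control spacing for conditioning) fit to coarse pixel-center
   values and evaluated at fine centers. With `tps_smoothing = 0` (the
   default) it interpolates the control values exactly and reproduces
   affine fields to machine precision.
5. **Residual distribution** (`distribute_residuals()`): within each
   coarse pixel, fine pixels receive the residual in proportion to
   `score = max(1e-6, homogeneity × (1 − disc / max_block_disc))`, where
   `disc = |TPS prediction − temporal prediction|` and homogeneity is
   the same-class fraction in a (2·ratio + 1)² window (window size scales
   with the coarse footprint). Pixels already explained by the spatial
   prediction, and pixels in homogeneous neighborhoods, absorb less
   residual. Weights are renormalized per coarse pixel, so the block
   mean of the allocation equals the residual exactly — after this step
   the prediction is coarse-consistent by construction.
6. **Neighborhood refinement** (`neighborhood_refine()`): each pixel's
   final change is the inverse-distance-weighted (w = 1/(1 + d)) mean of
   the preliminary changes of its `n_similar` most spectrally similar
   neighbors in the search window. Ties in spectral distance break by
   spatial proximity, then row-major order, so results are deterministic;
   a pixel is always its own most similar neighbor, so `n_similar = 1`
   is the identity on changes.

Output NDVI is clipped to [−1, 1]. **Defaults** (`fusion_params()`):
`n_classes = 4` — the synthetic scenes contain 4–7 spectrally distinct
covers and four NDVI clusters separate them at typical dates;
`n_similar = 20` and `window_radius = ratio`, typical of the
spatiotemporal-fusion literature; `tps_smoothing = 0` because the coarse
control values are trusted. All are overridable; none is claimed to match
any particular published run.

# The Mixed Degree Index

For each coarse pixel overlapping a plot (numbered row-major; pixels
covering less than 1 % of a pixel area are excluded),

* `M_PAR = (S_P / S_W) · (S_P / S_Y)` — intersection area over pixel
  area, times intersection area over plot area. Read as a product of two
  fractions it is dimensionless and sums to 1 when a plot exactly tiles
  pure pixels, which is what bounds the index to [0, 1]; the alternative
  reading `S_P / (S_W · S_Y)` has units of 1/area and was rejected.
  `S_P` comes from exact polygon–rectangle clipping (Sutherland–Hodgman,
  signed areas, holes included).
* `NDVI_Pro = |NDVI_M − NDVI_L| / max(NDVI_M, NDVI_L)`, where `NDVI_L`
  is the mean fine NDVI over the *pixel ∩ plot* footprint, not the whole
  pixel — the index contrasts the coarse signal against the plot's own
  signal; whole-pixel means would re-introduce the very mixing being
  measured. When neither value is positive (bare/degenerate surfaces)
  the ratio is defined as 0 with a warning.
* `MDI = Σ M_PAR · NDVI_Pro`. Zero iff every included pixel agrees with
  the plot signal. The seasonal curve (`mdi_series()`) is reported
  per date; no published numeric MDI value exists to validate absolute
  levels against, so the tests pin hand-evaluated toys, limits,
  monotonicity, and the resolution ordering instead.

# Phenology and reference dates

Per-plot series are means over fine pixels whose centers fall in the
polygon, linearly interpolated to daily resolution; derivatives are
central differences smoothed by a 15-day rolling mean. Stage selection
snaps to actual observation dates (a reference image must exist):

* rise threshold 0.004 NDVI/day — onset of rapid growth (early stage);
* plateau threshold 0.002 NDVI/day — growth settles (middle stage);
* end fraction 0.9 of peak with non-positive derivative — established
  decline (end stage).

The thresholds are configuration, not truth: in field practice such
stages are read off the derivative curve by eye, and different analysts
draw the lines differently. The defaults were fixed together with the
default cotton curve (below) so that the package's stated season
reproduces the reference behavior — stages at DOY 174 / 206 / 254 with
peak 230 on the 8-day observation calendar — and are not revisited
per scene.

# The synthetic world

`scene_config()` describes everything the tests rely on. Defaults:

* 96 × 96 fine pixels of 30 m; ratios 8 and 16; observations every
  8 days, DOY 126–302.
* **Covers**: three cotton variants (double-logistic seasons; plot A's
  curve has base 0.12, amplitude 0.65, rise midpoint DOY 186 at
  0.20/day, fall midpoint DOY 260 at 0.28/day — the late, fairly sharp
  fall mimics September defoliation and was calibrated *before* any
  acceptance measurement so that stage detection reproduces the
  reference dates), an early crop senescing mid-season, a late crop, flat
  fallow (0.15) and road (0.08).
* **Plots**: A pixel-aligned with the ratio-8 grid; B irregular, split
  into two sections by a road strip of roughly 13 % of its bounding
  area; C offset by half a coarse pixel. This reproduces the layout
  contrast the mixing analysis needs (aligned / irregular / offset).
* **Heterogeneity vs noise**: a spatially smoothed multiplicative
  amplitude field (SD 0.08, ~90 m correlation) and phase field (SD 3
  days) are *landscape truth* — they persist across dates and are what
  makes one reference date genuinely more informative than another.
  Observation noise is i.i.d. Gaussian, SD 0.01 (fine) and 0.02
  (coarse), added on top; coarse images are block means *of the truth*
  plus noise, since the two sensors' errors are independent.
* **Yield**: serpentine harvest tracks (15 m swaths, 10 m point
  spacing); `yield = 2.5 · peak NDVI + 0.3 + N(0, 0.1)` in t/ha-scale
  units, the generating coefficients used throughout the recovery tests.

What a green test does **not** establish: realism of sensor physics (no
PSF, BRDF, atmosphere, clouds, geolocation error), spatially correlated
observation noise, multi-modal within-class distributions, or real
yield-monitor artifacts (flow lag dynamics beyond isolated spikes). The
generator is a statement of assumptions, not an emulator.

# Numerical and degenerate-case choices

* No-change and uniform-shift inputs reproduce the reference image (plus
  shift) to < 1e-6 — exact up to floating-point summation.
* k-means on near-constant images: `fsdaf_fuse()` caps `n_classes` at
  the number of distinct values; `classify_fine()` itself raises a
  degenerate-class error, as an explicit request for more classes than
  values is a caller bug.
* TPS with fewer than 3 or collinear control points raises an
  interpolation error.
* The outlier filter computes leave-one-out window statistics: including
  the candidate in its own mean/SD masks exactly the large spikes the
  3-SD rule exists to remove. A single pass over the original values
  keeps removals independent; the filter is idempotent in practice and
  tested as such. The default window of 21 points is a local, odd-length
  choice; nothing in the source material fixes it.
* The fused-versus-reference agreement statistic `r2_adj()` is the
  standard coefficient of determination of the fused-on-reference
  regression. A literal variance-ratio form sometimes quoted for this
  statistic is not bounded by 1 and is not a goodness-of-fit measure; it
  is available via `literal = TRUE` for comparison only.

# Known limitations

* NDVI-space fusion only; multi-band reflectance fusion is out of scope.
* The resolution-ordering property (ratio 8 beating ratio 16 on
  boundary-mixed plots) holds with a modest margin under the default
  noise model: the fine-scale amplitude jitter is an error floor common
  to both resolutions and dilutes the ordering, so individual seeds can
  invert it (the 20-seed experiment passes its ≥ 15 bar, with typical
  win counts of 14–19).
* The 3-SD moving-window rule has an irreducible small per-track chance
  of removing one clean point through an underdispersed window-SD
  estimate; this is a property of the rule, not of the implementation.
* MDI absolute levels are validated only against hand-computed examples
  and structural properties, as no published numeric values exist.
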