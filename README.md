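# fusionyield

Field-scale crop monitoring from mixed-resolution satellite imagery, in R.

Fine-resolution sensors (Landsat-class, ~30 m) revisit a field only every
8–16 days; coarse sensors (MODIS-class, 250–500 m) image it daily but blend
each plot with its surroundings into *mixed pixels*. `fusionyield`
implements the standard workflow for working at the plot scale anyway:

* **FSDAF fusion** — the six-step flexible spatiotemporal data fusion
  algorithm. Given one fine NDVI image at a reference date t1 and coarse
  NDVI images at t1 and a target date t2, it predicts the fine image at t2:
  coarse temporal change is unmixed into per-class changes
  (solving `F Δ ≈ ΔC` by least squares over the class-fraction matrix `F`),
  a thin-plate spline of the t2 coarse image supplies a spatial prediction,
  the per-coarse-pixel residuals are distributed over fine pixels with
  homogeneity/TPS-guided weights, and a similar-pixel neighborhood average
  produces the final prediction.
* **Mixed Degree Index (MDI)** — a plot-level diagnostic of pixel mixing,
  `MDI = Σᵢ M_PARᵢ · NDVI_Proᵢ` over the coarse pixels overlapping a plot,
  with `M_PAR = (S_P/S_W)(S_P/S_Y)` (pixel purity times plot share, from
  exact polygon–pixel intersection areas, pixels under 1 % coverage
  excluded) and `NDVI_Pro = |NDVI_M − NDVI_L| / max(NDVI_M, NDVI_L)`.
  0 means pure and consistent; values grow toward 1 with mixing.
* **Phenology** — per-plot NDVI time series, daily linear interpolation,
  finite-difference derivatives, and threshold-based selection of the
  early / middle / end reference dates and the season peak.
* **Yield estimation** — yield-monitor cleaning (moving-window
  leave-one-out 3-SD rule), 0.5 m rasterization, pixel-footprint pairing,
  the linear model `yield = a · NDVI + b` with R² and RMSE, and per-date
  NDVI–yield correlation curves.
* **Synthetic scenes** — a generator that builds a fine grid of crop plots
  and background covers with double-logistic seasons, coarse imagery by
  block-mean aggregation at integer ratios (8×, 16×) plus noise, and yield
  ground truth, so every stage above is testable against known answers.

Rasters are plain-text ESRI ASCII grids (`.asc`), plots are GeoJSON, yield
points are CSV — no binary GIS dependencies.

## Worked example

```r
library(fusionyield)

cfg   <- scene_config(seed = 42, doys = c(174L, 206L, 230L, 254L))
scene <- generate_scene(cfg)

# 1. pick reference dates from the fine time series of plot A
series <- extract_series(scene$fine, scene$plots[[1]])
identify_stages(series, obs_doys = cfg$doys)
#> <stage_selection> early 174 | middle 206 | peak 230 | end 254

# 2. fuse the mid-season reference with the coarse image at the peak date
coarse <- scene$coarse[["8"]]
fused  <- fsdaf_fuse(fusion_inputs(stack_at(scene$fine, 206),
                                   stack_at(coarse, 206),
                                   stack_at(coarse, 230), ratio = 8))
raster_rmse(fused, stack_at(scene$truth_fine, 230))
#> fused RMSE vs truth: 0.0351   (naively upsampled coarse: 0.1229)

# 3. how mixed is each plot at 240 m?
for (p in scene$plots)
  print(compute_mdi(p, stack_at(coarse, 230), stack_at(scene$fine, 230)))
#> <mdi_result> plot 'A' at 240 m: MDI = 0.0270 over 16 pixel(s)
#> <mdi_result> plot 'B' at 240 m: MDI = 0.0417 over 23 pixel(s)
#> <mdi_result> plot 'C' at 240 m: MDI = 0.0485 over 25 pixel(s)

# 4. estimate yield from the fused peak-season NDVI
clean <- filter_outliers(scene$yield)
yr    <- rasterize_yield(clean[clean$plot == "A", ], cell = 0.5)
fit_yield_model(pair_ndvi_yield(fused, yr, scene$plots[[1]]))
#> <yield_model_fit> yield = 2.3139 * NDVI + 0.4337 | R2 = 0.7294, RMSE = 0.0718, n = 1024
```

The numbers mean: stage detection lands on the calibrated season's
reference dates; fusion cuts the error against the (withheld) fine truth
by ~3.5× relative to naive upsampling; the pixel-aligned plot A is least
mixed and the half-pixel-offset plot C most mixed; and the recovered yield
model is close to the generating truth `yield = 2.5 · NDVI + 0.3` despite
observation noise and 0.1 t-scale yield noise.

A full end-to-end run (simulate → phenology → fuse 3 references × 2
ratios → MDI → yield fits, with a checksummed `manifest.json`):

```r
run_pipeline(list(outdir = "out", seed = 3))
```

or from the shell via the launcher in `inst/cli/`:

```sh
fusionyield run --config cfg.json
fusionyield fuse --fine-t1 f1.asc --coarse-t1 c1.asc --coarse-t2 c2.asc \
                 --ratio 8 --out fused.asc
```

## Vignette

`vignettes/methods.Rmd` documents the model choices, parameter defaults,
what the synthetic generator does and does not emulate, and known
limitations.
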