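# carptex

Non-invasive prediction of fish muscle texture from skin hyperspectral
images (400–1000 nm), for chemometricians and food-quality researchers.

Texture profile analysis (TPA) — gumminess, springiness, cohesiveness,
resilience, hardness, brittleness, adhesiveness, chewiness — normally
requires a destructive compression test on excised muscle. `carptex`
implements the alternative: calibrate regression models that map skin
reflectance spectra to muscle TPA indicators, then apply the best model to
every pixel of a hyperspectral cube to draw texture prediction maps.

The pipeline:

1. **Reflectance calibration** — black/white correction
   `I = (I0 − D)/(W − D) × 100` of raw cubes against dark and white
   reference images.
2. **Preprocessing** — Savitzky–Golay smoothing along the spectral axis and
   region-of-interest (ROI) mean spectra, one spectrum per sample.
3. **Wavelength selection** — the regression-coefficient (RC) method:
   peaks and valleys of the β-vector of a full-spectrum PLSR on
   standardized variables.
4. **Calibration models** — PLSR (NIPALS), interval PLS variants
   (iPLS / SiPLS / BiPLS, selected by calibration RMSEC), LS-SVM with an RBF
   kernel (exact dual solve, CV grid for γ and σ²), and a backpropagation
   neural network (1 hidden layer, ≤ 1000 epochs, goal 1e−5, learning rate
   and momentum 0.01).
5. **Evaluation** — r_c, r_p (squared Pearson correlation),
   RMSEC = √(Σe²/(N−1−R)), RMSEP = √(Σe²/N) on z-scored targets; the model
   with the highest r_p per (region, indicator) is retained.
6. **Visualization** — pixel-wise prediction maps on a linear blue→orange
   scale, plus ggplot2 `autoplot()` methods.

A seeded synthetic generator emulates the spectral and texture structure of
carp skin (430 nm trough, 600–780 nm plateau, ~980 nm water dip, monotone
dorsal spectra, region reflectance ordering, latent components linking
spectra to indicators), so the whole workflow runs and is tested without
proprietary data.

## Worked example

```r
library(carptex)

# simulate a linked spectra + texture dataset for the dorsal region
cfg <- generator_config(n_samples = 120, n_bands = 600,
                        regions = "dorsal", seed = 7)
d   <- generate_dataset(cfg)
spec <- sg_smooth(d$spectra$dorsal)          # SG window 11, order 2

# evaluate three models for chewiness on a seeded 75/25 split
evaluate_models(spec, d$texture, "chewiness",
                models = c("plsr", "lssvm", "bpann"),
                split = list(fraction = 0.75, seed = 1))
#> # A tibble: 3 x 11
#>   region indicator model  n_wl factors   r_c   rmsec   r_p  rmsep   n_c   n_p
#>   <chr>  <chr>     <chr> <int>   <int> <dbl>   <dbl> <dbl>  <dbl> <int> <int>
#> 1 dorsal chewiness plsr    600       6 0.998 0.0423  0.994 0.0819    90    30
#> 2 dorsal chewiness lssvm   600       2 1.000 0.00167 0.969 0.197     90    30
#> 3 dorsal chewiness bpann   600       1 0.991 0.0968  0.989 0.107     90    30
```

`r_c`/`r_p` are calibration/prediction squared correlations; `rmsec`/`rmsep`
are on the standardized-target scale (so 0.08 means 8 % of one target
standard deviation). PLSR wins here (`r_p` 0.994) and would be the retained
model for this cell via `rank_models()`.

The one-call version, which also selects wavelengths, ranks models and
writes a run directory with report, log and content-hash manifest:

```r
res <- run_pipeline(list(
  seed = 7,
  simulate  = list(n_samples = 120, n_bands = 600, regions = "dorsal"),
  selection = list(method = "rc", mode = "peak_threshold", param = 0.1)
))
res$retained          # best model per (region, indicator)
```

Prediction maps from a cube:

```r
cube <- generate_cube(cfg, rows = 64, cols = 64)$cube
tex  <- subset(d$texture, region == "dorsal")
m    <- fit_plsr(spec, tex$chewiness[match(spec$sample_ids, tex$sample_id)])
map  <- predict_pixelwise(cube, m, indicator = "chewiness")
render_map(map, "chewiness_map.png")   # blue = low, orange = high
autoplot(map)
```

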