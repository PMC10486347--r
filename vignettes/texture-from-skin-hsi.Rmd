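---
title: "Predicting muscle texture from skin hyperspectral images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting muscle texture from skin hyperspectral images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carptex)
```

## The problem

Texture profile analysis (TPA) of fish muscle — gumminess, springiness,
cohesiveness, resilience, hardness, brittleness, adhesiveness, chewiness —
is normally measured with a destructive double-compression test on excised
muscle. Visible/near-infrared hyperspectral imaging (HSI) of the *skin*
offers a non-invasive alternative: each pixel carries a 400–1000 nm
reflectance spectrum whose shape reflects the chemistry (water, protein,
lipid, pigment) of the skin and the tissue beneath it, and chemometric
regression can calibrate those spectra against measured TPA values.

`carptex` implements that full calibration workflow: reflectance
calibration, spectral smoothing, region-of-interest (ROI) averaging,
wavelength selection, six calibration models, the standard accuracy metrics,
best-model ranking, and pixel-wise prediction maps. Because no public
carp-skin HSI dataset exists, the package also ships a synthetic generator
that reproduces the statistical structure such data is reported to have, so
every stage is testable end to end.

## Processing model

**Reflectance calibration.** Raw intensity cubes are converted to percent
relative reflectance with the black/white correction

$$I = \frac{I_0 - D}{W - D} \times 100,$$

where $W$ is the white-reference image (100 % reflectance) and $D$ the dark
image (0 %). The implementation treats $W \le D$ anywhere as an error rather
than clamping: a non-positive denominator means the references are unusable
and silently clamping would corrupt every downstream model.

**Smoothing.** Savitzky–Golay polynomial smoothing is applied along the
spectral axis only (window 11 bands, polynomial order 2 by default). These
defaults are common Vis–NIR practice; both are exposed in the configuration.
Smoothing and ROI averaging are both linear, and along commuting axes, so
their order is provably irrelevant; the package applies
calibrate → smooth → average.

**ROI spectra.** Each sample contributes one spectrum: the per-band
arithmetic mean over a rectangular ROI (200 × 200 pixels by default). ROI
placement is taken as explicit coordinates; automatic fish-region detection
is out of scope.

## The calibration models

All six models share one contract: predictors and the target are z-scored
on the calibration set, the model operates on standardized variables, and
predictions are mapped back through the inverse target scaling. This makes
every model scale-equivariant in the target and makes coefficient magnitudes
comparable across bands.

* **PLSR** — univariate NIPALS partial least squares. The latent-variable
  count is chosen by deterministic 5-fold cross-validation (interleaved
  folds, no randomness), minimizing CV RMSE; ties go to the smaller count.
* **iPLS / SiPLS / BiPLS** — the spectrum is split into equidistant
  contiguous intervals (sizes differing by at most one band). iPLS keeps the
  single interval with the lowest calibration RMSEC; SiPLS exhaustively
  searches interval combinations of a fixed size; BiPLS repeatedly drops the
  interval whose omission lowers RMSEC most, stopping when no drop improves.
  The latent count inside each candidate is cross-validated and capped by
  the interval width. Ties break toward the lowest interval index. Note the
  selected subset's RMSEC equals the minimum over the searched family — but
  is *not* guaranteed to beat the full spectrum, and the package does not
  pretend otherwise.
* **LS-SVM** — least-squares support vector regression with an RBF kernel,
  solved exactly through the dual linear system (block elimination through
  $H = K + I/\gamma$). Grid mode searches 20 log-spaced points per parameter
  over $(10^{-3}, 10^{3}]$ for both $\gamma$ and $\sigma^2$ by the same
  deterministic CV, using one eigendecomposition of $K$ per (fold,
  $\sigma^2$) so every $\gamma$ costs only $O(n^2)$. Cross-validated rather
  than train-set selection was chosen because train-set RMSE is minimized by
  unbounded $\gamma$ by construction.
* **BP-ANN** — one sigmoid hidden layer (10 units), linear output, trained
  full-batch by backpropagation with momentum: at most 1000 epochs, MSE goal
  $10^{-5}$, learning rate and momentum factor 0.01. Initialization is
  seeded and the global RNG stream is restored afterwards, so pipeline runs
  are reproducible end to end. The hidden transfer function and
  initialization scheme are free choices (documented here): weights start
  uniform, hidden weights scaled by fan-in, output weights somewhat larger
  so gradient flow is adequate under the fixed learning rate.

## Metrics and ranking

RMSEC uses the $N - 1 - R$ denominator, with $R$ the number of model
factors: the latent-variable count for the PLS family, and by package
convention 2 effective hyperparameters for LS-SVM and 1 for BP-ANN (the
convention is only used inside this denominator). RMSEP is the plain root
mean square. Metrics are reported on the standardized-target scale, which is
what makes RMSEP values of ~0.05–0.7 commensurate across indicators whose
raw scales differ by three orders of magnitude.

$r_c$ and $r_p$ are the squared Pearson correlation between predicted and
measured values, bounded in $[0, 1]$. A residual-ratio variant
(`mode = "printed"` in `r_coefficient()`) is retained for transparency; as a
coefficient of determination it is degenerate — it approaches 0, not 1, for
a perfect model — so it is not the default.

The calibration/prediction split is random 75/25 under a seed (the split
protocol is otherwise a free choice; Kennard–Stone is available when a
deterministic, spread-covering calibration set is preferred). Per (region,
indicator) cell the model with the highest $r_p$ is retained; ties break by
lower RMSEP, then by a fixed model-kind order.

Wavelength selection uses the regression-coefficient (RC) method: the
$\beta$ vector of a full-spectrum PLSR on standardized variables scores
every band, and either the $k$ largest $|\beta|$ bands (`top_k`) or the
local peaks/valleys of the profile exceeding a fraction of $\max|\beta|$
(`peak_threshold`, default 0.1) are kept. The literature this follows
reports only the resulting counts (tens of bands out of hundreds), not the
rule, so the threshold is exposed; 0.1 reproduces counts of the same order.
Inside the pipeline the RC profile is computed on calibration samples only,
keeping the prediction set untouched by selection.

## The synthetic generator

The generator is the package's stand-in for the unavailable study data and
defines the conditions under which the workflow is validated:

* **Region baselines.** Smooth piecewise-cubic curves with zero slope at
  their control points, encoding the reported spectral shape: a global
  reflectance trough at 430 nm in every region; for gluteal, pectoral and
  abdominal skin a rise to a flat 600–780 nm plateau, a fall to a local
  minimum near 970 nm (water absorption), then a rise; for dorsal skin a
  monotone rise from 430 nm to 1000 nm; mean reflectance ordered
  gluteal > pectoral > abdominal > dorsal.
* **Latent chemistry.** Four latent components drive both spectra and
  texture: Gaussian loading bumps near 500, 780 and 980 nm (absorption
  features discussed for carp skin) plus one broad linear slope component.
  Scores are standard normal per sample (optionally bimodal in the first
  component, giving the two-cluster indicator-PCA structure reported for
  real fish).
* **Texture indicators.** A fixed 8 × 4 mixing matrix maps scores to the
  eight indicators; every indicator loads on at least one component. A
  `nonlinearity` knob (default 0) adds a quadratic term in the first score
  to springiness, resilience and brittleness — the indicators reported
  hardest to predict — so kernel and neural models can outperform PLSR in
  that regime. An indicator's *active bands* (what RC selection should
  recover) are where its mixing-weighted spectral signature exceeds half its
  maximum.
* **Noise.** I.i.d. Gaussian band noise (default sd 0.5 %R) and indicator
  noise (default sd 0.05 on the standardized scale). No quantitative SNR is
  published for such data, so these are free parameters chosen to put
  full-spectrum PLSR in the high-accuracy regime reported for skin-HSI
  texture calibration ($r_p$ ≈ 0.92–0.98); they are documented, not fitted. Pixel noise is spatially independent — real
  instrument noise is not, and the generator makes no attempt at skin
  optics, scale-removal artifacts, or instrument response. Passing tests
  therefore demonstrate correctness of the chemometric machinery under the
  stated statistical structure, not performance on real carp.
* **Cubes.** For visualization tests, latent scores vary across pixels as a
  Gaussian-blurred random field; per-pixel ground-truth indicator rasters
  come from the same mixing map, and a raw-intensity variant is produced by
  inverting the calibration equation.

## Numerical choices and degenerate inputs

* Constant targets, zero-variance predictions, empty RC selections, ROI
  windows outside the raster, references with $W \le D$, and interval counts
  outside $[1, n_{bands}]$ are all hard errors with specific messages.
* NIPALS stops early if the residual weight norm underflows ($10^{-12}$);
  cross-validation then scores the truncated component path.
* The LS-SVM dual solve retries once with a $10^{-10}$ diagonal jitter on a
  singular system, then errors.
* The linear predictor is evaluated row-wise (`rowSums`), so a prediction is
  bitwise identical whether a spectrum is predicted alone or inside a batch
  — this is what makes pixel-wise maps exactly equal a per-pixel loop.
* Ties everywhere break deterministically (lowest index / smallest
  parameter), and every stage seed is derived from one global seed, so a
  pipeline run is byte-reproducible including the neural network.

## Problem sizes used in validation

The package's own validation exercises the pipeline at 300 samples × 600
bands for the headline end-to-end checks (all six models, eight indicators,
one region), 50-replicate batteries at 80 × 100 for the interval-search and
RC-recovery properties, and smaller designs for exact-identity oracles
(ordinary least squares, dense KKT solves, per-window polynomial fits).
These sizes were chosen to make sampling variability negligible relative to
the tested margins while keeping the whole suite quick on a laptop.

## Known limitations

* ROI placement is manual; there is no fish segmentation.
* No scatter correction (SNV/MSC) or derivative preprocessing — the
  workflow under study used SG smoothing only.
* One response at a time (no PLS2); no SPA/CARS/UVE/GA selection methods.
* The Spearman significance flags are uncorrected raw p-values at
  α = 0.05, reported as counts, matching how such matrices are usually
  summarized in this literature.
* Real-data accuracy claims cannot be validated from this package alone;
  the synthetic conditions state what *is* validated.
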