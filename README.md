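# chlorospec

Leaf chlorophyll estimation from proximal hyperspectral reflectance.

`chlorospec` implements a complete, reproducible workflow for estimating
maize leaf chlorophyll content (chlorophyll a+b, µg/g fresh weight) from
400–1000 nm leaf reflectance spectra, for plant-phenotyping and
precision-agriculture researchers who want to benchmark spectral indices
and regression models on this problem without access to a field campaign.

## What it does

**Reference chemistry.** Total chlorophyll from spectrophotometer
absorbances of an 80% acetone extract (Arnon relation):

    Chl(a+b) [µg/g FW] = (20.2·A644 + 8.02·A663) · V / w

with extract volume V (ml) and fresh weight w (g).

**Synthetic study data.** Field spectra with per-leaf chlorophyll labels
are rarely deposited, so the package ships a seeded generator that
emulates the statistical structure such campaigns show: a left-skewed
chlorophyll distribution (mean 2479.8, SD 632.5 µg/g, truncated to
321.1–3713.1 µg/g), green-region reflectance of 20–31% for
high-chlorophyll leaves and 43–50% for low-chlorophyll leaves, a
logistic red edge whose inflection shifts to longer wavelengths with
chlorophyll, carotenoid co-variation and measurement noise.

**Spectral indices.** Eleven indices computed from interpolated bands:
NDVI, red edge position (REP, the 700 + 40·((ρ670+ρ780)/2 − ρ700)/(ρ740 −
ρ700) interpolation), NDVI705, mSR705, mNDVI705, PRI, MCARI, VREI2, and
three chlorophyll indices built on the PCA/SD-selected 516, 551 and
763 nm bands:

    CHLI1 = (ρ551 + ρ763) / (ρ763 − ρ551)
    CHLI2 = (ρ763 − ρ516) / ρ551
    CHLI3 = (ρ516 + ρ551) / ρ763

**Wavelength and feature screening.** PCA with Kaiser-normalized Varimax
rotation plus per-wavelength relative-SD profiles to locate
pigment-sensitive bands; variance inflation factors (VIF = 1/(1−R²ⱼ),
flagged above 5) and tolerances for multicollinearity; and a
minimum-redundancy maximum-relevance (MRMR) ranker built from
discretized mutual information, with a G-test guard that assigns
importance 0 to features statistically indistinguishable from noise.

**Models and evaluation.** Six regression families — Huber robust linear
(IRLS), stepwise linear with pairwise interactions (partial-F entry
p < 0.05 / removal p > 0.10), quadratic-kernel and fine-Gaussian ε-SVR
(kernel scale 0.83), exact Gaussian process regression with a constant
mean and isotropic Matérn 5/2 kernel optimized by marginal likelihood,
and a 3×20-unit ReLU network — evaluated with R², RMSE, MAE, mean bias
deviation and mean squared prediction error over an every-third-record
split (for index calibration) or a seeded random 2:1 split (for the
models).

## Worked example

```r
library(chlorospec)

# one noise-free synthetic leaf at 2500 µg/g chlorophyll
sp <- simulate_spectrum(2500, 0.35, generator_config(noise_sd = 0))
compute_index(sp, "CHLI1")   # 2.234559
red_edge_position(sp)        # 714.1132 nm

# the full pipeline on the default 540-sample synthetic study
report <- run_pipeline(list(seed = 42))
print(report)
```

prints

```
chlorospec run_report (seed 42): 360 training / 180 validation samples
features: CHLI3, mSR705, MCARI, mNDVI705, VREI2, CHLI1, NDVI705, CHLI2, NDVI, REP
  robust_linear      validation R2 0.988  RMSE 64.0  MAE 49.5
  stepwise_linear    validation R2 0.988  RMSE 63.3  MAE 48.4
  svm_quadratic      validation R2 0.987  RMSE 65.8  MAE 50.4
  svm_fine_gaussian  validation R2 0.957  RMSE 120.7  MAE 78.0
  gpr_matern52       validation R2 0.988  RMSE 63.2  MAE 48.6
  trilayer_nn        validation R2 0.978  RMSE 86.0  MAE 65.2
```

The reported numbers are validation-stage statistics in µg/g (RMSE, MAE)
and dimensionless R²: each model was trained on the 360-sample training
part and scored on the 180 held-out samples. PRI is absent from the
feature list because the MRMR ranker assigned it zero importance on this
dataset. On the clean synthetic data all families do well; the
Matérn 5/2 GP is consistently at the top, the fine-Gaussian SVR and the
network trail it. Absolute values depend on the generator's noise level
and are not comparable to field campaigns.

A thin command-line front end with `simulate`, `indices`, `select`,
`rank`, `collinearity` and `run` subcommands lives at
`inst/cli/chlorospec.R`.

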