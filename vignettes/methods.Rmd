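---
title: "Methods: chlorophyll estimation from leaf reflectance in chlorospec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chlorophyll estimation from leaf reflectance in chlorospec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chlorospec` estimates maize leaf chlorophyll (a+b, µg/g fresh weight)
from 400–1000 nm proximal reflectance spectra. This vignette documents
the models and procedures, the assumptions behind the synthetic data
generator, the tunable parameters and their defaults, and the numerical
and design choices a maintainer should know about.

## The estimation problem

A field campaign of this kind yields, per leaf, a reflectance spectrum
(fractions in [0, 1] on a fine nm grid) and a wet-chemistry chlorophyll
label obtained spectrophotometrically from an acetone extract via the
Arnon relation, `(20.2·A644 + 8.02·A663)·V/w`. The analysis pipeline
compresses each spectrum into a small set of band-ratio indices, screens
and ranks those indices, and regresses chlorophyll on them. The package
implements each stage behind an explicit interface so that every stage
is testable in isolation and the whole chain is reproducible from one
seed.

## The synthetic data generator

Labelled field spectra for this problem are generally not deposited, so
the generator stands in for the study data. It is first-class, tested
code, not a fixture. What it emulates:

* **Chlorophyll distribution.** A skew-normal moment-matched to mean
  2479.8 µg/g, SD 632.5 µg/g and skewness −1, truncated by rejection to
  [321.1, 3713.1] µg/g. The skew-normal family attains |skewness| only
  up to ≈ 0.9953, so the shape parameter is clamped at the attainable
  boundary; the sampled skewness is then slightly less extreme than the
  nominal target, which we accept as the closest distribution in the
  family. The truncation bounds are the full-set descriptive extremes;
  narrower subranges reported for individual seasons can be obtained by
  configuring `chl_bounds`.
* **Spectral shape.** A pseudo-Beer–Lambert construction: a smooth NIR
  plateau (0.80 minus a water feature at 960 nm), a visible level set by
  a green shoulder `0.17 + 0.42·exp(−chl/2200)` minus Gaussian pigment
  absorption bands (chlorophyll at 430 and 670 nm, carotenoid at
  470 nm), and a logistic red edge with inflection
  `698 + 24·(1 − exp(−chl/1500))` nm and 7 nm width. The constants were
  calibrated once so that the green-window (520–580 nm) mean reflectance
  is 20–31% at 3000 µg/g and 43–50% at 800 µg/g, the red-edge inflection
  rises monotonically over the label range, and the per-wavelength
  relative SD of a mixed-chlorophyll group peaks at the 670 nm
  absorption — the qualitative features the downstream index definitions
  rely on. This is deliberately *not* a radiative-transfer model
  (PROSPECT/SAIL): the pipeline consumes spectra only through band
  ratios, so feature geometry matters and leaf optics physics does not.
* **Carotenoid co-variation.** A latent Gaussian correlated 0.6 with
  chlorophyll, mapped into a relative level in [0.2, 0.5] that scales
  the 470 nm absorption depth.
* **Noise.** Additive white per-band noise at `noise_sd` (default 0.005
  reflectance fraction) plus a smooth low-frequency component (random
  sinusoids with 80–400 nm periods) at the same SD, then clipping to
  [0, 1].

What it does **not** emulate: instrument line-shape and stray light,
specular/structural leaf effects, canopy or soil background, water- and
nitrogen-status covariates, and between-season drift. Tests passing on
this generator therefore demonstrate the pipeline's correctness and its
qualitative behaviour (index orderings, robustness contracts), not field
accuracy; absolute R²/RMSE on synthetic data are optimistic relative to
real campaigns.

One subtlety worth recording: the in-situ PRI computed from generated
spectra is *not* exactly independent of chlorophyll even though its two
bands (531, 570 nm) carry no chlorophyll signal — its denominator tracks
the green level, so the index noise is heteroscedastic in chlorophyll,
a weak dependence that mutual information legitimately detects. Tests
that need a feature independent of the target by construction pair the
PRI column from a second, independently seeded generation.

## Indices

The eleven-index catalog (NDVI, REP, NDVI705, mSR705, mNDVI705, PRI,
MCARI, VREI2, CHLI1–3) evaluates bands by linear interpolation on the
grid. Decisions taken where the definitions were open:

* NDVI bands are not standardized in this context; the default NIR/red
  pair is 780/670 nm, consistent with the four REP bands, and both are
  configurable.
* `mSR705` is implemented with the plus denominator `(ρ705 + ρ445)` and
  `VREI2` as `(ρ757 − ρ720)/(ρ757 + ρ720)`, the forms used to derive
  the feature tables here; `index_catalog(literature_variants = TRUE)`
  substitutes the Sims–Gamon mSR705 (minus denominator) and the
  Vogelmann VREI2 band set for users who want the literature forms.
* Reflectance may enter as fraction or percent: every catalog index is
  scale-invariant except MCARI, which scales linearly, so the choice
  only affects MCARI's magnitude (fractions are used throughout).
* Zero denominators raise a classed error carrying the index name; the
  feature-table assembler either drops the affected row with a warning
  (default) or fails fast.

## Wavelength selection

Reflectance is z-scored per wavelength and decomposed by PCA on the
correlation scale; components are retained by the Kaiser eigenvalue > 1
rule by default (`n_components` forces a count, e.g. five). Loadings
(eigenvector × singular value) are rotated by Kaiser-normalized Varimax.
The rotation is an in-package pairwise-Jacobi implementation (closed-form
angle per column pair, tolerance 1e-6, at most 500 sweeps): the
fixed-point iteration in `stats::varimax` can stall far from the optimum
when leading eigenvalues are nearly equal — exactly the regime of
two-pigment spectra — which we verified against a brute-force rotation
search on a two-block fixture. Component signs are canonicalized (the
largest-magnitude loading is positive) so results do not depend on
sample order. `pick_wavelengths` returns the largest local maxima and
smallest local minima of the first rotated component, ties broken toward
shorter wavelengths; the relative-SD profile is attached for inspection
rather than folded into the selection rule, since no principled
combination rule is available.

## Collinearity and MRMR

VIF for feature j is `1/(1 − R²ⱼ)` from regressing j on the remaining
features (with intercept); tolerance is its reciprocal; flags at VIF > 5
or tolerance < 0.1. Perfect collinearity reports an infinite VIF with a
flag instead of failing.

The MRMR ranker is built from first principles:

* **Discretization** (default 10 equal-frequency bins) uses rank-based
  labels, so bin sizes differ by at most one for distinct values, tied
  values always share a bin, and labels are invariant to row
  permutation. Equal-width binning is available.
* **Mutual information** is the plug-in estimate from the joint
  contingency table in bits. Inside the ranker the Miller–Madow
  bias correction is applied and the estimate clamped at zero; with
  10×10 tables the raw plug-in bias (~(k−1)²/(2N ln 2)) would otherwise
  dominate weak signals.
* **Relevance zeroing.** A plug-in MI estimate is strictly positive
  almost surely, so "no relevance" must be a statistical decision, not a
  numeric threshold: relevance is set to 0 when the G-test of
  independence (G = 2N ln 2 · MI_raw, df = (kx−1)(ky−1)) is not
  significant at α = 0.05. Zero-relevance features receive importance 0
  and rank last.
* **Greedy scoring** follows the quotient (MIQ) scheme — relevance over
  mean MI with the selected set, denominator floored at 1e-12 bits —
  with the difference (MID) scheme behind `variant = "difference"`. Ties
  break toward the earlier column for determinism. The first selection's
  importance equals its relevance.

## Model families

All fitters standardize features internally (z-score, parameters stored
with the model) and are deterministic given their seed.

* **Huber robust linear** minimizes the summed Huber loss
  (`r²/2` below δ, `δ(|r| − δ/2)` above) by IRLS with weights
  `min(1, δ/|r|)`. δ defaults to 1.345 × a MAD residual scale
  re-estimated each iteration (~95% Gaussian efficiency); a fixed δ can
  be supplied. Convergence is a max coefficient change below 1e-8.
* **Stepwise linear** steps over main effects and pairwise interactions
  by partial-F p-values (enter < 0.05, remove > 0.10, at most 1000
  steps, bidirectional by default starting from all linear terms).
  Interactions are only eligible while both parents are present, and
  parents of a retained interaction are never dropped. `p_enter <
  p_remove` is enforced to rule out cycling.
* **ε-SVR** (quadratic `(1 + x'z)²` or Gaussian kernel) uses the
  "automatic" convention: box constraint = IQR(y)/1.349 (a robust scale
  estimate of the response), ε = box/10. The fine-Gaussian preset fixes
  the kernel scale at 0.83 *in the kernel form* `exp(−d²/(2s²))`. A tube
  wider than the response spread leaves no support vectors; the fitter
  then returns the flat mean predictor, which is the ε-SVR solution in
  that degenerate regime. Backed by `e1071::svm`.
* **Matérn 5/2 GPR** is exact GP regression with a constant mean
  estimated by generalized least squares under the kernel
  `σ(1 + √5 r/l + 5r²/(3l²))·exp(−√5 r/l)` (σ is the kernel's value at
  r = 0, per the convention used here), isotropic in the standardized
  feature space, plus Gaussian noise variance. Hyper-parameters are
  optimized on the log scale by L-BFGS-B from a data-driven start
  (length scale at the median pairwise distance) with 3 seeded restarts
  and a jitter ladder 1e-12 → 1e-6 on Cholesky failure. Fixing
  `noise = 0` gives jitter-only interpolation; far from the data the
  posterior mean reverts to the fitted constant.
* **Trilayer network**: three hidden layers of 20 ReLU units, linear
  output, L2 penalty λ = 0 by default, trained full-batch by L-BFGS-B
  with analytic backpropagation gradients and He-style seeded
  initialization. Full-batch quasi-Newton training honors the
  deterministic iteration-limit contract (default 1000) that stochastic
  minibatching could not.

## Evaluation

Five statistics per model and stage: R² (1 − SSE/SST), RMSE, MAE, MBD
(mean of observed minus predicted, positive = under-prediction) and MSPE
(mean squared error). MSPE = RMSE² by construction; both are reported
because downstream consumers conventionally tabulate both. When the
observed vector has zero variance R² is undefined and returned as NA
with a warning, the other four still computed.

Two split schemes: the ordered every-third rule (positions 3, 6, 9, …
validate; 540 records give 360/180) used for per-index linear
calibrations, and a seeded random split (default validation fraction
1/3) used for the model families. `run_pipeline` defaults to the random
2:1 split for models and the every-third split for index calibration,
both overridable, and threads one seed through generation, splitting and
every stochastic fitter.

## Problem sizes and limitations

The default study configuration is 540 samples on the 0.6 nm grid
(1001 bands); the full pipeline runs in seconds on one core, and the
test suite uses a coarser 3 nm grid where spectral resolution is not the
property under test. Known limitations: the generator's realism bounds
what the tests can certify (see above); the MRMR zero rule depends on
the discretization and α (both exposed); stepwise inference p-values are
nominal, not selection-adjusted; the GP is exact (O(n³)) and intended
for n up to a few thousand; and the quadratic-kernel SVR with automatic
ε trades a small amount of training fit for sparsity by design.
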