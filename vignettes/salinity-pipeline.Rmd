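---
title: "Estimating root-zone soil salinity from canopy spectra: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating root-zone soil salinity from canopy spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salspec)
```

## The problem

Once a crop canopy closes, the soil underneath cannot be observed directly,
so soil salinity in the root zone (here, the electrical conductivity of a
1:5 soil–water extract, EC~1:5~, in dS m^-1^, averaged over the 0–20, 0–40
and 0–60 cm layers, labeled S1/S2/S3) has to be inferred from what the
*plants* reveal. Two channels carry that information:

1. **Canopy reflectance** (350–2500 nm). Salt stress changes pigment
   content, canopy water status and structure, which raises visible
   reflectance and lowers long-wave-infrared reflectance.
2. **Growth parameters.** Salinity suppresses plant height (H, cm),
   aboveground biomass (AGB, g plant^-1^) and shoot water content (SWC,
   fraction), most strongly early in the season.

`salspec` implements the full chain: spectral preprocessing, wavelength
selection, partial least squares regression (PLSR) with growth-parameter
covariates, and evaluation — together with a synthetic generator that
reproduces the statistical structure of a cotton amelioration field trial
(4 treatments × 5 stages × 7 replicates = 140 records) so the chain can be
exercised and tested end to end without field data.

## Preprocessing

Raw reflectance is trimmed (350–399, 2401–2500 nm instrument-noise margins;
1361–1489 and 1811–1959 nm water-vapour bands), leaving 1723 bands in three
contiguous segments; a Savitzky–Golay filter (13-point window, order-2
polynomial — the window size follows the emulated acquisition protocol, the
order is the conventional default and is configurable) smooths each segment
independently, and the first-derivative reflectance (FDR, nm^-1^) is the
Savitzky–Golay derivative with the same window. Per-segment processing
guarantees the filter never bridges a trimmed gap; segment edges use the
one-sided polynomial fit, which keeps the filter exact on polynomials up to
the chosen order everywhere (this exactness is property-tested). The
derivative is applied to the smoothed spectrum by default; derivative of
the raw spectrum is available via `derivative_of = "raw"`.

## Wavelength selection

All three selectors score candidate wavelength subsets by cross-validated
RMSE (RMSE~CV~) of a PLS1 model.

* **VIP** computes variable-importance-in-projection scores from one PLS
  fit and keeps bands with VIP > 1. The implementation uses the standard
  form whose scores satisfy the identity `sum(VIP^2) = K`; scores above 1
  therefore mark bands carrying more than an average share of the explained
  response variance.
* **CARS** runs `n_runs = 50` Monte-Carlo iterations, each fitting a PLS
  model on a random 80% of the samples and re-drawing the retained set
  (without replacement, proportional to the weights) under an exponentially
  decaying retention schedule from all bands down to exactly two. Weights
  are **standardized** coefficients, |b~j~|·sd(x~j~): with mean-centered
  spectra a raw coefficient scales like 1/sd, which would hand the
  competition to near-constant noise bands.
* **Random frog** is an MCMC-style subset search: normal proposals on the
  subset size, competitive shrinking/growth by standardized coefficient
  (growth draws an `omega = 3`-fold candidate pool and keeps the best), and
  acceptance of worse subsets with probability
  `eta · RMSECV_old / RMSECV_new`. Selection probabilities are inclusion
  frequencies after burn-in; the returned subset is the best over
  `n_restarts` chains.

### Guarding the selectors against their own criterion

A subtlety that shaped the implementation: the iterative selectors evaluate
thousands of candidate subsets against RMSE~CV~ computed on the same
calibration samples that drive the retention, so the search can *overfit
its own selection criterion* — it finds subsets whose cross-validated error
is far below anything honest while their validation error is worse than
the full spectrum's. Two design choices contain this:

* one fold partition is shared by all runs of a search, so the final
  arg-min cannot exploit partition luck, and
* the models used *inside* the search (weighting fits and subset scoring)
  are capped at `score_lv = 2` latent variables. Restricting the capacity
  of the internal models keeps the criterion honest; the final calibration
  model is refit afterwards with its own cross-validated component count
  (up to 10).

The cap is configurable; raising it reproduces the pathology and is an
instructive experiment.

## Calibration models

PLS1 by NIPALS, mean-centering the spectral block only (bands share units).
The component count is chosen by 5-fold RMSE~CV~ with ties going to the
smaller count. The stage-stratified split draws 20 of 28 records per growth
stage into calibration (100/40 overall), and *all* statistics — centering,
scaling, wavelength selection, component choice — are computed on the
calibration partition only (asserted by a permutation test).

Growth covariates enter as ordinary columns, autoscaled and then weighted
to **block parity**: the covariate block's total variance is set equal to
the spectral block's. Plain autoscaling (each covariate sd 1) lets two
covariates dominate 1723 derivative bands whose sds are of order 10^-3^ —
the first components then ignore the spectra and the combined model
underperforms the spectra-only model; pure per-band comparability without
rebalancing buries the covariates instead. Block parity lets both channels
compete on information content. Negative salinity predictions are reported
as-is (metric fidelity) and counted in the evaluation report.

`run_experiment_grid()` crosses {R, FDR} × {full, VIP, CARS, RFA} ×
covariate sets × {S1, S2, S3} (96 cells at the defaults) and reports, per
cell, the selected-feature count, LV, R²~C~, RMSE~C~, R²~V~, RMSE~V~ and
Lin's concordance correlation coefficient (LCCC).

## Evaluation metrics

R² = 1 − SSE/SST (about the mean of the measured values), RMSE in dS m^-1^,
and Lin's CCC in its standard form
2ρσ~y~σ~ŷ~ / (σ~y~² + σ~ŷ~² + (μ~y~ − μ~ŷ~)²) with population (1/n)
variances. Note the *minus* sign in the mean-difference term: a printed
variant of this formula with a plus sign circulates, but it violates
LCCC(y, y) = 1 and is not Lin's coefficient. Reported percents are rounded
half-up to two decimals.

## The synthetic generator: what it emulates

`synthetic_config()` defaults *are* the study conditions the package is
tested under:

* **Salinity surface.** Per-layer EC means are decomposed from the bundled
  treatment × stage table of layer averages (`field_ec_table()`), so the
  treatment ordering T2 < T1 < T3 < T4 and the mid-season dip at 124 days
  after sowing hold by construction; within-cell noise (sd 0.35 dS m^-1^,
  the scale of the tabulated replicate sds) has a shared profile component
  so layers are correlated within a sample.
* **Growth.** Height and biomass follow logistic curves in DAS (biomass
  peaking earlier under high salinity), SWC declines linearly; each is
  suppressed linearly in the record's S2 with a stage-attenuation schedule
  (1, 0.8, 0.6, 0.45, 0.35), so growth–salinity correlations are negative
  and weaken over the season. Replicate noise scales with the stage
  baseline (constant coefficient of variation), which makes the attenuation
  schedule — not the phenology — govern the correlation strength.
* **Spectra.** A hand-parameterized vegetation baseline (green peak, red
  edge, NIR plateau, water troughs; not a radiative-transfer model) plus a
  salinity response driven by a latent canopy-expressed salinity
  `s = S2 + N(0, latent_sd)`: visible reflectance up, LWIR down, and six
  narrow informative bands (577, 712, 980, 1180, 1640, 2190 nm). Nuisances:
  29 fixed-shape canopy-structure modes with random per-sample amplitudes,
  multiplicative gain and additive offset drift, and smooth plus white
  instrument noise.

Three defaults deserve explanation, because the emulated study reports no
quantitative effect sizes and they were chosen (once) so the study's
qualitative findings emerge as *consequences of structure*, not accidents:

* `latent_sd = 0.5` dS m^-1^ is the mismatch between root-zone salinity
  and what the canopy actually expresses. It caps spectra-only validation
  R² near 0.6 — the regime the emulated study operates in — and is the
  reason growth covariates genuinely help: they observe the soil through
  an independent noisy channel.
* The **canopy-structure modes** (amplitude sd 0.14 reflectance units,
  comparable to real between-canopy curve differences) are few in number
  but high in variance, and their spectral positions avoid the informative
  bands. This is what makes wavelength selection pay: full-spectrum PLS
  must spend components rejecting high-variance irrelevant directions
  estimated from only 100 calibration samples, while a selected subset
  sidesteps them entirely. With a low-dimensional or low-variance nuisance
  structure, full-spectrum PLS is near-optimal and *no* selector can beat
  it — a useful negative result to keep in mind when reading wavelength-
  selection benchmarks.
* `gain_sd = 0.05` and `offset_sd = 0.02` give the derivative its
  advantage: both drifts contaminate raw-reflectance correlations but are
  annihilated (offset) or strongly attenuated (gain) by differentiation.

`generative_ceiling()` reports the OLS R² of a layer target on the latent
salinity plus the H and SWC covariates — the accuracy an ideal estimator
could approach. On the defaults the key model family, averaged over ten
datasets, comes out as: full-spectrum FDR ≈ 0.53 < FDR + CARS ≈ 0.59 <
FDR + CARS + H + SWC ≈ 0.66–0.72, within 0.1 of the ceiling (≈ 0.74).
These numbers are recomputed, not quoted, by the test suite and
`scripts/acceptance.R`.

### What passing tests do and do not show

The generator emulates second-order structure (means, correlations,
orderings), not canopy physics. Passing tests show the pipeline recovers
what was put in under realistic noise; they do not show the effect *sizes*
match any real field. Known divergences, deliberate:

* The derivative's improvement of the best band–salinity correlation is a
  few percent here, far smaller than in the emulated study, because the
  informative windows are cleaner than real spectra.
* Treatment-mean Vis/LWIR orderings are asserted on the salinity-response
  component (nuisances off, 21 replicates). At 7 replicates under full
  canopy variation the 0.2 dS m^-1^ contrast between the two least saline
  treatments is below sampling error — as the emulated trial itself
  observed, curves of mildly differing treatments nearly coincide.
* Likewise the 124-DAS minimum of the salinity trajectory is a property of
  the mean surface; a 7-replicate draw cannot resolve a 0.09 dS m^-1^ dip.

## Numerical and degenerate-input choices

* Fold assignment, Monte-Carlo draws and chain proposals are all seeded;
  one master seed fans out to stages via `derive_seed(seed, tag)`, so any
  stage can be rerun in isolation.
* RMSE~CV~ ties on the component count go to the smaller count; tied
  best subsets go first to the smaller subset, then the earlier run.
* A fold whose response is constant (rank-0 covariance) falls back to the
  centered model, predicting the training mean.
* Constant-response CARS weighting falls back to uniform weights with a
  warning; zero-variance bands are excluded from correlation argmaxes.
* Reflectance above 1 is tolerated to 1.5 with a warning
  (calibration-panel artifacts) and rejected above; generated spectra are
  clipped to [0, 1.2].
* Problem sizes in the test suite (thinned grids, reduced run counts,
  10-seed averages) were chosen to keep the full suite under two minutes
  on one CPU while leaving every assertion at the granularity of the
  scientific claim it checks.

## Limitations

Beyond the generator caveats above: the pipeline is PLS1-only (one target
at a time); selection stability across resampled calibrations is not
quantified (the emulated protocol re-runs the stochastic selectors and
keeps the best subset, which the defaults mirror); and the random frog
defaults (1000 iterations × 100 restarts) reflect the protocol rather than
desk-scale exploration — `grid_control()` uses reduced settings, and the
protocol-faithful values should be restored for production runs where the
cost is acceptable.
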