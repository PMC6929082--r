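---
title: "Methods: benchmarking VIS-SWNIR calibration of pear soluble solids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking VIS-SWNIR calibration of pear soluble solids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Non-contact VIS-SWNIR diffuse reflectance (here: 1024 points on a fixed
432–1147 nm grid) carries information about the soluble solids content (SSC,
°Brix) of thin-peel fruit through weak sugar O–H/C–H overtone bands that sit
on top of a dominating water spectrum and a ripeness-correlated chlorophyll
band near 680 nm. Under packinghouse conditions the signal is further
distorted by fruit size (variable optical path and fruit–probe distance) and
peel temperature (band shift and broadening). Predicting SSC therefore
requires multivariate calibration, and the practical question is which
combination of preprocessing, wavelength selection, regression engine and
validation protocol is trustworthy.

`sscbench` implements that benchmark end to end: a synthetic-data generator
that emulates the statistical structure of a packinghouse-scale pear survey
(the original data are not publicly deposited), the standard preprocessing
grid, a PLS wrapper wavelength selection, four calibration engines with their
optimization schemes, and internal plus external (chronological) validation
with a metric suite including the Prediction Gain.

## The synthetic population

`generate_population()` draws `n_fruits` fruits, two samples each (opposite
equatorial sides). Defaults are the emulated survey's published summary
statistics:

| quantity | default | unit | origin |
|---|---|---|---|
| SSC mean / sd | 13 / 1.725 | °Brix | mean 13; ~95 % of fruit in 9.5–16.4 (±2σ) |
| SSC hard range | 7–19.1 | °Brix | observed extremes |
| side-to-side ΔSSC sd | 0.62 | °Brix | repeated destructive measurements |
| diameter | 43–81, mean 60, sd 7 | mm | observed range/mean |
| peel temperature | 4.7–39 | °C | three regimes: chilled (6 ± 2), ambient (22 ± 3), heated (35 ± 2.5), weights ¼/½/¼ |
| subsets | A–E, equal fifths | – | chronological acquisition blocks |

Distributions are truncated normals: the survey reports means, ranges and a
±2σ interval but no higher-order shape, and the truncated normal is the
simplest family matching those summaries. The sd 7 mm for diameter and the
regime means/sds are the package's own choices within the stated ranges.

Each side's SSC is `fruit SSC ± d/2` with `d ~ N(0, 0.62)`, so the
side-to-side difference has exactly the configured spread. Sides share
temperature, diameter and chlorophyll but have independent spectral noise.

### Spectra

Absorbance is a sum of Gaussian bands on a smooth quadratic baseline:

* chlorophyll at 680 nm, amplitude proportional to a latent chlorophyll
  variable drawn with correlation −0.6 to fruit SSC (riper fruit: more sugar,
  less peel chlorophyll). The correlation is configurable and deliberately
  not deterministic — the chlorophyll–SSC association is a ripeness
  covariance, not a causal link, and models exploiting it should fail on the
  chlorophyll-free range.
* sugar bands at 755, 840, 920, 970 and 1100 nm with amplitudes *per °Brix*,
  so noiseless absorbance at any wavelength is exactly linear in SSC (the
  regression slope equals the band-library amplitudes summed through their
  Gaussians — a property the tests pin).
* fixed water background bands (760, 970, 1135 nm).

Reflectance is `10^(-A)` times a size-dependent multiplicative scatter factor
`1 + 0.004 (diameter − 60)`, clipped to (0, 1]. Spectral noise is additive in
absorbance (sd 0.0015 AU), which is where detector noise is additive after
the log transform; with `noise_sd = 0` the deterministic band model is
reproduced exactly.

Temperature moves all bands: centers shift by 0.2 nm/°C relative to 20 °C and
widths change monotonically by 0.5 %/°C (warmer = broader) while conserving
band area, so peaks flatten as bands broaden — the classic NIR temperature
effect. Each sample additionally receives a small random smooth quadratic
baseline (`baseline_jitter_sd`, default 0.01 AU), emulating the variable
fiber-to-fruit distance and lighting of a non-contact setup. These two
choices matter: without the area-conserving (peak-suppressing) broadening and
the baseline jitter, a linear model can read temperature essentially
noise-free out of the broad water bands, and appending the measured
temperature as an extra feature is informationally redundant. With them, the
appended temperature/size columns measurably reduce RMSEP when the
temperature effect is on and are neutral when it is off — the behaviour the
benchmark is designed to probe.

Band amplitudes and widths were calibrated once, by construction, to two
properties of the emulated instrument: the SSC-driven spectral variance at
the band centers is roughly an order of magnitude above the additive noise
floor, and after the support-vector input scaling all non-SNV spectral
features fall inside [−0.2, 0.2].

### Chronological drift

Subsets D and E (the second harvest season) get a +0.3 °Brix offset applied
to the *reported* SSC after the spectra are simulated — a season-induced
change in the fruit-matrix-to-refractometer mapping, not a change in the
sugar bands. This is deliberate: if the offset also drove the bands it would
be fully visible to the models and external validation would pay no penalty
for crossing seasons. D–E also get a distinct absorbance baseline tilt, and
the second half of subset E oversamples extreme diameters (big and small
fruit), reproducing the reported composition of the final acquisition block.

### Reference noise (`ssc_ref_noise_sd`)

By default the reported SSC is exactly the value encoded in the spectrum.
Setting `ssc_ref_noise_sd > 0` adds refractometer-scale noise to the reported
value only, which creates an irreducible prediction floor: with
`ssc_ref_noise_sd = 0.62` and an otherwise clean linear configuration, every
engine's internal-validation RMSEP converges to ≈ 0.62 °Brix. The acceptance
suite asserts this within 15 % on 600 fruits for all four engines.

### What the generator does *not* emulate

No radiative transfer or photon Monte-Carlo; no raw dark/white-reference
counts (the dark/reference arithmetic is exposed as the utility
`compute_reflectance()` only); no wavelength-dependent detector response; no
non-Gaussian band shapes; no within-season maturity trends beyond the subset
offsets. Consequently the synthetic world is *cleaner* than a real
instrument: desk-scale RMSEP values are optimistic, and passing tests
demonstrate correctness and internal orderings of the pipeline, not
field-level accuracy. The published headline errors of the emulated study
(internal ≈ 0.8, external ≈ 1.1 °Brix on 3300 spectra) are not reproducible
from synthetic data and are not targeted.

## Preprocessing

Pipeline order is fixed: absorbance `log10(1/R)` → optional Savitzky–Golay
derivative (window 51 points, polynomial degree 2, derivative per unit grid
index — the detector pitch is uniform to within 0.7 nm) on the full grid →
trim 75 points per edge (1024 → 874, ≈ 500–1100 nm) → optional restriction to
λ ≥ 730 nm (`noChl`) → optional SNV → optional appended temperature and size
columns. Two conventions are pinned by tests:

* **SNV uses the population (n) denominator** and is computed over spectral
  features only — never over appended covariates — making it idempotent and
  exactly invariant to multiplicative reflectance scaling for absorbance
  variants.
* **The `noChl` restriction precedes SNV**, so the normalization statistics
  come only from retained wavelengths. The alternative (slicing a full-range
  SNV) would let the highly variable chlorophyll region contaminate the
  correction, which is the very effect the chlorophyll-free variants exist to
  avoid. The survey text does not fix this order; it is a package decision.

`scale_for_svm()` applies the engine-specific input scaling: absorbance / 10,
1st derivative × 100, 2nd derivative × 1000; temperature and size centered on
*calibration* means and divided by 100, with the centering constants stored
and reused verbatim for validation samples. SNV variants are unit-scale by
construction whatever the base transform, so they take the absorbance rule
(/10) — applying the derivative multipliers to SNV output would inflate
features to O(300) and defeat the purpose of the scaling.

## Wavelength selection

`wrapper_select()` runs the PLS wrapper: the outer loop sweeps #LV = 1 …
`max_lv` (default 25, the largest component count the full protocol ever
selects); the inner loop removes one spectral feature at a time — the one
with the smallest |PLS regression coefficient| — refits, and records the
5-fold RMSECV of every (#LV, n_removed) cell. The global minimiser yields the
retained mask and the optimal #LV. Conventions:

* folds are a seeded random partition, identical across the whole surface so
  cells are comparable;
* the ranking is recomputed after every removal (full wrapper). A cheaper
  fixed-ranking-per-#LV mode is available (`recompute_ranking = FALSE`) since
  the protocol's wording admits both readings; the full wrapper is the
  default;
* ties: equal |coefficients| remove the lower wavelength index first; equal
  RMSECV minima prefer more features removed, then fewer #LV (parsimony);
* the inner loop stops when the retained spectral features equal #LV (the
  model is saturated); augmented temperature/size columns are always retained
  and never ranked;
* RMSECV is in °Brix on the original response scale regardless of any
  engine-specific input scaling.

The wrapper is verified against brute-force enumeration (with an independent
Krylov-space closed form for the PLS coefficients) on a 12-feature instance.

## Calibration engines

All four engines share one contract: predictions in °Brix, any input scaling
from stored calibration statistics only. A leakage test corrupts validation
responses after the split and asserts all predictions unchanged.

* **PLS** — NIPALS-style PLS1 with X deflation; coefficients are
  reconstructed in the original feature space for every component count,
  which both the wrapper ranking and the fast RMSECV-per-#LV evaluation rely
  on. Component extraction stops early (and the coefficient path saturates)
  if X is exhausted. At full rank PLS equals ordinary least squares to 1e-8,
  and the reported RMSEC is a 10-fold cross-validation RMSE — deliberately
  more conservative than the in-sample residual.
* **MLR** — QR least squares with intercept; refuses `n_samples <=
  n_features` with a typed "MLR not applicable" error (benchmark cells record
  the skip, mirroring the protocol's exclusion of the uniform Small set), and
  surfaces rank deficiency instead of silently dropping columns.
* **SVR (RBF)** — libsvm via `e1071::svm` with the analytic seeding described
  in the README; the k-NN noise estimate uses k = 5 (in-sample predictions,
  self included, with the `n^(1/5)k/(n^(1/5)k − 1)` small-sample correction)
  and ε is floored at 1e-4 so the search interval cannot degenerate in the
  zero-noise limit; γ maximises the variance of off-diagonal RBF kernel
  entries over 25 log-spaced values in 1e-4–1e2, estimated on ≤ 500 random
  row pairs. The randomized refinement runs three coordinate passes in the
  order C → γ → ε (the protocol fixes the scheme but not the order); each
  pass draws 30 uniform candidates from `[0.001 P_th, 3 P_th]` and always
  evaluates the incumbent too, so the final 5-fold CV RMSE (the reported
  RMSEC) can never be worse than the theoretical-parameter model on the same
  folds.
* **MLP** — single hidden layer of ⌈p/3⌉ ReLU units, Adam (lr 1e-3,
  β = 0.9/0.999), minibatches of 16, MSE loss, at most 300 epochs with early
  stopping (patience 10, best weights restored) on an internal 20 % split of
  the calibration set; `n_repeats` networks (10 in the full protocol, 3 at CI
  scale) are trained from seeded initializations and their *predictions*
  averaged (averaging metrics of separate fits is the other reading of the
  protocol; prediction averaging is implemented because it also defines a
  usable predictor). Inputs are standardized and the response standardized to
  mean 0 / sd 1 with stored calibration constants. Min-max normalization of
  the response was tried first and rejected: it leaves the target range ~5×
  smaller than the network's initial output scale, so training spends its
  budget unlearning the random output layer and plateaus far above the
  reference-noise floor. The output layer is therefore also initialized near
  zero (sd 0.05), so the network starts at the calibration mean. A
  non-finite loss restarts the repeat with the next derived seed.

## Validation and metrics

Internal validation shuffles and splits 80/20 **at fruit level**: the two
sides of one pear are near-duplicates, and letting them straddle the
partition inflates internal optimism. `sample_level_splits = TRUE` restores
literal sample-level splitting for fidelity runs. External validation holds
out each chronological subset in turn (calibrate on the other four), no
shuffling; the five rotations are aggregated by arithmetic means with the
population (n = 5) standard deviation of RMSEP as the error bar.

`compute_metrics()` reports RMSEP, R² (headline: squared Pearson correlation
of observed vs predicted; `1 − SSE/SST` is also returned as `r2_1sse`),
`CV% = 100·RMSEP/mean(y_val)`, `SDR = sd(y_val)/RMSEP` (population sd) and
the Prediction Gain `PG = rms(y_val − mean(y_cal))/RMSEP`. PG equals SDR
exactly when the calibration and validation means coincide and exceeds it
when a model bridges differing means, which is why it is the fairer statistic
for external validation. A zero RMSEP makes PG/SDR infinite; the report flags
the row as degenerate and warns rather than failing. EV R² is the mean of
per-rotation R² (not pooled), and is labelled as such.

## Benchmark orchestration

`run_benchmark()` iterates strategies × data types × engines, re-running the
wrapper selection on each calibration partition (so every external rotation
gets its own mask and #LV), fitting all engines on the same masked features,
and recording per-cell metrics, mask sizes, #LV and SVR hyperparameters.
Every seed — data generation, splits, selection folds, randomized search,
network initializations — derives deterministically from `master_seed`, so an
identical configuration reproduces the cells and best tables bit for bit.
Per-cell failures (e.g. MLR on wide data) are recorded with their reason and
the run continues. The uniform "Small" set is the first 150 fruits measured
at ambient temperature (15–28 °C) with mid-range diameters (52–68 mm), in
acquisition order; per the protocol's own admission, no Small-specific tuning
path exists — engines inherit the choices made for the big set.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` run at desk scale as the package's
own CI configuration: populations of 70–600 fruits (one check uses 1650
fruits to pin the ΔSSC spread), spectral grids thinned after full-resolution
preprocessing (`thin_features()`, typically every 10th–50th wavelength),
`max_lv` 3–12, SVR with its full 30 candidates, MLP with 3 repeats. Thinning
happens *after* preprocessing so the Savitzky–Golay window semantics are
untouched. Full-fidelity settings — 1650 fruits, 874 wavelengths, `max_lv =
25`, 10 MLP repeats, the whole 24-recipe grid — use the same code paths and
run in hours rather than minutes.

Numerical conventions not already mentioned: NIPALS stops a component when
the weight norm or score variance falls below 1e-12; truncated normals are
drawn by inverse-CDF (exact, no rejection loop); derived seeds come from a
31-bit rolling hash of the master seed and a stage tag, so they stay valid R
integer seeds.

## Known limitations

* The generator's band model is low-rank and far cleaner than a real
  spectrometer; absolute error levels are not comparable to field studies,
  only orderings and identities are.
* The chlorophyll–SSC correlation magnitude and the band amplitudes are not
  instrument-measured; they are declared, tunable defaults.
* PG/SDR are undefined at zero RMSEP (flagged, not hidden).
* The MLP is a faithful small-scale implementation of the stated training
  rules, not a deep-learning framework; very wide inputs (thousands of
  features) train slowly in pure R.
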