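---
title: "NIRS calibration for grain composition: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NIRS calibration for grain composition: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainspec)
```

`grainspec` builds near-infrared reflectance spectroscopy (NIRS)
prediction models for brown-rice composition traits under one hard
constraint: the models must work on germplasm collections, where trait
values reach far beyond what ordinary market samples cover. This vignette
explains the models and procedures the package implements, the parameters
that matter and their defaults, what the synthetic data generator does and
does not emulate, and the numerical and design choices we made where the
method description left them open.

## The data model

Spectra are apparent absorbance Log(1/R) of flour scanned in diffuse
reflectance on a 400–2490 nm grid at 2 nm steps (1046 points). The grid
is a default, not an invariant: every operator works on any strictly
increasing grid. The `spectra_set` container pairs the absorbance matrix
(samples × wavelengths) with sample ids and an append-only processing
history; the `reference_table` holds laboratory trait values (percent,
dry basis) — protein, total dietary fiber (TDF), starch, amylose, oil —
plus nuisance columns such as moisture and nitrogen (protein is nitrogen
× 5.95, the cereal conversion factor).

## Representative-set selection

Calibrations trained on normally distributed samples learn the middle of
the range and fail at the extremes — exactly the samples a gene bank
cares about. The selection procedure therefore works on spectral
diversity, which is available for all scanned accessions before any wet
chemistry:

1. MSC-normalize all spectra (see below) so scatter differences do not
   masquerade as diversity.
2. Cluster with Ward's minimum-variance criterion on squared Euclidean
   distances (`stats::hclust(method = "ward.D")` on `dist()^2`), cut into
   `k_main` clusters, and re-cluster each into up to `k_sub` sub-clusters.
3. From every cluster and sub-cluster take the member nearest the
   centroid (center) and the `n_boundary` members farthest from it
   (extreme boundary). Clusters with at most `small_cluster_max = 4`
   members contribute everything.

Defaults are `k_main = 6`, `k_sub = 5`, `n_boundary = 2`. Center-and-
boundary picks alone yield on the order of 100 selections from 500
samples, so when a `target` size is requested (180 by default in
`run_study()`, the usual reference-set size for a 500-accession scan
set), the selection is topped up round-robin across sub-clusters with the
next most-extreme members until the target is met. This keeps the
boundary-heavy character of the selection while making the set size a
config input rather than an emergent property. Determinism: `hclust` and
`cutree` are deterministic for a fixed input order; remaining ties break
by sample id.

## The 2:1 split

For each trait the reference set is sorted ascending by the laboratory
value (ties broken by sample id) and ranks 2, 5, 8, … — every third
sample counting from the second — are held out as validation,
`floor(n/3)` samples in all. Starting at rank 2 rather than rank 1 or 3
is deliberate: rank 1 and rank n can then never fall in validation, so
the global minimum and maximum stay in calibration and the validation
range is always contained in the calibration range. A model is thereby
never asked to extrapolate during validation, while both sets still span
the diversity.

## Preprocessing

**MSC.** Each spectrum `x` is regressed on a reference spectrum `m` (the
calibration-set mean): `x = a + b·m + e`; the corrected spectrum is
`(x − a)/b`. The fitted `m` is stored in the model and re-used unchanged
on validation spectra — recomputing it on new data would leak information
across the split. A slope `|b| < 1e-12` is an error naming the sample.

**SNV-DT.** Per spectrum: subtract the mean, divide by the SD (standard
normal variate), then fit and subtract a second-degree polynomial of
absorbance on wavelength (detrend). Affine and quadratic baselines are
annihilated exactly; the output is orthogonal to `{1, λ, λ²}` to machine
precision. The polynomial basis is condition-scaled before the QR
projection. A constant spectrum (SD < 1e-12) is an error.

**Math treatments.** The four-integer code `d,g,s1,s2` means: boxcar
smooth of width `s1` points, then `d` successive centered gap derivatives
`y[i] = x[i + g/2] − x[i − g/2]` with gap `g` points, then a smooth of
width `s2`. Conventions we fixed (the code notation itself does not
define the operator):

* The derivative is the centered Norris-style point difference. Whether
  the original instrument software differences gap-block means instead of
  points is not recoverable from its documentation; the point-difference
  form is implemented and tested against a literal brute-force oracle.
* Odd gaps with `d ≥ 1` are rejected, not rounded — the centered
  difference needs `g/2` points on each side.
* Smoothing is a centered moving average; even widths use the left-center
  window `i − w/2 … i + w/2 − 1`.
* Edges are trimmed, never padded: padding fabricates data. The output
  grid records the trim, and a treatment that would empty the grid errors
  with the required minimum length.
* Operator order is scatter correction first, then the treatment.

All preprocessing operators are row-local (apart from MSC's stored mean),
so they commute with sample permutation — a property the tests exercise.

## Regression

All fitters center X and y and do not variance-scale (the spectroscopy
convention); MPLS applies its own scaling. All return nested coefficient
paths, so k-component predictions come from one fit.

**PLS1 (NIPALS).** Weight `w ∝ Eᵀf`, score `t = Ew`, loadings
`p = Eᵀt/tᵀt`, `q = fᵀt/tᵀt`, deflate `E ← E − tpᵀ`, `f ← f − qt`. For a
single response the weight step is closed-form, so no inner iteration is
needed; extraction stops early if the residual structure falls below
1e-12. At full rank PLS1 reproduces ordinary least squares (a test
oracle).

**MPLS.** Between factor extractions, the X-residual columns and the
y-residual are rescaled by their current standard deviations, damping
domination by high-variance spectral regions. The per-factor scalings and
deflations compose into a linear map, so the final model is still a
single coefficient vector on the treated grid; the implementation applies
the accumulated operators in O(a·p) per factor rather than materializing
a p×p matrix. Residual columns with zero SD are dropped from scaling with
a warning. This variant is standard-NIR-software-compatible in spirit,
not bit-compatible: the vendor's exact algorithm is unpublished.

**PCR.** SVD of centered X, ordinary regression of y on the leading
scores, coefficients mapped back to wavelength space. Components with
singular values below 1e-10 of the maximum are dropped.

**Component count.** Contiguous-block cross-validation (default 4
blocks — deterministic, unlike random folds) computes SECV(k) as the RMSE
of pooled held-out predictions; the chosen count is the SECV minimizer
capped at 5 components, reflecting practice for these traits on this kind
of grid. Whether SECV or external SEP should drive the choice per trait
is genuinely open; SECV-argmin is implemented because it uses calibration
data only.

**Outlier elimination.** Samples with standardized y-residual above
`t_limit = 2.5` or score-space leverage GH (Mahalanobis-type, scaled to
mean ≈ 1) above `gh_limit = 3.0` are removed and the model refit, at most
`max_passes = 2` passes, with total removals capped at 10 % of the set
(about 10 of 120, the scale reported in practice). Hitting the cap stops
elimination with a warning, never an error. External validation never
removes outliers — robustness claims would otherwise be circular.

**Conventions.** SEC is reported as `sqrt(RSS/(n−1))`: with a fixed
denominator the training error is provably non-increasing in the number
of components (a tested invariant), which the `n−k−1` convention would
not guarantee. SECV uses the pooled-RMSE form above.

## Validation statistics

With `d = predicted − lab` on the external set of size n:

* `bias = mean(lab − predicted)` — the sign convention under which a
  negative bias means the model overestimates. (The squared-looking
  typeset form this statistic sometimes receives cannot produce the
  negative values routinely reported for it; only the signed mean can.)
* `SEP = sqrt(Σd²/n)`; `SEP(C) = sqrt(Σ(d − mean(d))²/n)`. The n
  denominator is kept deliberately; a flag exposes the n−1 convention for
  comparison with other software. Under n, `SEP² = SEP(C)² + bias²` is an
  exact identity, which the test suite checks to 1e-10.
* `RPD = SD/SEP(C)` by default (the bias-corrected flavour is what the
  abstracted summary statistics use); a config switch computes it from
  uncorrected SEP instead. Bands: < 1.0 very poor, 1.0–1.4 poor, 1.4–1.8
  fair, 1.8–2.0 good, 2.0–2.5 very good, ≥ 2.5 excellent. A zero SEP
  (perfect fit) is flagged as an error rather than returning infinity.
* Paired t-test on `lab − predicted`: SE = SD/√n, t = mean/SE, df = n−1,
  two-sided p from Student's t. Note that some statistical packages print
  the SE as SD/√(n−1); we use the standard SD/√n and verify the
  implementation against `stats::t.test`.

`validation_report()` refuses to score a set that overlaps the model's
training ids unless explicitly allowed (the report is then flagged
in-sample).

## The synthetic generator

The generator exists because the motivating scan set is not public. It
emulates the *statistical structure* the workflow relies on, not the true
rice NIR signature:

* **Compositions.** Each trait is drawn 70 % from a scaled Beta(2,2)
  (central mass) and 30 % uniform over the full laboratory range —
  protein 6.45–14.63 %, TDF 4.43–5.84 %, starch 65–85.45 %, amylose
  5.23–30.7 %, oil 3.05–7.00 % — mimicking a germplasm set curated toward
  uniform coverage with real extreme-value mass. Amylose, being a starch
  fraction, is a uniform fraction of starch clipped to its own range (so
  amylose ≤ starch row-wise). Moisture is a nuisance trait in 9.5–11.9 %;
  nitrogen satisfies protein = N × 5.95 exactly.
* **Spectra.** Beer–Lambert-style linear mixing of Gaussian constituent
  bands placed at the six major observed brown-rice flour bands — 1196
  and 2322 nm (C-H, oil), 1466 and 2288 nm (N-H/O-H, protein, with a
  starch share at 1466), 1904 nm (O-H/C-O, starch), 1634 nm (O-H, water)
  — plus free-parameter bands distinguishing amylose (2136 nm) and fiber
  (1730, 1374 nm), a fixed curved baseline, per-sample multiplicative
  scatter `b ~ N(1, 0.05²)` and additive offset `a ~ N(0, 0.02²)` (the
  effects MSC/SNV are built to remove, so preprocessing efficacy is
  testable), and i.i.d. noise of SD 3×10⁻⁴ AU.
* **Band widths and amplitudes are free parameters** (published band
  positions come without molar absorptivities). Amplitudes are set small
  relative to the baseline so the per-sample MSC slope barely depends on
  composition: MSC divides by that slope, and large composition-dependent
  slopes would make corrected spectra nonlinear in concentration. With
  the defaults, scatter- and noise-free spectra after MSC regress onto
  compositions with RSQ > 0.999 at six components — the generator's
  linearity-limit property, enforced by test.

What the generator does **not** emulate: realistic band shapes and
overlaps of actual rice flour, wavelength-dependent instrument noise,
nonlinear detector response, moisture–constituent interactions, or
particle-size effects beyond the two-parameter scatter model. Passing
tests on synthetic data therefore demonstrate that the *pipeline*
(selection, preprocessing, regression, statistics) is implemented
correctly and recovers known structure at realistic noise — not that any
particular accuracy will be reached on real instrument data.

## Problem sizes used by the test suite

Unit tests run on generated sets of 20–200 samples; the end-to-end
acceptance-style checks use the standard 500-accession fixture with the
grid restricted to the five per-trait finalized treatments
(`finalized_treatments()`) crossed with all scatter corrections and
regression methods — the structure of the full search at a fraction of
the cells. The full 17-treatment, 153-cell grid (`grid_spec()`) runs in a
few minutes and is exercised via `run_study()` in exploratory use.

## Known limitations

* JCAMP-DX support covers single-spectrum `(X++(Y..Y))` AFFN tables only;
  vendor binary formats are out of scope.
* The gap-derivative and MPLS definitions follow published descriptions
  of the WinISI-era algorithms; exact numerical agreement with
  proprietary software is not claimed.
* Sub-clustering is applied to every main cluster larger than
  `small_cluster_max`; whether the original procedure sub-clustered only
  large clusters is unstated.
* One grid search is run per trait (trait-specific treatments support
  this); a shared-preprocessing mode is not implemented.
* PLS2 (multi-response), variable selection, and nonlinear calibration
  are deliberately out of scope.
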