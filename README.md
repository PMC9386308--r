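# grainspec

Near-infrared reflectance spectroscopy (NIRS) lets a gene bank or breeding
program estimate grain composition — total protein, dietary fiber, starch,
amylose, oil — from a one-minute scan of flour instead of days of wet
chemistry. The catch is that prediction models calibrated on ordinary
market samples fail on germplasm collections, whose trait values run far
outside the commercial range. `grainspec` implements the calibration
workflow designed for that situation, for brown-rice flour in particular:

* **Spectral-diversity-driven sample selection.** All scanned accessions
  are MSC-normalized and clustered by Ward's minimum-variance method on
  squared Euclidean distances; from every cluster and sub-cluster the
  center sample and the extreme boundary samples are taken (small clusters
  contribute all members), yielding a reference set that spans the
  spectral — and hence compositional — diversity.
* **Rank-ordered 2:1 splitting.** For each trait, samples are sorted by
  the laboratory value and every third one (ranks 2, 5, 8, ...) is held
  out, so calibration (2/3) and validation (1/3) sets cover the same
  range and the extremes always stay in calibration.
* **WinISI-style preprocessing.** Scatter corrections — multiplicative
  scatter correction (MSC: regress each spectrum on the calibration mean,
  correct as `(x − a)/b`) and standard normal variate with second-degree
  detrend (SNV-DT) — followed by math treatments written `d,g,s1,s2`:
  a moving-average smooth of width `s1`, `d` centered gap derivatives
  `y[i] = x[i + g/2] − x[i − g/2]`, and a final smooth of width `s2`.
* **Calibration.** PLS1 (NIPALS), modified PLS (MPLS: X- and y-residuals
  are re-standardized between factor extractions) and principal component
  regression, with the component count chosen by contiguous-block
  cross-validation under a cap of 5, and iterative outlier elimination
  (standardized residual > 2.5 or score-space leverage GH > 3, at most two
  passes, removals capped at 10 % of the set).
* **Validation statistics.** For the external set: RSQ, slope, signed bias
  `mean(lab − predicted)`, SEP and bias-corrected SEP(C) (n denominator,
  so `SEP² = SEP(C)² + bias²` exactly), RPD = SD/SEP with the usual bands
  (RPD > 2.5 = excellent), and a paired t-test of laboratory vs predicted
  values.

Because instrument data for the motivating study are not public, the
package ships a synthetic generator (`simulate_compositions()`,
`simulate_spectra()`, `make_study_fixture()`) that emulates a
500-accession brown-rice scan set — Gaussian constituent bands at the six
major observed wavelengths (1196, 1466, 1634, 1904, 2288, 2322 nm),
Beer–Lambert-style linear mixing, multiplicative/additive scatter and
instrument noise — so the whole workflow is exercisable and testable
end-to-end.

## Worked example

```r
library(grainspec)

fx <- make_study_fixture(seed = 42)           # 500 accessions x 1046 wavelengths
norm <- msc_fit_apply(fx$spectra)$spectra     # MSC-normalize for clustering
tree <- ward_cluster(norm)
sel  <- select_representatives(tree, target = 180)
sp   <- subset_samples(fx$spectra, sel)
ref  <- fx$reference[match(sel, fx$reference$sample_id), ]

plan <- split_by_trait(ref, "protein_pct")    # 120 calibration / 60 validation
cal  <- subset_samples(sp, plan$calibration_ids)
val  <- subset_samples(sp, plan$validation_ids)

model <- calibrate(cal, ref, "protein_pct",
                   method = "mpls", scatter = "snv_dt", treatment = "4,8,8,1")
model
#> <calibration_model> protein_pct: MPLS / snv_dt / 4,8,8,1, 5 PCs
#>   n=120  RSQ=0.998  SEC=0.103  SECV=0.326  SD=2.122  outliers=0

validation_report(model, val, ref)
#> <validation_report> protein_pct (MPLS / snv_dt / 4,8,8,1, 5 PCs)
#>   n=60  RSQ=0.990  slope=0.939  bias=-0.001  SD=2.132  SEP(C)=0.238  RPD=8.94 (excellent)
#>   paired t = -0.048 (df 59, p = 0.962)
```

Reading the report: RSQ is the squared correlation between predicted and
laboratory protein; the slope near 1 and bias near 0 mean the calibration
is neither tilted nor offset; SEP(C) = 0.238 % protein is the prediction
error after bias correction; RPD = 8.94 (the validation-set SD divided by
SEP(C)) is far above the 2.5 threshold for "excellent", so the model can
replace wet chemistry for screening; and the paired t-test finds no
significant difference between predicted and laboratory means (p = 0.96).

`run_grid()` searches treatments × scatter corrections × regression
methods for one trait and ranks cells by external RSQ (ties: higher RPD,
lower SEP); `run_study()` performs the whole workflow — simulate, select,
split, grid-search, validate — for all five traits from a single seed.
A thin command-line wrapper with `simulate` / `preprocess` / `select` /
`split` / `calibrate` / `validate` / `run` subcommands is installed at
`inst/cli/grainspec.R`.

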