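# iphdetect

Semi-automatic detection and quantification of carotid **intraplaque
hemorrhage (IPH)** on heavily T1-weighted (MP-RAGE) vessel-wall MR images.

IPH appears hyperintense on MP-RAGE because methemoglobin shortens T1, but
raw intensities are not comparable across slices or patients: surface coils
make signal fall off with depth. The method implemented here therefore
classifies each pixel inside a reviewer-drawn outer-wall contour by its
ratio to a **reference tissue intensity**, calling IPH where

```
intensity > t × reference
```

with three interchangeable references:

- **SCM** — mean of the sternocleidomastoid muscle, clipped to a 4 cm
  circular ROI centered at the carotid lumen;
- **adjacent muscle** — mean of a nearby deep muscle (e.g. scalene) drawn
  isointense with normal carotid wall;
- **local median** — median intensity of the whole 4 cm ROI, requiring no
  manual muscle ROI at all.

The operating threshold `t` is not fixed a priori: it is **fitted** against
histology ground truth by building an ROC curve of slice-level IPH presence
over `t` and maximizing Youden's index `J = sensitivity + specificity − 1`
on a 0.1-step lattice. Generalization is estimated by **patient-level
leave-one-out cross-validation**: each patient's slices are classified with
the threshold fitted on all other patients, and the pooled held-out
predictions yield sensitivity, specificity and the Pearson correlation of
detected vs histological IPH area. Analyses run over six data subsets that
cross minimum histological IPH area (0, π·0.63², π·(0.63·1.5)² mm²) with
exclusion of heavily (>50 %) calcified IPH.

Because patient MR + histology data cannot ship with the package, it
includes a **synthetic phantom generator**: annular vessel wall, IPH disk at
a controlled contrast ratio, optional calcified core, superficial SCM and
deep adjacent-muscle regions, exponential coil-sensitivity falloff and
Gaussian noise — with exact painted ground truth, so the entire pipeline is
exercised and validated end to end.

## Worked example

```r
library(iphdetect)

cfg    <- phantom_config(seed = 42)           # 14 patients x 10 slices, IPH at 1.6 x muscle
cohort <- generate_cohort(cfg)
cohort
#> <iph_cohort> 140 slices from 14 patients (64 IPH+ by truth)

ds  <- prepare_dataset(cohort, ref_kind = "adjacent_muscle")
fit <- iph_fit(truth_present ~ score, data = ds$table)
fit
#> IPH threshold fit (Youden-optimal)
#> Call: iph_fit.formula(formula = truth_present ~ score, data = ds$table)
#>   slices: 64 positive / 76 negative   AUC: 1.000
#>   threshold: 1.6 x reference   J = 1.000 (sens 1.000, spec 1.000)

cv <- iph_loocv(ds, subset = subset_spec(min_iph_area_mm2 = area_cutoff(1.5),
                                         exclude_heavily_calcified = TRUE))
cv
#> IPH leave-one-out cross-validation (adjacent_muscle reference)
#> <subset> IPH area >= 2.806 mm^2, excluding IPH > 50% calcified
#>   112 slices (36 IPH+), 14 folds
#>   fold thresholds: 1.4-1.5 (spread 0.1)
#>   pooled sensitivity 1.000, specificity 1.000
#>   Pearson r (area): 0.985 all slices, 0.861 IPH+ only
```

Reading the output: the fitted threshold (1.6 × adjacent-muscle intensity)
recovers the generative IPH contrast; fold thresholds vary by only 0.1
across the 14 leave-one-out fits; the held-out area correlation on
IPH-positive slices is depressed below 1 by calcified cores, whose low
gradient-echo signal is (correctly) not detected as IPH — the phantom
reproduces that known failure mode.

`evaluate_cohort()` runs the full reference × subset grid and returns the
threshold/AUC table and the cross-validated performance table;
`run_simulate()`, `run_detect()`, `run_evaluate()` and `run_roc()` are
file-based equivalents, also reachable from a shell via
`inst/cli/iphdetect.R`.

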