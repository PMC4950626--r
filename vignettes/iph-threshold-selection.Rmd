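---
title: "Reference-normalized threshold selection for intraplaque hemorrhage detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-normalized threshold selection for intraplaque hemorrhage detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iphdetect)
```

## The problem and the model

Intraplaque hemorrhage (IPH) in carotid atherosclerotic plaque is
hyperintense on heavily T1-weighted MP-RAGE images, but the raw signal is
uninterpretable in absolute terms: surface receive coils impose a
multiplicative sensitivity field that decays from the skin toward the neck
center, and scaling differs between scans. The method in this package
normalizes each pixel by a per-slice reference intensity and declares IPH
where the ratio strictly exceeds a threshold `t`, restricted to a
reviewer-drawn loose outer-wall contour around the artery:

* pixel is IPH  ⇔  pixel inside outer wall  and  `intensity > t × reference`.

The per-slice **detection score** is the maximum normalized intensity over
outer-wall pixels; comparing it to `t` reproduces the slice-level presence
call for every `t` simultaneously, which is what makes an ROC sweep over
`t` cheap and exact.

Three references are supported. The SCM and adjacent-muscle references are
means over manually drawn polygons (the SCM one clipped to a 4 cm circular
ROI centered at the carotid lumen); the local-median reference is the median
over the whole 4 cm ROI and needs no manual muscle ROI. A reference can be
*invalid* on a slice (polygon absent, or SCM entirely outside the ROI);
invalidity is a value, not an error, and such slices are excluded from
analyses with that reference — deliberately mirroring how slices whose SCM
lies more than 2 cm from the artery drop out of SCM-referenced analyses.

## Threshold fitting

`iph_fit()` builds the ROC curve with candidate thresholds at midpoints
between consecutive distinct scores plus sentinels below the minimum and
above the maximum, so both degenerate endpoints are always present. AUC is
trapezoidal, which for this candidate set equals the tie-corrected
Mann–Whitney concordance (the test suite checks this identity against
exhaustive pair enumeration).

Candidates are then snapped to a lattice of multiples of `grid_step`
(default 0.1), duplicates merged, and the operating point *recomputed* at
each lattice value; the fitted threshold maximizes Youden's
`J = sensitivity + specificity − 1`, with ties broken toward the **larger**
threshold. The 0.1 step matches the one-decimal precision at which such
thresholds are conventionally reported and stabilizes ties; the upward
tie-break prefers the lower false-positive rate, the sensible default for
clinical decision-making (both are arguments, not constants).

## Histology fusion and analysis subsets

Histology sections are matched to MR slices per patient by signed distance
to the carotid bifurcation; a section attaches to the nearest slice within
`half_window_mm` (default 0.5 mm — half the 1 mm slice thickness, the
natural nearest-slab rule; the matching tolerance is not prescribed by the
method, so it is a parameter). With several sections on one slice, truth is
fused as: present if **any** section has IPH; area = **mean** of section
areas; calcified fraction = IPH-area-**weighted** mean (weighting preserves
the fraction's meaning over the pooled area; the fusion rule for fractions
is otherwise underdetermined, so it is documented here rather than hidden).

Six analysis subsets cross a minimum histological IPH area — 0 and
`area_cutoff(x) = π (0.63 x)²` mm² for x = 1 and 1.5, i.e. ≈1.25 and
≈2.81 mm² at the 0.63 mm *acquired* in-plane resolution — with exclusion of
heavily calcified IPH. Comparisons are strict on both rules: present slices
are removed when area `<` cutoff or calcified fraction `>` 0.5; IPH-absent
slices are never removed. Note the deliberate resolution split: pixel areas
use each slice's own (reconstructed, e.g. 0.31 mm) spacing, while the
small-IPH cutoff is pinned to the acquired 0.63 mm resolution.

## Cross-validation

`iph_loocv()` is patient-level leave-one-out: the threshold is refitted on
all other patients' included slices and applied to the held-out patient.
Held-out predictions are **pooled** (micro-averaged) before computing
sensitivity, specificity and Pearson correlations, because per-fold metrics
are frequently undefined with one patient per fold. The area correlation is
reported both over all pooled slices and over truth-positive slices only:
the population underlying a headline correlation is ambiguous in general,
so both are first-class outputs (the positive-only value is the stricter
one — all-zero pairs inflate the all-slices correlation). Fold-threshold
spread (max − min) is reported as the robustness summary.

## The phantom: what it emulates, and what it does not

`generate_cohort()` paints, per slice: background at 0.2 × muscle, an SCM
ellipse near the top edge (superficial), an adjacent-muscle ellipse beside
the vessel at depth, a vessel-wall annulus between 3 and 6.5 mm radius
around a dark lumen (0.1 × muscle), and — with the configured prevalence —
an IPH disk at `iph_contrast_ratio` × muscle placed uniformly inside the
annulus, optionally with a concentric calcified core at 0.3 × muscle whose
area fraction is drawn from `calcified_fraction_range`. The image is then
multiplied by an exponential coil field `exp(−depth/decay)` (depth from the
top edge, standing in for the skin surface) and Gaussian noise is added
(σ = `noise_sigma_ratio` × muscle; a Rician option exists but at these
contrasts the difference is second-order) before clipping at zero.

Defaults are the simulated study conditions: 14 patients × 10 slices,
192 × 192 pixels at 0.31 mm, contrast ratio 1.6, noise σ = 5 % of muscle,
uniform coil field, prevalence 0.5 (chosen to echo a roughly half-positive
slice mix), IPH radius 0.7–1.6 mm so blobs always fit the annulus and truth
areas (≈1.5–8 mm²) straddle both area cutoffs. Geometry is circles and
ellipses only, so every truth quantity is exact by construction: the truth
mask is the rasterized disk and the truth area is its pixel count × pixel
area, which is what makes "detected mask equals painted mask" a meaningful
exact test. All randomness flows from a single seed through per-patient
sub-streams; a configuration reproduces its cohort bit for bit.

What the phantom does **not** emulate: MP-RAGE signal physics (T1/TI/TR are
not simulated), k-space/reconstruction effects, partial-volume mixing at
tissue boundaries, anatomic shape variability, and registration error
between histology and MR positions (phantom truth sits exactly at slice
positions). Passing the phantom suite therefore demonstrates correctness of
the *pipeline* — rasterization, normalization, ROC/Youden optimization,
matching, cross-validation — not clinical performance on patient data.

## Numerical conventions

* Pixel membership in any region is by **pixel center** (no area-weighted
  partial pixels); distances are computed in mm per axis, so anisotropic
  spacing is supported.
* Polygon rasterization uses the even–odd rule with the standard half-open
  ray-casting convention, so a center exactly on a shared edge belongs to
  exactly one of two adjacent polygons; polygons are validated simple
  (non-self-intersecting) with ≥ 3 vertices and nonzero area.
* "Exceeds the threshold" is a strict inequality throughout (detection,
  scoring, ROC), and both subset-exclusion comparisons are strict.
* Median with an even pixel count is the midpoint of the two central order
  statistics.
* IPH presence on a slice defaults to *any* supra-threshold pixel; a
  minimum-pixel-count parameter exists (`min_area_px`) because the original
  presence rule is not fully determined — the default documents the gap
  without inventing post-processing. No connected-component or
  morphological cleanup is applied.
* Degenerate cases: empty circle masks are legal (a reference ROI entirely
  off-image is an error only for the local-median reference, which cannot
  be invalid); zero-variance area vectors make a correlation `NA` with a
  warning rather than an error.

## Problem sizes used in the test suite

The simulation-based tests run the full 14 × 10 study-condition cohort for
threshold recovery, a 5 × 6 noiseless cohort for the degenerate-perfection
check, an 8 × 8 cohort with 60 mm coil decay for the reference-choice
effect, and 64 × 64 grids with 100 random shapes for the rasterization
oracles; these sizes were chosen so each check is statistically meaningful
at interactive runtimes.

## Known limitations

* Contours are inputs; no lumen/outer-wall segmentation is provided.
* No coil-sensitivity correction is implemented — the three-reference
  design is precisely a way of coping without one, and the phantom's coil
  model exists to demonstrate the consequence (the SCM-referenced optimum
  falls below the deep-muscle optimum when the field decays).
* Thresholds are optimized on slice-level presence only, not on lesion
  location or size.
* No statistical comparison between references (e.g. AUC difference tests)
  and no confidence intervals on AUC are computed.
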