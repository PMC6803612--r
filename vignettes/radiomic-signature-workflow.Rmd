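---
title: "PET/CT radiomic signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PET/CT radiomic signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petradiomics)
```

# Overview

`petradiomics` implements a complete radiomic analysis of paired FDG-PET/CT
tumor volumes for a binary mutation-status endpoint (labelled
`mutant` / `wild` throughout). The pipeline has five stages:

1. **Segmentation** — the lesion volume of interest (VOI) is the set of
   voxels with SUV at or above 42% of the lesion SUVmax, 26-connected to the
   SUVmax voxel; the metabolic region is the connected set of voxels with
   SUV strictly above 2.5.
2. **Conventional PET quantification** — SUVmax, SUVmean, SUVpeak (1 cm³
   spherical neighbourhood mean), MTV and TLG.
3. **Radiomic feature extraction** — a fixed, ordered 38-feature vector per
   modality from the 2-d analysis slice: 4 morphology + 9 grayscale
   statistics + 6 GLCM + 15 GGCM + 4 GLDS features.
4. **Univariate statistics** — Wilcoxon rank-sum per feature with
   Benjamini–Hochberg control at FDR 10%, Spearman correlation against the
   conventional metrics, per-feature ROC with a Noether test of AUC > 0.5.
5. **Signature construction** — LASSO-selected features feed an AdaBoost
   classifier, evaluated by stratified 10-fold cross-validation repeated 10
   times; signatures are built from PET features alone, CT alone, and both,
   each optionally augmented with clinical covariates.

A synthetic phantom generator supplies two-class PET/CT cohorts with the
statistical structure the analysis assumes, so every stage is tested end to
end without any imaging download.

# Segmentation model

`segment_isocontour()` needs a seed voxel inside the lesion's high-uptake
region (for phantoms, the known lesion centre). The lesion SUVmax is found
iteratively: threshold at 42% of the current maximum, take the connected
component around the seed, update the maximum, repeat until stable. Because
the threshold is *relative*, the VOI is invariant under positive rescaling
of the PET grid; the seed-validity check is likewise relative (the seed must
exceed 10% of the global maximum) to preserve that invariance exactly. The
42% cutoff is inclusive (`>=`); the metabolic SUV 2.5 cutoff is strict
(`>`), reading "above a threshold" literally — a lesion whose SUVmax is
exactly 2.5 therefore has MTV = 0. Lesions with SUVmax below the cutoff
report MTV = 0 and TLG = 0 by convention.

Connectivity is 26-neighbour in 3-d and 8-neighbour in 2-d. The 2-d
analysis slice is the axial slice with the most in-mask pixels; feature
extraction falls back to the next-largest slice in the rare case that the
largest one cannot support a 3×3 gradient stencil. A slice-averaging mode
(`slice_mode = "average"`) is provided because pixel-based feature
definitions leave open whether a single slice or a slice-wise average is
meant; the single largest slice is the default.

# Conventional PET metrics

SUVpeak has no universal definition; the PERCIST-style choice is used: the
mean SUV over voxels whose centres fall in a 1 cm³ sphere centred on the
hottest voxel, clipped to the grid (sphere volume configurable). TLG is
defined from the metabolic region: TLG = MTV × mean SUV over the MTV mask.
Because "multiplying MTV by SUVmean" is ambiguous about which region's mean
is intended, `tlg_region = "voi"` switches to the VOI mean; the metabolic
mean is the default since TLG is a property of the metabolic volume.

# The 38-feature catalog

The catalog is fixed at 4 + 9 + 6 + 15 + 4 = 38 features
(`radiomic_feature_names()` gives the canonical order). Choices worth
stating explicitly:

* **Morphology** is measured in pixel counts, per the literal definitions:
  area = in-mask pixels; perimeter = in-mask pixels with an out-of-mask
  4-neighbour; diameter = maximum pixel count on a digital line between
  boundary pixels (Chebyshev distance + 1). Concavity is (A − B)/B with B
  the number of pixel centres inside the convex hull of the mask, so convex
  digital shapes score exactly 0 and concave shapes score negative; an
  absolute-value variant is available behind
  `concavity_absolute = TRUE` for users who prefer "higher concavity = more
  irregular".
* **Quantization** maps the in-mask intensity range onto 16 equal-width
  bins. It is range-relative, which makes all co-occurrence and difference
  features invariant under strictly increasing affine rescaling of the
  intensities.
* **GLCM** matrices are symmetric, restricted to pixel pairs that lie
  entirely inside the mask, and averaged over the four angles (0°, 45°,
  90°, 135°) at distance 1. Correlation with a zero-variance marginal is
  defined as 0 so constant regions cannot produce NaN. Logarithms are base
  2 with 0·log 0 := 0.
* **GGCM** uses a 3×3 Sobel gradient computed only at pixels whose full
  3×3 neighbourhood is in-mask; gray levels use the 16-bin quantization and
  gradient magnitudes are binned over [0, max in-mask gradient] into 16
  bins. The 15 features are the canonical gray-gradient set (small/big
  gradient dominance, gray/gradient asymmetry, energy, marginal means and
  variances, correlation, three entropies, inertia, inverse difference
  moment).
* **GLDS** uses the four displacements (0,1), (1,1), (1,0), (1,−1) in
  (Δx, Δy) convention and averages the per-displacement mean, contrast,
  ASM and entropy; displacements without a valid in-mask pair are dropped
  from the average with a warning.

Every texture family is verified in the test suite against independent
brute-force oracles (exhaustive pair and joint-histogram enumeration) on
images up to 8×8, to 1e-9.

# Statistics

The Wilcoxon rank-sum test uses midranks and switches to exact enumeration
when the combined sample size is at most 10 and untied. BH adjustment is
the standard step-up procedure with monotonicity enforcement; the
screening threshold is FDR 10%. AUCs use the Mann–Whitney formula with 0.5
credit for ties; reported per-feature AUCs are oriented into [0.5, 1]. The
Noether test of AUC > 0.5 is one-sided and uses the DeLong
structural-components variance because the test is named in the field
without a variance formula; under perfect separation the standard error
degenerates and is replaced by the continuity bound 1/sqrt(n1·n0) (with a
message), which keeps the p-value finite and conservative. Operating
points (sensitivity/specificity/accuracy) are Youden-optimal because no
fixed-threshold rule is standard for this analysis.

# Signature model

Within every training fold — and only there — features are standardized,
LASSO-selected (`glmnet`, binomial deviance minimized over an inner
stratified 10-fold search) and passed to AdaBoost over threshold stumps
(100 rounds, depth 1 by default; depth > 1 delegates the weak learner to
`rpart`). Held-out scores are pooled per repeat; AUC and the
Youden-optimal accuracy (reported as percent), sensitivity and specificity
are averaged over 10 repeats. When the deviance-optimal penalty selects no
feature (pure-noise folds), the largest penalty admitting one nonzero
coefficient is used so a classifier can always be fit; this only matters
under the null and cannot inject signal.

Two selection reports exist deliberately: `describe_selected_features()`
runs LASSO once on the full cohort for a descriptive "identified features"
list, while `evaluate_signature()` re-selects inside every training fold,
which is what makes the cross-validated performance honest. The
`fit_score_fold()` unit is exported so that leakage audits can drive it
directly; the test suite includes a canary in which a feature equals the
label only on held-out rows and verifies that the pooled AUC stays at
chance.

Clinical covariates enter as seven columns — age, male gender, smoker,
advanced stage, and three lobe-location dummies (upper lobe reference) —
and by default pass through the LASSO together with the radiomic features.

# The phantom generator

`generate_cohort()` draws, per patient: a lesion radius (8–14 mm uniform),
a star-convex lesion mask (an ellipsoid whose radius is modulated by
low-order direction harmonics scaled by the boundary-irregularity
amplitude; amplitude 0 gives a digital ellipsoid, and the construction
guarantees a single connected component), a spatially correlated Gaussian
random field (white noise smoothed with a kernel whose width is the
texture correlation length) that modulates the lesion SUV level, and an
analogous HU field for CT. The grid is 44³ voxels at 2 mm spacing — finer
than clinical PET, chosen so that 8–14 mm lesions contain enough pixels on
the analysis slice to support 16-level texture statistics. Dose and weight
metadata are back-filled so the activity-to-SUV conversion path is
exercised round-trip.

The default class parameters encode the qualitative contrasts the analysis
targets, with the mutant class having *lower* uptake (SUV level 6.5 vs 8.5,
between-patient SD 2.2), *higher and finer-grained* heterogeneity
(amplitude 0.23 vs 0.13; correlation length 4.3 vs 6.5 mm, SD 1.3) and a
*more irregular* boundary (0.22 vs 0.10). Because quantization is
range-relative, texture discrimination is driven mainly by the
correlation-length difference, not the raw amplitude.

The two modalities are made *complementary* rather than redundant. For
most lesions the CT channel carries only a weak class contrast (HU level
40 vs 37, texture amplitude 40 vs 37 HU, equal correlation lengths), so
the class signal is predominantly metabolic. A minority of lesions
(`pet_occult_rate`, default 25%) are *PET-occult*: their PET-side
parameters are drawn from the across-class pooled means — no metabolic
class contrast at all — while their CT density phenotype carries an
amplified contrast (HU level 48 vs 29, texture amplitude 48 vs 29 HU,
class-specific correlation lengths). This mirrors the clinical rationale
for acquiring both modalities: a subgroup that is inseparable on PET is
separable on CT, so the combined signature genuinely gains over either
modality alone and the expected ordering
AUC(PET/CT) ≥ AUC(PET) ≥ AUC(CT) is a property of the generating process
rather than an accident of one draw.

No effect sizes for texture differences are available to copy from real
cohorts; the defaults were calibrated once so that end-to-end
discrimination is non-trivial (cross-validated AUC around 0.8, matching
the performance regime the analysis is designed for) and then frozen.
Clinical covariates are generated independently of image texture given
the class label: age on 28–77 with median near 63 (a rescaled
Beta(2.5, 1.2)), smoking prevalence 23.4% / 41.2% per class, ~78% early
stage, and class-specific lobe distributions.

What the phantom does **not** emulate: scanner point-spread and partial
volume effects, attenuation and reconstruction artifacts, respiratory
motion, and any dependence of clinical covariates on image phenotype
beyond the class label. Passing tests therefore demonstrate that the
pipeline recovers planted class structure correctly and without
information leakage — not that any particular AUC will be attained on real
patients.

# Numerical conventions and degenerate inputs

* Constant regions: SD, skewness, kurtosis, entropy and span are 0; ASM
  and energy are 1; homogeneity is 1; correlations are 0.
* Histograms and co-occurrence matrices always normalize to sum 1
  (asserted to 1e-9 in tests).
* The radial boundary multiplier is clamped to [0.4, 1.8], which bounds
  lesion extent and underlies the fits-in-grid validation.
* Lesions that do not fit the grid, empty masks, empty VOIs, single-class
  label vectors and misaligned patient tables are hard errors, not
  warnings.
* All randomness is seeded: cohorts are a deterministic function of the
  master seed and the patient index, and `evaluate_signature()` derives
  its fold assignments from `spec$seed`, so identical seeds give
  bit-identical artifacts.

# Problem sizes used in the test suite

Unit tests run on small grids (≤ 28³) with 6–20-patient cohorts; oracle
comparisons use images up to 8×8 where exhaustive enumeration is exact.
The end-to-end class-recovery check uses the full default cohort (115
patients, 64/51) with 10-fold CV repeated 10 times; the null-calibration
checks use 20 permutation seeds for the cross-validated AUC and 2000 label
permutations for the Noether test size. These sizes were chosen as the
smallest that make the corresponding statistical assertions stable.

# Known limitations

* Features are 2-d (pixel-based definitions); no 3-d texture matrices or
  filtered (wavelet/Laplacian) feature classes.
* No partial-volume correction and no decay correction (a fixed uptake
  time is assumed).
* No DICOM ingestion — NIfTI and CSV only.
* The GGCM feature set follows the canonical 15-feature definition; other
  conventions exist in the literature (e.g. unnormalized dominance
  weights), and numerical values are not comparable across conventions.
* The boosting weak learner is a threshold stump by default; deeper trees
  are supported but not tuned.

# A minimal run

```{r, eval = FALSE}
cfg <- run_config(seed = 1, out_dir = "run1",
                  phantom = list(n_mutant = 64, n_wild = 51))
bundle <- run_pipeline(cfg)
render_report(bundle)
read_table_csv(bundle$paths["signatures"])
```
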