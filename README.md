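# petradiomics

Radiomic signatures from paired FDG-PET/CT tumor images for binary
mutation-status prediction.

## The problem

Activating mutations in oncogenes such as EGFR change tumor glucose
metabolism and tissue architecture, and those changes leave traces in the
imaging phenotype: mutated lesions tend to show different uptake levels,
more heterogeneous tracer distribution and more irregular boundaries than
wild-type lesions. `petradiomics` is for imaging researchers who want to
quantify that connection: it turns a cohort of segmented PET/CT lesions
into a cross-validated *radiomic signature* — a multivariate classifier
score over texture, shape and intensity features — and reports how well
the signature separates the two mutation classes.

## What it computes

For each lesion the package computes:

- **Segmentation** — the volume of interest (VOI) at the 42% SUVmax
  isocontour (`segment_isocontour()`), and the metabolic region at the
  absolute SUV > 2.5 cutoff, with SUV defined as
  `activity (mCi/mL) / [dose (mCi) / body weight (g)]`.
- **Conventional PET metrics** — SUVmax, SUVmean, SUVpeak (1 cm³
  neighbourhood mean), MTV (mL) and TLG = MTV × SUVmean of the metabolic
  region. A lesion whose SUVmax does not exceed 2.5 has MTV = TLG = 0.
- **38 radiomic features per modality** — 4 morphological (area,
  perimeter, diameter, concavity = (A−B)/B against the convex hull), 9
  grayscale-statistic, 6 gray-level co-occurrence (GLCM, 16 gray levels, 4
  angles at distance 1), 15 gray level–gradient co-occurrence (GGCM,
  Sobel gradients) and 4 gray-level difference (GLDS, 4 displacements)
  features, all restricted to in-mask pixels.

Cohort-level analysis then applies Wilcoxon rank-sum screening with
Benjamini–Hochberg control (FDR 10%), Spearman correlation against the
conventional metrics, per-feature ROC with a Noether test of AUC > 0.5
(DeLong variance), and builds PET, CT and PET/CT signatures — optionally
combined with clinical covariates — via LASSO feature selection and an
AdaBoost stump classifier inside stratified 10-fold cross-validation
repeated 10 times. Standardization, selection and fitting all happen
inside training folds only.

Because no public lesion cohort accompanies the method, the package ships
a phantom generator (`generate_cohort()`) producing two-class PET/CT
cohorts (default 64 mutant / 51 wild-type) with controllable lesion
intensity, spatial heterogeneity, boundary irregularity and clinical
covariate structure. See the vignette
(`vignettes/radiomic-signature-workflow.Rmd`) for the model and every
default.

## Worked example

```r
library(petradiomics)

cfg <- run_config(seed = 1, out_dir = "run1",
                  phantom = list(n_mutant = 20, n_wild = 20),
                  scopes = c("pet", "ct"), clinical = FALSE,
                  folds = 5, repeats = 2)
bundle <- run_pipeline(cfg)
bundle$signature_table
```

```
  signature clinical      auc accuracy_pct sensitivity specificity
1       PET    FALSE 0.708125        71.25       0.800       0.625
2        CT    FALSE 0.640625        70.00       0.975       0.425
```

Each row is one signature: the mean cross-validated AUC, accuracy (%),
and the sensitivity/specificity at the Youden-optimal threshold, averaged
over the repeats. On this small 40-patient phantom the PET-feature
signature separates the two classes better (AUC ≈ 0.71) than the
CT-feature signature (AUC ≈ 0.64), reflecting the phantom's PET-dominant
class contrast; the default 115-patient cohort gives sharper separation.
The other artifacts written to `out_dir` are the per-patient
feature table, the Wilcoxon/BH comparison table, the Spearman grid
against the conventional PET metrics, the per-feature ROC table and a
JSON manifest of every analysis parameter applied
(`render_report(bundle)` writes a plain-text summary).

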