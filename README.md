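# pannenct

Quantitative multiphase-CT analysis for grading pancreatic neuroendocrine
neoplasms (panNENs), for imaging researchers who want the full chain —
enhancement-ratio quantification, 3D first-order texture, grade statistics
with ROC — as tested, scriptable code rather than workstation clicks.

PanNENs are graded G1/G2/G3 by the Ki67 index. Their CT phenotype tracks
grade twice over: high-grade tumors are hypo-enhancing in the pancreatic
(arterial) phase, and their necrotic/fibrotic foci make the tumor intensity
histogram leptokurtic. The package quantifies both signals:

- **Enhancement/permeability ratios** from six circular-ROI measurements
  (`A = HU_tumorART`, `P = HU_tumorPORT`): tumor/parenchyma ratios per
  phase, `A/HU_aorta`, `P/HU_portal`, and the permeability indices
  `(A+P)/HU_aorta`, `(P−A)/HU_aorta`, `A/P`.
- **First-order texture** of the segmented 3D tumor on the pancreatic phase
  (5 mm standardized slices): mean, variance `m2`, skewness `m3/m2^1.5`,
  **excess** kurtosis `m4/m2² − 3`, Shannon entropy (bits, 128 bins).
- **Grade statistics**: Pearson χ² for qualitative flags, pooled t for
  sizes, pairwise two-sided Mann-Whitney U (exact for small samples) for the
  quantitative features, ROC (positive class G3 vs G1+G2) with cutoff
  sensitivity/specificity for significant features.
- **A phantom cohort generator** with analytic Gaussian-mixture ground truth
  (`mixture_moments()`), so every stage is validated end to end without
  patient data.

Volumes and masks are read/written as NIfTI-1 (`.nii`/`.nii.gz`, HU after
intensity scaling); ROIs travel in a JSON sidecar; cohorts in a documented
CSV (`cohort_columns()`).

## Worked example

```r
library(pannenct)

## one high-grade phantom patient
les <- generate_lesion(default_grade_profiles()$G3, seed = 42)
les$volumes$pancreatic
#> <ct_volume> 96x96x20 voxels, spacing 1x1x5 mm, phase pancreatic, HU [-24.9, 317.5]
texture_from_study(les$volumes$pancreatic, les$mask)
#> <texture_panel> n=11448 voxels | mean 76.63  var 544.66  skew -1.528  ex.kurt 2.231  entropy 5.922 bits (128 bins)
str(les$truth$moments)   # analytic mixture ground truth
#> List of 4
#>  $ mean    : num 76.6
#>  $ variance: num 543
#>  $ skewness: num -1.53
#>  $ kurtosis: num 2.21
```

The extracted excess kurtosis (2.23) sits within sampling noise of the
analytic mixture value (2.21): the 12% necrotic fraction at −70 HU makes the
G3 histogram leptokurtic, which is exactly the grade signal.

```r
## a small cohort, simulated and analyzed in memory
df  <- phantom_cohort_features(n_per_grade = c(10, 10, 10), master_seed = 1)
rep <- grade_report(df)
rep
#> <grade_report>
#>   patients per grade: G1=10, G2=10, G3=10
#>   qualitative flags tested: 10
#>   pairwise Mann-Whitney comparisons: 36
#>   significant features (alpha=0.05): tumor_parenchyma_ratio_1, tumor_arterial_ratio, ...
#>   ROC kurtosis: AUC 1.000
subset(rep$pairwise, feature == "kurtosis")
#>   feature  pair U      p_value n1 n2
#>  kurtosis G1vG2 0 0.0001826718 10 10
#>  kurtosis G2vG3 0 0.0001826718 10 10
#>  kurtosis G1vG3 0 0.0001826718 10 10
```

Kurtosis separates all three grade pairs (exact Mann-Whitney p ≈ 2e-4 at
n = 10/10), mirroring the clinical finding that histogram shape is the
strongest grade discriminator. At the default 31/52/17 cohort the G3
kurtosis AUC is ≥ 0.85 in ≥ 95% of replicate cohorts (see
`tests/testthat/test-acceptance.R`, criterion 7).

## Command line

```sh
Rscript inst/cli/pannen.R simulate --n 31,52,17 --seed 1 --cohort cohort/
Rscript inst/cli/pannen.R extract  --cohort cohort/ --out results/
Rscript inst/cli/pannen.R analyze  --out results/
```

(installed copy: `system.file("cli", "pannen.R", package = "pannenct")`; a
sample YAML config ships in `inst/extdata/example-config.yaml`).

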