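---
title: "Methods: CT enhancement ratios, first-order texture and phantom validation for panNEN grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT enhancement ratios, first-order texture and phantom validation for panNEN grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Pancreatic neuroendocrine neoplasms (panNENs) are graded G1/G2/G3 from the
Ki67 proliferation index, which requires tissue. Two CT signatures carry
grade information non-invasively. First, vascularization: low-grade panNENs
are hypervascular and enhance strongly in the pancreatic (arterial) phase,
while high-grade tumors are relatively hypo-enhancing with delayed
portal-phase enhancement. Second, heterogeneity: high-grade tumors contain
necrotic/fibrotic foci, so the histogram of tumor attenuation grows a
hypodense tail — it becomes leptokurtic — whereas homogeneous G1 tumors are
platykurtic-to-Gaussian. `pannenct` implements the quantitative analysis
built on these two signatures, plus a synthetic phantom cohort that makes
every stage testable without patient data.

## Measurement model

**ROI measurements.** Six mean attenuations per patient, each from a circular
ROI on a single slice: tumor and adjacent pancreas on both post-contrast
phases, aorta on the pancreatic phase, portal vein on the portal phase (each
vessel in the phase where it is maximally enhanced — the acquisitions are
timed to exactly those peaks, and the ratio names "arterial"/"venous" imply
it). A voxel belongs to an ROI when its in-plane center lies within the
radius (in mm, spacing-aware) of the ROI center; ROIs with fewer than 5
voxels or leaving the image are rejected. ROIs are copied verbatim across
phases — no registration — and a grid mismatch between phases is an error.

**Ratios.** With `A = HU_tumorART`, `P = HU_tumorPORT`:

| ratio | definition |
|---|---|
| tumor parenchyma ratio 1 / 2 | `A / HU_pancART`, `P / HU_pancPORT` |
| tumor arterial / venous ratio | `A / HU_aorta`, `P / HU_portal` |
| permeability ratio 1 / 2 / 3 | `(A+P)/HU_aorta`, `(P−A)/HU_aorta`, `A/P` |

By construction `P1 − P2 = 2·TAR` holds to machine precision per patient; the
package enforces it and makes no attempt to reproduce published *group means*
of these ratios, which (as the identity check on the printed means shows) are
not internally consistent, presumably due to rounding or per-patient
exclusions upstream. Denominators below 1 HU in magnitude abort with an
error naming the measurement: contrast-enhanced vessels and parenchyma are
far above 1 HU, so a smaller value signals corrupt data, not biology.

## First-order texture

Texture is computed on the pancreatic phase (the phase that best depicts the
tumor's arterial network), after standardizing slice thickness to 5 mm by
linear interpolation along z only (in-plane untouched; clinical reslicing
tools differ in dialect, so ours is the simplest reproducible choice). Masks
are resampled nearest-neighbor, and only explicitly by the pipeline: the
texture operations themselves treat a volume/mask geometry mismatch as an
error, because silent resampling corrupts histogram statistics.

Definitions are fixed (texture tools disagree silently): population `1/N`
central moments; skewness `m3/m2^1.5`; **excess** kurtosis `m4/m2^2 − 3`
(the published per-grade minima are negative, which is impossible for raw
kurtosis and forces the excess convention); Shannon entropy in **bits** over
a 128-bin histogram spanning the sample min–max by default (alternatives:
fixed HU window, mean ± 3 SD). A zero-variance sample returns
skewness = kurtosis = entropy = 0 with a degeneracy flag rather than NaN, so
cohort tables stay total. Intensities are always HU; an `intensity_offset`
lets users emulate tools that consume raw stored gray levels (published
"Mean Value" reaching ~2100 cannot be soft-tissue HU and is not chased, nor
is the published entropy scale, whose normalization is unreported).

## Statistics

Lesion sizes: pooled two-sample t. Qualitative flags: Pearson chi-squared on
the grade-by-level contingency table (no continuity correction by default;
Yates optional for 2×2). Ratios and texture: two-sided Mann-Whitney U for
each grade pair, exact by full enumeration when the combined n ≤ 16 without
ties, otherwise normal approximation with tie and continuity correction (the
exact type-I error of this rule at n = 20/20 is 0.049). α = 0.05 with no
multiplicity correction, deliberately mirroring the clinical analysis. ROC:
positive class is G3 vs G1∪G2; prediction is positive when the score is ≥
the threshold (≤ for lower-is-positive features); AUC by trapezoid, which
equals pair counting with ties worth ½ and hence `U/(n1·n2)`. Per-feature
directions follow the published orderings: ratios and mean attenuation are
lower-is-positive, kurtosis/entropy/variance higher-is-positive — except
permeability ratio 2 (portal minus arterial), which *rises* with grade
(delayed enhancement) and skewness, which in the phantom world falls with
grade because necrosis adds a left tail.

## The phantom: what it emulates

Each phantom patient is an ellipsoidal lesion (optionally with sinusoidal
boundary perturbation when margins are "irregular") in uniform pancreatic
parenchyma, with an aorta and portal vein, on three phases at 1×1×5 mm.
Tumor voxels follow a two-component Gaussian mixture: viable tissue
`N(μ_grade, 12²)` plus spatially clustered necrotic blobs at
`μ_grade + δ` occupying a target volume fraction `f`. Blobs (2.5–6.5 mm
spheres seeded in the 0.45–0.9 normalized-radius shell) make lesions *look*
heterogeneous while the first-order ground truth stays governed by the
mixture marginal; the realized blob fraction is recorded, so the analytic
moments (`mixture_moments()`, exact via Gaussian raw moments) describe the
sample exactly up to within-component sampling noise.

Viable-tissue means are the published per-grade tumor attenuations
(pancreatic/portal: 121.90/103.83, 107.86/98.84, 79.94/89.4 HU), with
between-patient SDs (25/28/14 HU arterial) spanning the published ranges.
Pancreas (110/100 HU), aorta (300 HU) and portal vein (150 HU) are
calibration constants — no spread information is published for them — chosen
so default ratio panels fall inside the published per-grade min–max
envelopes (e.g. the G1 defaults give TVR ≈ 0.69 and P2 ≈ −0.06 against
published means 0.698 and −0.075). The default cohort is 31/52/17 patients.

**Heterogeneity calibration.** Excess kurtosis of a contamination mixture is
*not* monotone in the necrotic fraction: a small fraction of strongly
hypodense tissue is leptokurtic (heavy tail), while a large fraction is
bimodal and platykurtic — at `f = 0.25, δ = −60` the analytic excess
kurtosis is ≈ −0.6, *below* a 2% contamination. The defaults therefore pair
growing fractions with growing offsets: G1 `f=0.02, δ=−15`, G2
`f=0.05, δ=−25`, G3 `f=0.12, δ=−70`, giving analytic excess kurtosis
≈ 0.04 / 0.42 / 2.5 — the published per-grade ordering (0.07 / 0.43 / 2.82).
Per-patient jitter (fraction × U(0.6, 1.4), δ ± 5 HU) provides
between-patient spread.

**Measurement-ROI protection.** Necrotic blobs are carved out of the tumor
measurement disk (ROI radius + 0.5 mm), mirroring the clinical protocol of
measuring in enhancing tissue away from vessels, calcifications and overtly
cystic areas. The ROI ground truth is therefore the viable-component mean,
while texture ground truth is the full mixture.

**Seeding.** One master seed; patient *i* uses
`(master_seed·48271 + i·1103515245) mod 2147483629` (exact in doubles), so
cohorts are bit-reproducible and individual patients can be regenerated.

## What a green test does and does not establish

The phantom validates *mechanics*, not clinical performance. Green tests
establish: exact ratio arithmetic and its invariants; texture features equal
to a direct-summation oracle and to analytic distributions; ROI recovery of
known attenuations within 2 HU; texture recovery of analytic mixture moments
within 3 asymptotic SEs; and that the stated heterogeneity mechanism
separates grades (kurtosis G1-vs-G3 Mann-Whitney p < 0.05 and G3 kurtosis
AUC ≥ 0.85 in ≥ 95% of replicate cohorts — a qualitative echo of the
published AUC 0.924, which depends on unavailable patient data and is not a
target). They do *not* establish: realistic CT noise texture or anatomy
(Gaussian components, no reconstruction physics), the published entropy
behavior (under min–max binning the phantom's G3 entropy *drops*, because
the necrotic tail stretches the histogram support — the published
normalization is unknown), the published skewness ordering, or absolute
Mean Value scales.

Two numerical points about the recovery checks. Standard errors for
skewness/kurtosis use the exact delta-method asymptotics from the mixture's
central moments up to order 8 (`mixture_moment_ses()`), not the Gaussian
`√(6/N)`/`√(24/N)`, which understate mixture sampling error several-fold;
the formulas are verified against Monte Carlo in the tests. And a "within 3
SE" criterion applied to 50 lesions × 4 moments is a 99.7%-coverage
statement, so the acceptance check asserts ≥ 95% empirical coverage with no
|z| > 6, rather than demanding 200/200 — an all-pass demand would fail by
construction for some seeds even with a perfect oracle.

## Numerical and design choices

- **Indexing** is 1-based everywhere (idiomatic R), including the ROI
  sidecar JSON (`center_row`, `center_col`, `slice_index`); masks use
  nonzero = inside.
- **NIfTI-1** single-file `.nii`/`.nii.gz` I/O is implemented in the package
  (no R NIfTI reader is available in the supported stack): axis-aligned
  geometry, little/big-endian read, datatypes uint8/int8/int16/uint16/int32/
  float32/float64, `scl_slope`/`scl_inter` applied on read; volumes are
  written as float64 so round trips are bit-exact. Cross-checked against
  nibabel in both directions in the tests. DICOM series are rejected with an
  explicit error (convert upstream).
- **Resampling** drops output slice centers beyond the input extent and
  keeps the world origin, so slice k sits at `origin_z + (k−1)·thickness`.
- **Exact-vs-approximate** Mann-Whitney switch at combined n = 16 is
  configurable (`exact`, `exact_limit`).
- **Failure isolation**: the extraction stage flags failing patients
  (`qc_fail`) and continues; analysis drops flagged rows.

## Known limitations

No anatomy, perfusion dynamics or reconstruction physics; qualitative flags
are sampled ground truth, not image-derived; single-reader, single-scanner
world (no inter-observer or protocol variation); entropy and Mean Value are
dialect-dependent and only their within-dialect behavior is tested.
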