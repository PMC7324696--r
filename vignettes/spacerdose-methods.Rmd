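---
title: "Methods: geometry, models and decision rules in spacerdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, models and decision rules in spacerdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The clinical problem

A polyethylene-glycol hydrogel spacer injected between the prostate and the
rectum pushes the rectum out of the high-dose region of prostate external-beam
radiotherapy, lowering the risk of rectal toxicity. The implant is invasive
and resource-limited, and its dosimetric benefit varies widely between
patients, so the practical question is *which* patients to implant.

`spacerdose` implements a decision-support chain for hypofractionated
60 Gy / 20 fraction plans. The dose level of interest is the rectal V55Gy —
the percentage of rectal volume receiving at least 55 Gy — which plays the
role that V70Gy plays for conventional 78 Gy fractionation (55 Gy is the
linear-quadratic equivalent once the fraction of the prescription represented
by the metric is taken into account). Two endpoints drive the decision:

* **Pre-RV55**: the rectal V55Gy of a plan made *without* a spacer, and
* **ΔRV55 = Pre-RV55 − Post-RV55**: the reduction achieved by implanting one,

both in % of rectal volume. The package predicts both endpoints from
geometry that is visible on the *pre-implant* CT alone, and turns the
predictions into an implant recommendation.

## Structures and geometric predictors

All structures live in one container, the `contour_stack`: ordered axial
slices, each a list of closed polygons in patient coordinates (x = left,
y = posterior, z = superior, mm). Multiple polygons on a slice follow the
even-odd rule, so nested contours are holes — which is exactly how wall
shells are represented.

Derived structures follow the standard planning recipes:

* **PTV** = CTV grown by anisotropic margins, 7 mm everywhere except 5 mm
  posteriorly (toward the rectum). `expand_margin()` evaluates a scaled
  distance field — each displacement component is divided by the margin
  acting in its direction — on a raster grid and re-contours the unit level
  set per slice, which keeps the boundary sub-voxel accurate. New slices are
  added as far as the superior/inferior margins reach in whole slices.
* **Rectal wall (RW)** = rectum minus a 3 mm inward erosion, kept as
  outer-contour-plus-hole. The erosion is *three-dimensional*: the distance
  of an interior point to the organ surface is the minimum 3D distance to the
  contour curves of nearby slices (plus virtual half-slice curves that damp
  z-quantization) and to the end caps. In-plane-only erosion was considered
  and rejected: away from the organ's equator the nearest surface point is
  partly out-of-plane, and a per-slice 2D erosion of a 20 mm sphere
  understates the shell volume by about 17 %, whereas the 3D erosion agrees
  with the closed form to about 1.5 % at the default 1 mm raster. Slices
  thinner than the wall keep the whole slice (with a message), matching
  planning-system behaviour for collapsed lumens.
* **RW17.5** = the wall truncated 17.5 mm beyond the most extreme PTV
  slices (`height_limit()`), the optimization structure used clinically and
  the structure whose extent makes the distance metric below well defined.

From these, `extract_features()` assembles the predictor vector:

| column | meaning | units |
|---|---|---|
| `rectum_vol_cc`, `rw_vol_cc`, `ctv_vol_cc` | absolute volumes | cc |
| `norm_ctv_pct` | 100 · CTV / rectum | % |
| `rinptv_cc` | rectum ∩ PTV overlap | cc |
| `norm_rinptv_pct` | 100 · RinPTV / rectum | % |
| `rw_to_ctv_cm` | mean slice-wise Hausdorff RW17.5 ↔ CTV | cm |
| `rw_to_ctv_cubed_cc`, `rw_to_ctv_inv_cubed` | its cube and inverse cube | cm³, cm⁻³ |

Normalization always divides by the *whole-rectum* volume (not the wall):
the normalized columns are relative metrics in %, and the identity
`norm · rectum / 100 = absolute` holds exactly for every extracted row.

Two geometric choices deserve a note. The slice Hausdorff distance is the
**symmetric** Hausdorff distance between the boundary *curves* (the larger
of the two directed farthest-point distances); a directed variant is
available behind the `directed` argument. Slices where only one of the two
structures has a contour are excluded from the mean — the height-limited
wall exists precisely to keep the superior/inferior extents comparable.
Volumes are computed from the vector contours by the shoelace formula
(holes subtracted), so only boolean and morphological operations ever touch
a raster.

### Numerical accuracy

The raster resolution defaults to 1 mm in-plane. Against closed forms at
2 mm slice spacing: expanded-sphere volume within 2 %, spherical-shell wall
within 3 %, sphere–sphere lens overlap within 3 %, and the error decreases
as the raster is refined. Hausdorff distances are computed by resampling
one curve at 0.2 mm against the exact segments of the other, and agree with
dense brute force to well under 0.2 mm. The residual geometry error is
dominated by the axial slice quantization, which is a property of the input
data, not of the resolution knob.

## Dose endpoints

`compute_dvh()` builds cumulative, left-closed DVHs ("volume receiving at
least d") on a regular dose grid. Voxel centres are tested against the
matching slice's polygons with 2 × 2 in-plane supersampling, giving
fractional occupancies that reduce raster bias for thin walls; relative
volumes are normalized by the structure's own voxelized volume so curves
always start at 100 %. The default bin width is 0.05 Gy — refining it
further moves V55 by well under 0.1 percentage points. `paired_metrics()`
evaluates each plan's V55 on its own rectum contour and differences them.

## The statistical pipeline

The models are ordinary least-squares linear models,
`y = β₀ + β₁x₁ + β₂x₂ + …`, built and validated by `stepwise_select()` and
`loocv()`:

1. **Pearson screening** of every candidate against the endpoint (the
   significance level α = 0.01 flags entries in the report; it is never a
   selection criterion).
2. **Exclusive groups**: near-duplicate predictors (whole rectum vs rectal
   wall volume) never co-enter; the member with the larger absolute
   correlation represents the group.
3. **Backward stepwise AIC**: starting from the full model, repeatedly
   remove the single term whose removal lowers the AIC most, stopping when
   no removal lowers it. The AIC is the Gaussian-profile form
   `n · ln(RSS/n) + 2(k + 2)`; any monotone-equivalent variant selects the
   same models, and rankings are verified against likelihood-based AIC in
   the tests. Ties (within 1e-9) are broken toward the term with the larger
   p-value, making the elimination deterministic.
4. **VIF pruning**: while any variance inflation factor
   `1/(1 − R²ⱼ)` is ≥ 5, drop the worst offender.
5. **Size cap**: at most three predictors (n = 21 cohorts overfit quickly),
   enforced by further AIC-ordered removal.

Each term's **structure coefficient** `rs = r_pears / √R²` apportions the
explained variance; `rs² = 1` identically for a single-predictor model.

Validation is leave-one-out cross-validation with the term set *fixed* (no
re-selection inside folds). The held-out residuals come from the hat-matrix
identity `eᵢ/(1 − hᵢᵢ)`, which the tests verify against explicit refits to
1e-8. Reported are the predicted R² = 1 − PRESS/SST, the mean absolute
held-out error (MAE), and the relative MAE, `%MAE = 100 · MAE / range(y)`.

## The published models and the decision flowchart

`published_models()` ships four frozen models as a versioned JSON resource:
for each endpoint a full-feature **Model 1** and a planning-system-only
**Model 2** (volumes and their normalizations; no wall-to-CTV distance
metrics, which require contour post-processing that is impractical when
decisions must be made quickly). Model 2 is the default throughout: it
validated with the lower %MAE and the higher predicted R², and needs
nothing beyond TPS volume read-outs.

One registry entry carries a documented caveat: evaluating the ΔRV55
Model 1 coefficients at the cohort-mean features does not recover the
cohort-mean endpoint (the OLS centroid identity), so those printed
coefficients are internally inconsistent — most plausibly a units or
transcription issue in the source table that cannot be resolved from the
published information. They are shipped verbatim, predictions from that
model warn, and no unit guess is applied. The Model 2 centroid identities
hold to within 0.1 %, and the acceptance suite asserts both facts.

`decide_implant()` runs the two-stage flowchart on the predictions:

1. **Stage 1**: predicted Pre-RV55 ≥ ω₁ (default 3.0 %). Below the cutoff
   the rectal dose is low even without a spacer and toxicity risk is small.
2. **Stage 2** (only for stage-1 survivors): predicted ΔRV55 ≥ ω₂
   (default 3.5 %). Below it the implant buys too little reduction to be
   worth the procedure.

Values exactly at a cutoff are retained ("lower limit" read inclusively).
The verdict is monotone in both endpoints. `apply_flowchart()` exposes the
same logic for externally supplied (e.g. measured) endpoints; the default
input is predictions because the use case is pre-implant selection.
`build_nomogram()` renders any of the models as the conventional
0–100-point nomogram (100 points = the largest single-term contribution
span over the predictor ranges); because every scale is affine, reading a
prediction back off the points axis reproduces `predict()` exactly, which
the tests check to far better than 0.1 %.

## The synthetic-data generator

No per-patient clinical data are distributable, so `simulate_cohort()`
provides two generation modes that the whole test suite runs on.

**Model mode** draws the predictor marginals from the published 21-patient
cohort summary — log-normal for volumes (right-skewed, matching the printed
max/mean ratios), truncated normal for the wall-to-CTV distance, all
truncated to the printed ranges — coupled by a Gaussian copula. Joint
correlations were never published; the generator assumes a 0.8 coupling
between rectum and wall volumes (near-duplicates) and a −0.5 coupling
between overlap and distance (organs that overlap the PTV more lie closer),
both exposed as knobs and documented as assumptions. The summary prints
both the absolute and the normalized overlap volume; since the feature
identities force one to be derived from the other, the generator draws the
*normalized* metric (the model predictor) and derives the absolute volume.
Moment-matching before truncation means the realized normalized-overlap
mean sits slightly below the printed 3.4 % (about 3.2 % in expectation);
the calibration tests use the printed standard error as their yardstick, so
this bias is visible but within tolerance, and it is not corrected to avoid
tuning the generator to its own checks. Endpoints are generated from the
published Model 2 equations plus Gaussian noise with
`σ² = Var(ŷ)(1 − R²)/R²`, which reproduces the published R² (0.81 / 0.87)
in large samples — at n = 10 000 the refitted slope is within 1 % and the
realized R² within 0.05, per the tests.

**Geometric mode** builds a randomized phantom per patient — ellipsoidal
CTV, bowed cylindrical rectum with a sampled rectum–CTV gap, spherical
bladder, optional low-frequency radial contour jitter emulating manual
contouring — and runs the *full* pipeline: PTV expansion, wall, height
limiting, feature extraction, a virtual spacer (raised-cosine posterior
displacement peaking at mid-gland, volume-conserving translation, with the
vacated crescent contoured as the spacer structure), and a surrogate dose.

The surrogate dose is deliberately not a beam model: prescription inside
the PTV, sigmoidal falloff with 3D distance to the PTV surface, 8 mm
80→20 % penumbra. It exists to give geometry-dependent RV55 values with
the correct monotone structure — rectal V55 decreases strictly as the
rectum–PTV gap grows until the high-dose region no longer reaches the
rectum, after which it is pinned at zero. Phantom cohorts therefore
reproduce *relationships* (positive ΔRV55 under displacement, overlap-dose
coupling), not the clinical endpoint scale: the phantom's fat convex rectum
also yields wall-to-CTV distances around 4 cm versus the clinical 2.2 cm.
Statistical claims always use model mode; geometric mode is the end-to-end
plumbing check.

## Problem sizes and reproducibility

Everything stochastic runs under explicit seeds. The test suite uses
cohorts of 21 (the published design), 200 replicate cohorts for the
retention envelope, 500 replicates for slope recovery and coverage,
n = 1000–10 000 draws for correlation/parameter calibration, a 3-patient
geometric-mode cohort for the full-pipeline smoke test, and 1–2 mm rasters
for the closed-form geometry comparisons. Retention of the two-stage
flowchart over simulated cohorts averages about 55 % — individual cohort
retention is dispersed, so the acceptance check brackets the mean in
[40 %, 80 %] rather than pinning a cohort-specific count, which is not
reproducible without the original per-patient data.

## Known limitations

* No DICOM import in this build: structures and dose are read from the
  documented JSON interchange formats (plus CSV cohorts). A DICOM-RT
  front end would slot in at `read_structure_json()`/`read_dose_json()`
  without touching anything downstream.
* The models are fitted to one institution's planning style (margins,
  optimization objectives, 60 Gy / 20 fx). Different PTV margins change the
  overlap metric and hence the predictions; adopters should refit with
  `stepwise_select()` on their own cohorts and recalibrate ω₁/ω₂.
* Predicted reductions above ~10 % are outside the observed training range
  and carry uncharacterized error (the package warns).
* The generator reproduces published *marginals* and assumed couplings,
  not the true joint anatomy distribution; passing calibration tests shows
  consistency with the printed summaries, not clinical validity.
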