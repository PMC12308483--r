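---
title: "Measuring left-ventricular wall-thickness heterogeneity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring left-ventricular wall-thickness heterogeneity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(madwt)
```

## The biomarker

Left-ventricular hypertrophy is usually summarised by totals — LV mass,
maximum wall thickness — but its *regionality* carries independent
information: pathological hypertrophy (hypertensive remodelling, HCM) tends
to thicken the wall unevenly, while physiological, exercise-related
hypertrophy is more uniform. `madwt` implements a heterogeneity biomarker on
the AHA 16-segment model: for each segment the *maximal* end-diastolic wall
thickness is measured, and

* `MeanWT` is the mean of the 16 segmental maxima,
* `MaxWT` is their maximum, and
* `MadWT` is the mean absolute deviation of the segmental maxima about their
  mean, `mean(|wt_s - MeanWT|)`, in mm.

A perfectly uniform ventricle has `MadWT = 0` whatever its mass; focal
thickening raises `MadWT` even when the mass stays normal.

## From label masks to segmental thickness

The measurement input is a short-axis stack of integer label masks
(`lv_mask_stack`): 0 background, 1 LV cavity, 2 LV myocardium, optionally
3 RV, with the voxel geometry attached. The pipeline is:

1. **Level allocation.** The stack's base-to-apex extent is split into
   basal/mid/apical thirds, as equal as possible, remainders going basal
   first then mid (10 slices → 4/3/3). The stack is assumed cropped to the
   ventricle's coverage; a slice whose myocardium is missing still occupies
   its level and simply contributes no rays, so its segments can come back
   `NaN`.
2. **Cavity centroid.** Area centroid of the (single, 4-connected) cavity
   component per slice.
3. **Angular reference.** Segment 1 starts at the anterior RV–LV insertion.
   If an RV label is present, the insertion is detected as the most
   counter-clockwise epicardial myocardium voxel adjacent to RV; otherwise
   the angle must be supplied in the stack metadata. Angles are measured
   from the image "up" direction, counter-clockwise as displayed (apex
   view).
4. **Ray casting.** From the centroid, rays are cast at 1° steps (the
   segmental maxima change by less than ~0.15 mm up to 2° steps on
   phantoms). Along each ray the myocardium indicator is sampled by
   bilinear interpolation at quarter-voxel steps; thickness is the distance
   from the first endocardial crossing of the 0.5 contour to the end of
   that contiguous myocardial run, both crossings refined by 1-D linear
   interpolation. Sub-voxel interpolation roughly halves the voxelisation
   error of a nearest-neighbour reading.
5. **Sector maxima.** Basal and mid levels have six 60° sectors, the apical
   level four 90° sectors, numbered counter-clockwise from the insertion.
   Each myocardium voxel is assigned to a sector by the angle of its own
   centre, and each sector is measured against *its own wall only*; this
   keeps a thick neighbouring sector from leaking into the interpolated
   boundary of a thin one. Rays are cast at angular *bin centres*
   (0.5°, 1.5°, …): a ray exactly along a sector discontinuity runs along
   the thickness step and is degenerate. The segment value is the maximum
   ray thickness over all rays of all slices of its level.

Two deliberate conventions deserve a note. The thickness operator is radial
ray-casting rather than a distance transform, because the per-segment
*maximum* of nearest-boundary distances systematically under-reports oblique
walls; a centerline-chord method is a possible extension point. And
measurement is purely in-plane — no long-axis correction for through-plane
obliquity — which matches how clinical short-axis measurements are made.

## Quality control

Within each subject's scan, segmental values strictly above
`Q3 + 3 × IQR` of that subject's measured segments are removed, with
quartiles computed by linear interpolation (type 7). The rule is an upper
fence only — the clinical failure mode it targets is a spuriously *thick*
segment from a segmentation error — applied in a single pass: the quartiles
are not recomputed after removal, so re-applying QC is a no-op. A value
exactly on the fence is retained. Subjects with fewer than 12 valid segments
are excluded and their indices set to `NaN`.

The fence is per-subject, not per-cohort: the rule reads as within-scan
cleaning of segmentation failures, and a per-cohort fence would remove the
genuinely hypertrophied. The package keeps the per-subject rule only; a
cohort-level screen, if wanted, belongs to the caller.

## Phantoms: the geometric oracle

`generate_phantom()` rasterises an analytic annulus: cavity inside a known
endocardial radius, epicardium stepped so each AHA sector has a designed
thickness, and an optional RV blob to exercise insertion detection. Because
the design thickness of every sector is known exactly, phantoms give the
measurement chain a ground truth with a computable error budget: at 0.5 mm
in-plane spacing the worst segmental error on stepped designs is ~0.34 mm
(within the half-voxel-diagonal budget), it halves with the spacing, and a
uniform phantom yields `MadWT` at numerical zero. The phantoms deliberately
do **not** model cine intensities, papillary muscles, the LV outflow tract,
trabeculation or motion — passing phantom tests demonstrates that the
geometry is measured correctly, not that segmentation of real images is
correct (segmentations are an input here).

## The cohort simulator

`generate_cohort()` produces cohorts in which every quantity the fitting
code is later asked to recover is known. Defaults emulate a UK-Biobank-scale
CMR population: age 64.6 ± 7.7 years, 48.1% male, 97.1% white, 3.5% current
smokers, BMI 26.5 ± 4.4 kg/m², hyperlipidaemia 31.8%, diabetes 6.1%, and
hypertension at 27.4% prevalence generated from a logistic model in age and
BMI (intercept solved for the marginal prevalence) so that the
propensity-matching stage faces real confounding. Sex-specific height
distributions reproduce the overall 170 ± 9.4 cm.

The wall-thickness biomarkers follow identity-link Gamma models — the same
family the risk-factor analysis fits, so parameter recovery is exact in
expectation. `MeanWT` has mean ≈ 7.1 mm (shape 55) and `MadWT` mean
≈ 0.97 mm (shape 11, giving median ≈ 0.94 and IQR ≈ 0.76–1.15), with
additive effects of age (0.05 mm per SD), sex, BMI, hypertension
(0.10 mm by default) and log-activity. The generator verifies that the
identity-link mean is positive for every subject and errors otherwise
rather than silently re-drawing. By default 16 segmental values are drawn
per subject — a zero-mean, unit-mean-absolute-deviation pattern scaled by
the subject's `MadWT` around their `MeanWT` — and the indices are derived
through the real QC/index code path; `segment_level = FALSE` draws the
indices directly (used in large replicate studies of the survival stage
where the segment-level detour adds nothing to what is measured).

Physical activity mimics the questionnaire structure: days per week
(categorical 0–7) and minutes per session (log-normal) for walking,
moderate and vigorous activity, combined as
`TPA = 3.3·walk + 4.0·moderate + 8.0·vigorous` MET-min/week. The component
parameters were calibrated once so the simulated median TPA is
≈ 2000 (Q1 ≈ 1140, Q3 ≈ 3350) MET-min/week; the accelerometer mean vector
is log-normal with median 27.6 mg, available only for the configurable
fraction passing the 72-hour calibrated-wear filter (default 40%).

Event times follow a Weibull proportional-hazards model (shape 1.2;
the baseline family is a simulator choice — Weibull for closed-form
inverse-transform sampling under PH) with linear predictor
`Σ β_k · (x_k − mean)/SD`, i.e. per-SD log hazard ratios; the default MACE
effect for `MadWT` is log(1.28) per SD. Administrative censoring at 7.1
years minus uniform entry jitter over 0–2.8 years gives follow-up
U(4.3, 7.1) with median 5.7 years; the slight right-skew of real accrual is
not reproduced, only the median. The Weibull *scale* is solved by
root-finding so the expected event fraction under the realised linear
predictors and censoring times matches the configured target (1.7% for
MACE, 0.6% HF, 2.5% arrhythmia, 1.5% death); an explicit `weibull_scale`
may be supplied instead, in which case the event fraction is whatever the
hazard implies (this is how the monotonicity of event rate in the log-HR is
tested at a fixed baseline). Covariates are drawn independently apart from
the built-in hypertension–age–BMI and biomarker–covariate links; real
cohort correlations (e.g. activity falling with age) are not modelled and
can be added through the configuration if needed.

## Statistical stages

**Risk-factor model.** `fit_gamma_glm()` fits a Gamma GLM with identity
link — additive covariate effects on the mm scale for a strictly positive,
right-skewed biomarker. Continuous predictors are standardised to SD units
(coefficients read mm per SD); the fit starts from the intercept-only
solution, and fitted means are checked to stay positive, failing loudly
otherwise.

**Standardisation.** `standardize()` divides by the analysis-sample SD
(computed after exclusions, before modelling) and keeps the SD map, so
per-unit and per-SD hazard ratios interconvert exactly:
`HR_SD = HR_unit^SD`. Binary covariates are never rescaled.

**Prognosis models.** `fit_cox()` fits Cox proportional-hazards models by
partial likelihood with Efron tie handling. The stepwise ladder
(`fit_cox_ladder()`) is: Model 1 biomarker only; Model 2 + cardiovascular
risk factors (age, sex, ethnicity, BMI, smoking, hyperlipidaemia,
hypertension, diabetes); Model 3 + LVEDVi and LVEF; Model 4 + LVMi. All
levels are fitted on the identical complete-case row set of the largest
model and strict nesting is asserted at run time. Separation (unbounded
coefficients) and event-free data raise errors.

**Discrimination.** Harrell's C is computed through
`survival::concordance` (ties in risk count ½) and is verified against a
brute-force O(n²) pair enumeration in the test suite. `delta_cindex()`
reports `ΔC = C_aug − C_ref` with a two-sided p-value from a paired
bootstrap over subjects (default 1000 resamples, seeded): both C-indices
are recomputed on each resample and
`p = 2·min(P(ΔC* ≤ 0), P(ΔC* ≥ 0))`. The bootstrap is the package's choice
of inference; identical models short-circuit to `ΔC = 0`, `p = 1`. One
property worth knowing: with rare events, ΔC increments of ~0.01 carry
wide bootstrap intervals — at 10,000 subjects and a 1.7% event fraction
(~170 events) such an increment is usually not distinguishable from zero,
which is why the package's power demonstration of `delta_cindex()` uses a
10% event-rate design (~1000 events) and why population studies of such
increments need very large event counts.

**Diagnostics.** `cox_diagnostics()` reports variance inflation factors
from auxiliary linear regressions of each design-matrix column on the
others (`VIF = 1/(1−R²)`; the conventional screen is VIF < 5), and a
proportional-hazards check that regresses each predictor's Schoenfeld
residuals on event time and tests the slope.

**Propensity matching.** `estimate_propensity()` fits a logistic model of
hypertension on age, sex, ethnicity, height, BMI, smoking, hyperlipidaemia
and diabetes. Full separation — the model predicting the indicator
perfectly — is an error; quasi-separation on individual rare covariates
(common in small strata, e.g. a handful of smokers all in one arm) leaves
usable scores and raises a warning instead. `match_pairs()` is greedy 1:1
nearest-neighbour matching without replacement: treated subjects in
descending score order (ties by id), each taking the unused control nearest
in score (distance ties to the lower-score side, then the lower id), no
caliper. Greedy matching is order-dependent and *not* optimal matching; the
documented order makes it deterministic given the scores. Balance is
reported as standardised mean differences before and after matching.

**Activity strata and comparisons.** `select_top_active()` keeps rows at or
above the `(1−fraction)` type-7 quantile of TPA, vigorous MET-min/week, or
the accelerometer mean vector (the latter restricted to valid-wear rows);
ties at the threshold are all included. `compare_biomarkers()` compares
nine biomarkers (MadWT, MaxWT, MeanWT, LVMi, LVEDVi, LVMVR, LVEF, GLS,
native T1) between matched groups: group medians with seeded
percentile-bootstrap 95% CIs (default 2000 resamples), two-sided
Mann–Whitney U (exact when both groups have ≤ 20 observations without
ties; normal approximation with tie and continuity correction otherwise),
a Bonferroni flag at `0.05/alpha_family` (default family = 9 biomarkers,
α ≈ 0.0056), and the relative difference of medians. Matching is done
within the activity stratum; matching before stratification is possible by
calling the pieces directly.

## Problem sizes and what the tests show

The test and acceptance suites run entirely on phantoms and simulated
cohorts: stepped phantoms at 1, 0.5 and 0.25 mm; one full cohort at
n = 37,080 for calibration, Model-2 recovery and the matched top-1%
contrast; 100 replicates at n = 37,080 for CI coverage of the design-point
hazard ratio (per-SD HR 1.28 at a 1.7% event fraction); 1000 replicates at
n = 5000 for the Wald test's type-I error; and 200 replicates of the
matched-comparison experiment at ~160 pairs and a +0.13 mm
hypertension-only MadWT shift. At that last design point the measured
detection rate is around 70–75% for flagging MadWT at the Bonferroni level
while keeping the seven null biomarkers unflagged — the Gamma dispersion of
MadWT (SD ≈ 0.29 mm, set by the cohort calibration) makes ~160 pairs
borderline for a 0.13 mm median contrast at α ≈ 0.0056, a fact the
acceptance suite measures and reports rather than hides.

Passing these suites shows the geometry is exact on analytic shapes, the
estimators recover known truths at the calibrated effect sizes, and the
inference is honest under the null. It does not validate segmentation of
real images, nor transfer of the simulator's independence assumptions to a
real population.

## Known limitations

* Thickness is radial from the cavity centroid; strongly non-convex or
  heavily trabeculated walls would need the centerline extension.
* Only end-diastole is modelled; no multi-phase analysis.
* The simulator draws most covariates independently; correlation structure
  beyond hypertension–age–BMI and the biomarker links is not emulated.
* The QC fence is per-subject by design; no cohort-level screening.
* ΔC bootstrap inference is approximate; no closed-form test is attempted.
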