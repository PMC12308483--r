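# madwt

Left-ventricular wall-thickness **heterogeneity** from short-axis CMR
segmentations, and its epidemiology.

Total measures of left-ventricular hypertrophy — LV mass, maximum wall
thickness — miss how *unevenly* the wall thickens, yet regionality is what
separates pathological remodelling (hypertension, HCM) from the uniform
hypertrophy of exercise. On the AHA 16-segment model, with `wt_s` the
maximal end-diastolic wall thickness of segment *s* (mm):

```
MeanWT = (1/16) Σ wt_s
MaxWT  = max_s wt_s
MadWT  = (1/16) Σ | wt_s − MeanWT |
```

`MadWT` (mean absolute deviation of maximum segmental wall thickness) is 0
for a perfectly uniform ventricle regardless of mass, and grows with focal
thickening. The package implements the full pipeline around it:

* **geometry** — per-segment maximal thickness from 3-D label masks
  (cavity/myocardium/RV) by radial ray-casting from the cavity centroid,
  with sub-voxel boundary interpolation and AHA sector maxima
  (`segment_wt()`, `radial_thickness()`, `rv_insertion_angle()`);
* **indices** — per-subject outlier QC (values above `Q3 + 3·IQR` removed;
  subjects with < 12 valid segments excluded), `MadWT`/`MaxWT`/`MeanWT`,
  questionnaire MET-minutes (`compute_tpa()`), BSA-indexed volumetrics
  (`index_volumetrics()`);
* **survival** — Gamma GLM (identity link) risk-factor models of MadWT,
  stepwise Cox prognosis Models 1–4 with per-SD hazard ratios, Harrell's
  C-index, bootstrap ΔC-index, VIF and Schoenfeld diagnostics
  (`fit_gamma_glm()`, `fit_cox_ladder()`, `delta_cindex()`);
* **psm** — propensity-score estimation, greedy 1:1 nearest-neighbour
  matching without replacement, top-10%/1% activity strata, and
  Bonferroni-corrected Mann–Whitney biomarker comparisons
  (`psm_compare()`);
* **synth** — analytic annulus phantoms with known per-sector thickness and
  cohort simulators with known covariate effects, hazard structure and
  censoring (`generate_phantom()`, `generate_cohort()`,
  `generate_activity()`), so every stage has an oracle.

## Worked example

Measure a stepped phantom whose design thicknesses are known, then fit the
cohort-level prognosis model on a simulated population:

```r
library(madwt)

design <- c(8,12,8,8,10,8, 9,8,8,11,8,8, 8,10,8,9)   # mm per AHA segment
ph   <- generate_phantom(phantom_spec(endo_radius = 20,
                                      sector_thickness = design,
                                      in_plane_spacing = 0.5))
prof <- segment_wt(ph)
compute_wt_indices(qc_segments(prof))
#> wt_indices (subject): MadWT 1.023, MaxWT 12.34, MeanWT 9.11 mm (16 segments)
```

The recovered segmental maxima sit within a third of a millimetre of the
design (`wt_02` = 12.34 vs 12; the systematic +0.3 is the voxelisation
budget at 0.5 mm spacing, and halves with the spacing). The design vector's
true MadWT is 1.0156 mm; the measured 1.023 reflects the same voxel-level
error.

```r
sim <- generate_cohort(cohort_sim_config(n = 20000, seed = 1))
sim
#> cohort_sim: n = 20000 (segment-level biomarkers)
#>   MACE: 319 events (1.59%)
#>   HF: 128 events (0.64%)
#>   arrhythmia: 493 events (2.46%)
#>   death: 319 events (1.59%)

fit_cox(sim$cohort, cox_model_spec("MACE", 2), per = "sd")
#> Cox model, endpoint MACE: n = 20000, events = 319, C-index = 0.709
#>              term               hr            p  scaling
#> 1           MadWT 1.32 (1.19-1.46) 6.550972e-08   per_sd
#> 2             age 1.60 (1.43-1.79) 2.112973e-16   per_sd
#> 3            male 2.35 (1.85-2.99) 4.330844e-12 per_unit
#> ...
```

The simulator's true per-SD hazard ratio for MadWT on the MACE-like
endpoint is 1.28; the fitted 1.32 (1.19–1.46) covers it. `print` truncation
aside, every predictor of the risk-factor set is reported with per-SD or
per-unit scaling as appropriate, and `fit$sd_map` converts between the two
exactly (`HR_sd = HR_unit^SD`).

The matched hypertension-vs-exercise comparison runs the same way:

```r
top1 <- psm_compare(sim$cohort, metric = "TPA", fraction = 0.01,
                    n_boot = 1000, seed = 2)
```

which selects the top-1% most active stratum, matches hypertensive to
non-hypertensive participants 1:1 on propensity, and compares nine CMR
biomarkers with bootstrap median CIs and Bonferroni-corrected Mann–Whitney
tests.

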