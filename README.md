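# scarshape

Scar characterization and corridor analysis for late gadolinium
enhancement cardiac MRI (LGE-CMR), in R.

After myocardial infarction, LGE-CMR shows dense scar ("core") as bright,
viable myocardium as dark, and a partially viable **border zone (BZ)** in
between. The border zone — and especially BZ **corridors** threading
through core — is the anatomic substrate for reentrant ventricular
tachycardia (VT), and thresholding-based scar maps derived from LGE-CMR
are used both to guide catheter ablation and to predict arrhythmia
recurrence afterwards. `scarshape` implements that analysis pipeline as
tested, reusable functions, together with synthetic phantoms and cohorts
that give every stage a ground truth.

## What it computes

Given a 3D short-axis LGE stack and a left-ventricular myocardium mask
(NIfTI in, NIfTI/VTK/CSV/JSON out):

* **PSI maps** — full-width-at-half-maximum normalization: each voxel's
  pixel signal intensity (PSI) in percent of a reference maximum, so half
  maximum is PSI 50 (`compute_psi()`).
* **Tissue classification** under a PSI window $(t_\ell, t_h)$: healthy
  below $t_\ell$, border zone in $[t_\ell, t_h]$, core above $t_h$, for
  the four standard windows 45–55, 40–60, 35–65, 30–70
  (`classify_psi()`, `psi_threshold_presets()`).
* **Masses** in grams (voxel count × voxel volume × 1.05 g/mL), with
  total enhancement = BZ + core exactly (`quantify_masses()`).
* **Conducting corridors** — 26-connected BZ components whose boundary is
  predominantly core — with per-corridor and total masses
  (`detect_corridors()`, `corridor_report()`).
* **Labeled tetrahedral meshes** and the two interface surface areas in
  cm²: healthy ↔ hyperenhancement (BZ + core) and BZ ↔ core
  (`build_labeled_mesh()`, `interface_area()`), plus a concentric-layer
  shell model for visualization and layer export
  (`build_layered_model()`, `write_layers_vtk()`).
* **Outcome statistics** — Mann–Whitney AUC with Youden-J optimal cutoff
  (ties broken toward the highest sensitivity, then the lower cutoff),
  Pearson correlation, paired between-threshold differences with t-based
  confidence intervals, and a per-metric × per-window ROC summary table
  gated at AUC > 0.7 (`empirical_roc()`, `youden_optimal()`,
  `pearson_r()`, `paired_difference()`, `table3_report()`).
* **Synthetic data** — an ellipsoidal-shell LV phantom with configurable
  scar patches, BZ rims and core-enclosed BZ channels at
  1.3 × 1.3 × 5 mm default resolution (`phantom_spec()`,
  `generate_phantom()`), and a synthetic patient cohort whose binary
  recurrence follows a stated logistic model on a chosen scar metric
  (`generate_cohort()`, `cohort_implied_auc()`).

See the vignette (`vignettes/scar-quantification.Rmd`) for the model
details, parameter choices and known limitations.

## Worked example

```r
library(scarshape)

# A transmural infarct spanning 280 degrees with three 6 mm BZ channels,
# partial-volume blur and noise:
patch <- scar_patch(
  angle_center_deg = 0, angular_extent_deg = 280,
  apicobasal_extent = 0.5, transmural_extent = 1,
  channels = list(bz_channel(-110, width_mm = 6),
                  bz_channel(0,    width_mm = 6),
                  bz_channel(110,  width_mm = 6)))
spec <- phantom_spec(scar_patches = list(patch),
                     noise_sigma = 4, blur_sigma_mm = c(1, 1, 1.5),
                     seed = 7)
stack <- generate_phantom(spec)
scar_metrics(stack)
```

```
    config total_enhancement_g bz_mass_g scar_g total_corridors corridor_mass_g
1 psi45_55                73.8       9.6   64.2               3           0.311
2 psi40_60                77.2      13.8   63.4               3           0.612
3 psi35_65                78.2      15.5   62.6               3           0.949
4 psi30_70                78.7      16.5   62.1               3           1.260
  surface_healthy_he_cm2 surface_bz_core_cm2
1                   97.8                33.4
2                   45.1                42.5
3                   34.8                44.8
4                   37.5                45.4
```

Reading the table: as the PSI window widens from 45–55 to 30–70, border
zone mass rises (9.6 → 16.5 g) and core mass falls (64.2 → 62.1 g) while
total enhancement stays their exact sum; all three inserted channels are
recovered as corridors at every window, with corridor mass growing with
the window width (0.31 → 1.26 g).

```r
field <- classify_psi(compute_psi(stack), threshold_config(40, 60))
detect_corridors(field)
#> <corridor_set> 3 corridor(s), total mass 0.612 g

cohort <- generate_cohort(27, seed = 1)
empirical_roc(cohort$surface_healthy_he_cm2_psi45_55, cohort$recurrence)
#> <roc_result> AUC 0.654 (13 pos / 14 neg, higher_predicts_positive)
#>   Youden cutoff 77.2: sens 0.846, spec 0.500, J = 0.346
```

At n = 27 the empirical AUC is a noisy estimate of the generating model's
implied AUC (`cohort_implied_auc()` ≈ 0.79); the parameter-recovery test
shows the estimator is centred once cohorts are large.

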