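---
title: "Quantifying ventricular scar, corridors and tissue interfaces from LGE-CMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ventricular scar, corridors and tissue interfaces from LGE-CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarshape)
```

## The analysis

After myocardial infarction, late gadolinium enhancement cardiac MR
(LGE-CMR) shows dense scar ("core") as bright signal, viable myocardium as
dark, and a partially viable rim — the border zone (BZ) — in between. The
border zone, and in particular BZ corridors threading through core, form
the substrate for reentrant ventricular tachycardia. `scarshape`
implements the standard thresholding pipeline used to characterize this
substrate, plus the outcome statistics used to relate the derived metrics
to post-ablation arrhythmia recurrence:

1. **PSI mapping** (`compute_psi()`). Voxel signal intensity inside the
   left-ventricular myocardium mask is normalized to a reference maximum
   and expressed as *pixel signal intensity* (PSI) in percent. This is the
   full-width-at-half-maximum (FWHM) construction: a voxel at half the
   maximal myocardial signal has PSI 50.
2. **Tissue classification** (`classify_psi()`). A threshold window
   $(t_\ell, t_h)$ splits the myocardium: PSI $< t_\ell$ healthy, PSI in
   $[t_\ell, t_h]$ border zone, PSI $> t_h$ core. The four standard
   windows 45–55, 40–60 (conventional), 35–65 and 30–70 are provided by
   `psi_threshold_presets()`.
3. **Masses** (`quantify_masses()`). Class masses in grams are voxel
   count × voxel volume × density. Total enhancement is BZ + core by
   construction, and healthy + enhancement equals total myocardial mass
   exactly — these identities are contracts, not approximations.
4. **Corridors** (`detect_corridors()`). Conducting channels are
   26-connected BZ components whose face-adjacent boundary inside the
   myocardium is predominantly core.
5. **Interfaces** (`build_labeled_mesh()`, `interface_area()`). A labeled
   tetrahedral mesh yields the two interface surface areas: healthy ↔
   hyperenhancement (BZ + core) and BZ ↔ core, in cm².
6. **Outcome statistics** (`empirical_roc()`, `youden_optimal()`,
   `pearson_r()`, `paired_difference()`, `table3_report()`). Per-patient
   metrics against binary recurrence: Mann–Whitney AUC, Youden-J optimal
   cutoffs, correlations, and paired between-threshold differences.

Every stage is testable without patient data through the synthetic
left-ventricle phantom (`phantom_spec()`, `generate_phantom()`) and the
synthetic cohort generator (`generate_cohort()`), both of which carry
known ground truth.

## PSI normalization choices

The reference maximum defaults to the 98th percentile of in-mask signal
(`mode = "robust_percentile"`), with values above it clipped to 100. A
literal global maximum (`mode = "global_max"`) is retained for exact
small-phantom arithmetic, but a single hot voxel would otherwise rescale
the whole map, so the robust mode is the analysis default. Normalization
is global over the myocardium mask rather than per slice: a per-slice
reference would make PSI discontinuous across slice boundaries and let
the same tissue change class between adjacent slices. Whether clinical
tools normalize globally or per layer is not documented publicly; the
global choice is flagged for sensitivity analysis.

PSI is invariant to positive rescaling of the raw signal and preserves
ordering under monotone max-preserving transforms; both invariances are
property-tested.

## Boundary assignment and the threshold window

Voxels landing exactly on a cutoff are assigned to the border zone
(closed interval), consistent with the usual "40%–60% is BZ" phrasing.
The choice only matters for exact-boundary values, which occur in
noise-free phantoms; it is documented because floating-point comparisons
at the boundary are tolerance-sensitive. Widening the window can only
grow the BZ set and shrink the core set — a monotonicity property tested
by brute force, and the mechanism behind the familiar cohort-level
pattern of rising BZ mass and falling core mass with wider windows.

## Masses

Masses are computed on the voxel grid, not on the layered shell: the
voxel path gives an exact, resolution-independent contract, whereas a
shell-based mass would depend on the layer count. Myocardial density
defaults to 1.05 g/mL, the standard tissue value. At the default
1.3 × 1.3 × 5 mm spacing one voxel is 0.00845 mL, so e.g. 1000 BZ voxels
weigh 1000 × 0.00845 × 1.05 = 8.8725 g.

## Corridor detection

"Regions of BZ surrounded by scar core" is operationalized as: group BZ
voxels into 26-connected components; classify each component's
face-adjacent (6-connected) non-BZ neighbours inside the myocardium as
core or healthy contacts; report the component as a corridor when core
contacts make up at least `core_fraction_min` (default 2/3) of all
contacts and the component has at least `min_voxels` (default 5) voxels.
The permissive 26-connectivity groups diagonal runs of BZ into one
channel, while the conservative face-adjacency for contacts avoids
counting corner touches as enclosure. Both knobs are exposed. The
contact-fraction rule deliberately admits both a fully core-enclosed
channel and a true isthmus whose ends open into healthy tissue; whether
clinical channel detection demands the latter is not publicly specified.
Detection is a pure function of the label field, with components reported
in a canonical order (minimum linear voxel index).

## Meshes and interface areas

Each in-mask voxel is split into five tetrahedra inheriting the voxel
label, using the mirrored (checkerboard) variant of the 5-tet
decomposition so that neighbouring voxels agree on face diagonals and
every interior facet is shared by exactly two elements. Volumes are
conserved exactly: the mesh volume equals voxel count × voxel volume to
rounding error. A second path builds the mesh from the concentric-layer
shell model (prisms between consecutive layers, split into tetrahedra
with diagonals chosen consistently from global vertex indices, element
labels from the classified PSI at element centroids — centroid assignment
is deterministic, unlike majority voting with ties). Inverted layer
surfaces are rejected with an error naming the slice and angle, mirroring
the real-world failure mode in which volumetric meshing fails for some
patients.

Interface area offers two estimators:

* `method = "facet"` (default) sums raw facet areas — the exact staircase
  boundary. It conserves every interior facet exactly once, is exact for
  axis-aligned interfaces, and is the unambiguous bookkeeping choice used
  in the mass/area reports. Its known systematic property is that the
  staircase area of a *smooth* boundary exceeds the true area (for a
  sphere the factor approaches 1.5 as the grid refines, since the mean of
  $|n_x| + |n_y| + |n_z|$ over the sphere is 3/2).
* `method = "normal_weighted"` weights each facet by the cosine between
  the facet normal and the local boundary orientation, estimated from the
  gradient of a Gaussian-smoothed class indicator (smoothing length
  `smooth_sigma_mm`, default 2.6 mm). This is the standard convergent
  voxel surface-area estimator: it recovers a 10 mm sphere's $4\pi r^2$
  to well under 5% at 1.3 mm voxels and leaves flat axis-aligned
  interfaces untouched away from edges.

Because published cohort areas come from proprietary postprocessing whose
surface construction (smoothed vs voxelized) is unstated, absolute cm²
values are not comparable across implementations; orderings and
arithmetic relations are. The reports therefore use the conservation-
exact facet estimator, with the weighted estimator available where a
smooth-surface value is wanted.

## The layered shell model

`build_layered_model()` represents the wall as `n_layers` concentric
triangulated surfaces from endocardium to epicardium, the representation
used clinically for scar visualization and layer exports. Rays are cast
per slice from the mask centroid; the first contiguous in-mask run along
each ray defines the wall, and layer $k$ sits at relative depth
$(k-1)/(n_\mathrm{layers}-1)$. Degenerate rays (no wall) raise an error
naming the slice rather than being patched. The default of 9 layers keeps
layer spacing at or below ~0.7 mm for typical 5–10 mm walls. Ray casting
at 5 mm slice spacing clips the polar caps, so layer-path volumes are
held to a looser tolerance (8%) than voxel-path volumes (2%) in the test
suite.

## The phantom generator

The phantom is a truncated-ellipsoid idealization of a short-axis LGE
acquisition: an ellipsoidal myocardial shell (semi-axes in mm, long axis
along the slice normal) on a regular grid at 1.3 × 1.3 × 5 mm default
spacing, with scar patches defined in angular / apicobasal / transmural
coordinates. A patch's interior is core; a BZ rim of configurable
thickness (default 2.6 mm, two in-plane voxels) lines it laterally,
apicobasally and — for non-transmural patches — on the epicardial side
(subendocardial infarcts touch the endocardium, so no rim is placed
there). Channels are BZ tubes carved through the core at fixed angle and
mid-wall depth, with default margins that keep them strictly
core-enclosed, so the ground-truth corridor count equals the channel
count by construction. The rim and channel geometry are produced by
parametric shrinking of the patch in its own coordinates, which keeps the
construction analytic and deterministic.

Signal is the per-class mean plus additive Gaussian noise, clipped at
zero. Defaults: healthy 20, BZ 50, core 100 arbitrary units — BZ at
exactly half maximum, the FWHM premise — and `noise_sigma = 4` (core SNR
25, a typical LGE figure). Gaussian rather than Rician noise is a
deliberate simplification: the object under test is the thresholding
pipeline, not MR physics. An optional partial-volume blur
(`blur_sigma_mm`, default 0) smooths the noise-free tissue signal within
the mask before noise is added, emulating the scanner point spread at
tissue boundaries; mask-normalized smoothing avoids darkening toward the
unmodelled blood pool.

Two phantom regimes are used in the test suite, reflecting two distinct
mechanisms in real images:

* **Channels phantom** (blur 1 × 1 × 1.5 mm, noise 4, 6 mm channels): the
  boundary gradation is thin, channels survive classification at all four
  windows, and corridor *count* is stable across windows while corridor
  *mass* grows with window width — the qualitative cohort pattern.
* **Gradation phantom** (blur 3 mm isotropic, noise 2, no channels):
  thick gradation makes the apparent core shrink as the window widens, so
  the mean BZ–core interface area is smallest at 30–70 — the direction
  reported for cohort data.

No single crisp three-level phantom reproduces both patterns, because
both arise from boundary gradation and tissue heterogeneity that a
piecewise-constant model lacks. What passing these tests shows is that
the pipeline responds to window changes with the correct signs and
conserved quantities — not that phantom magnitudes match any patient
cohort; phantoms also omit inversion-recovery contrast behaviour, coil
inhomogeneity, motion and through-plane partial volume with blood.

## The cohort generator and its implied AUC

`generate_cohort()` draws per-patient metrics for the four windows from
log-normal distributions whose scale parameters (recorded in the
`distributions` attribute of the output) match the magnitudes typical of
ischemic VT-ablation cohorts — BZ mass of order 10–40 g, interface areas
of order 70–120 cm². A shared latent severity factor (64% of log-scale
variance) plus a per-metric factor induce realistic between-metric
correlation and near-perfect rank correlation of the same metric across
windows. Recurrence is Bernoulli with
$\mathrm{logit}\,p = \beta_0 + \beta \cdot \text{metric}$; the default
effect (`cohort_effect()`: slope 0.035 per cm² on the healthy–HE surface
at PSI 45–55, intercept centring the marginal recurrence rate near one
half) implies a population AUC of about 0.79, the discrimination level
reported for surface metrics.

`cohort_implied_auc()` computes that implied AUC independently of the
ROC code, by quadrature over the generating log-normal: with density $f$
and $p(m)$ the logistic recurrence probability,
$\mathrm{AUC} = \Pr(M_1 > M_0)$ for $M_1 \sim p f / \int p f$ and
$M_0 \sim (1-p) f / \int (1-p) f$. Parameter recovery (mean empirical AUC
over 50 cohorts of n = 2000 within ±0.01 of the implied value) closes the
loop between the generator and the ROC machinery.

## ROC conventions

The AUC uses the rank (Mann–Whitney) formulation with ties contributing
one half. Candidate cutoffs are midpoints between consecutive sorted
unique values plus ±∞, so the reported cutoff never coincides with an
observed value. The Youden-optimal point maximizes
$J = \text{sens} + \text{spec} - 1$; ties are broken toward the highest
sensitivity and then toward the lower cutoff — without a stated
tie-break, published cutoffs are not reproducible. Direction defaults to
"higher metric predicts recurrence" (all scar metrics trend that way),
with an explicit flag to invert. Operating points in `table3_report()`
are reported only for AUC strictly greater than 0.7, following the usual
reporting gate; AUC p-values use the Hanley–McNeil asymptotic formula and
are informational.

The "cumulative J" sometimes used to rank windows is not computed: its
definition (sum? mean? which metrics?) is not stated publicly, so it is
left out rather than guessed.

## Problem sizes and numerical tolerances

The test-suite and acceptance problem sizes are chosen so the full run
completes in a few minutes on one core while keeping Monte-Carlo error
well below the tolerances tested: phantoms on 64 × 64 × 24 grids (about
17 000 myocardial voxels), 20-phantom batches for monotonicity, spheres
on 24³ isotropic grids, null-cohort AUC at n = 5000 (tolerance 0.02
against a standard error of about 0.008), and AUC recovery over 50
cohorts of n = 2000 (tolerance 0.01 against a standard error of about
0.002). Exact identities (mass partition, facet conservation, J
arithmetic) are asserted to rounding error, not to a tolerance.

## Known limitations

* Endo/epicardial segmentation is an input; the package does not contour
  real images.
* Corridor detection is voxel-based (3D); a per-layer 2D mode is out of
  scope, as are channel length and orientation analytics.
* Meshes are analysis artifacts, not simulation-ready (no quality
  optimization, no fiber architecture).
* Repeated-measures ANOVA F statistics and survival analysis of
  time-to-recurrence are outside the package's statistics scope.
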