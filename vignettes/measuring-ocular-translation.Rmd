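---
title: "Measuring translatory eyeball movement from multi-gaze orbital MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring translatory eyeball movement from multi-gaze orbital MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

The eye is usually modelled as a ball joint: a sphere rotating about a
fixed centre. But the globe is suspended in orbital fat, not mounted on a
shaft, so its *position* can also change when gaze changes — a small
translatory movement of a fraction of a millimetre. Measuring it from
multi-gaze orbital MRI requires separating three superimposed motions:

1. **gaze rotation** of the globe about (approximately) its own centre —
   large, tens of degrees;
2. **globe translation** within the orbit — the signal of interest,
   roughly 0.4–0.7 mm, i.e. *below the slice thickness* of a typical
   acquisition;
3. **head motion** between acquisitions — up to a couple of millimetres
   even with a fixated head, which would otherwise swamp the signal.

`oculotrans` implements the full chain: head motion is removed by rigid
registration driven *only by static (non-ocular) tissue*; the globe is
extracted by seeded region growing; its position is summarised by the
centroid (the arithmetic mean position of all member voxels — invariant
to rotation of a symmetric globe, hence a pure translation probe); and
the centroid displacement between central and eccentric gaze is reported
as an in-plane distance and direction.

## Coordinate and angle conventions

All volumes live in one patient frame: +x toward the patient's left,
+y anterior, +z superior; voxel `i` (zero-based) along an axis sits at
`i * spacing` mm. Horizontal gaze is analysed in the axial (x–y) plane,
vertical gaze in the sagittal (y–z) plane; displacements are 2D in-plane
(the out-of-plane component is recorded separately but not analysed).

Directions use a two-argument arctangent. A one-argument arctangent of
the coordinate ratio is quadrant-ambiguous — it cannot distinguish a
postero-lateral from an antero-medial movement — so `atan2` is the only
construction consistent with direction values beyond ±90°. In the axial
plane, angles are measured with medial = 0°, anterior = 90°,
lateral = ±180°, posterior = −90°; because adduction and abduction are
mirror-symmetric about the midline, the lateral–medial component of the
*right* eye is negated so both eyes read in a single (left-eye)
convention. In the sagittal plane anterior = 0°, up = +90°, down = −90°;
no mirroring is needed. Both a signed (−180°, 180°] and a positive
[0°, 360°) reporting range are available (`wrap_angle()`), since both
conventions appear in practice. When the displacement distance is zero
the direction is flagged undefined rather than reported as 0°.

## The synthetic phantom

Real multi-gaze orbital MRI of a cohort is not redistributable, so every
stage is validated by parameter recovery on a digital phantom
(`generate_phantom()`). The phantom emulates what the measurement needs:

* two ellipsoidal globes (bright vitreous interior, 1 mm dark scleral
  shell, embedded dark lens) in bright orbital fat, with bony plates, a
  midline septum and four point landmarks as static tissue;
* T2-like intensities (vitreous 1.0, fat 0.6, sclera 0.2, bone 0.05,
  landmarks 0.9) — fixed but arbitrary; registration and segmentation are
  deliberately intensity-scale invariant;
* a secondary gaze = globe rotation about its own centre (30° horizontal
  / 20° vertical by default, matching the fixation-target geometry of the
  emulated acquisition) **plus** a configurable globe-centre translation
  (defaults: 0.7 mm along the gaze for horizontal, 0.43 mm opposite for
  vertical — the effect sizes the pipeline must resolve);
* a random rigid head motion (≤ 2°, ≤ 2 mm by default) applied to the
  whole scene per secondary acquisition, and additive Gaussian noise
  (2% of vitreous intensity). Rician noise and MR physics (bias fields,
  k-space artefacts) are deliberately out of scope; passing recovery
  tests therefore demonstrates correctness of the measurement chain, not
  robustness to every real-acquisition artefact.

Rendering is analytic with partial-volume anti-aliasing: voxels within
half a voxel diagonal of a surface are resolved on a `supersample`^3
subvoxel grid (default 3). Ground truth (rotation, translation, head
motion, truth masks, globe centre and lens centroid per eye) is returned
for every volume, and the whole output is bit-reproducible from the seed.

One honest wrinkle: the *binarised* truth mask (voxel in mask iff
occupancy ≥ 0.5) does not converge to the analytic ellipsoid volume —
centre-sampling can be coincidentally excellent, so its error is not
monotone in the oversampling factor. Monotone convergence holds for the
partial-volume estimate (`ellipsoid_occupancy_volume_ml()`), and the test
suite asserts exactly that, alongside a non-increasing error check for
the binary mask between supersample 1 and 3.

## Registration: static tissue only

`build_static_mask()` takes foreground tissue (≥ 15% of the robust
intensity maximum) and removes the globes dilated by 3 mm, so neither the
eye nor peri-ocular tissue that moves with it can drive the alignment.
The 3 mm default covers the globe translation (≤ 1 mm), head motion
(≤ 2 mm) and segmentation boundary uncertainty.

`register_static()` maximises normalized cross-correlation over the
static mask. Choices that matter:

* **NCC, not mutual information** — the volumes are same-modality,
  same-session; NCC is smooth, cheap, and intensity-scale invariant.
* **Smoothed metric** — both volumes are 3×3×3 box-smoothed before
  sampling. This widens the capture basin and stops the optimum NCC from
  being dominated by trilinear-interpolation error at sharp edges, which
  would otherwise leave a misleading residual on perfectly aligned data.
* **Deterministic optimisation** — a fixed 3³ grid of translation starts
  (±3 mm) at a 2× pooled resolution, Nelder–Mead refinement, then a
  full-resolution polish, all in a fixed evaluation order: the same
  inputs always give the same transform. If the optimum leaves ±10° /
  ±10 mm the report is flagged failed instead of raising.
* **Residual gate** — the alignment report carries
  `residual = 1 − masked NCC`; the default pass threshold 0.02 was set
  on phantoms at the default noise level and replaces a two-rater visual
  agreement check with an auditable number (it should be relaxed for
  real acquisitions with physiological variation).

The recovered transform is applied to the *centroid as a point*. Masks
are never resampled for measurement — resampling would add interpolation
error to a sub-voxel signal and is the reason the pipeline can resolve
displacements below the slice thickness.

## Segmentation and centroid

`segment_globe()` reproduces a tolerance-wand selection in 3D: 6-connected
region growing from a seed (auto-located as the brightest smoothed voxel
on the requested side), including voxels within 25% of the seed
intensity, followed by a one-voxel closing, cavity filling (the lens) and
largest-component selection. Two failure modes are detected rather than
silently tolerated: a region that touches the grid boundary (leak
through the scleral opening or a bad tolerance) and a region that is a
shell around a large cavity (> 20% of its filled volume — the signature
of a seed placed in orbital fat, which grows *around* the globe). A
minimum plausible globe volume of 1 ml guards against speckle seeds.
The segmented proxy is the vitreous interior; an optional `shell_mm`
dilation includes the scleral shell for sensitivity analyses (the
centroid of a closed shell coincides with the interior's for a symmetric
globe, so the default proxy does not bias translation).

The centroid is the *unweighted* mean of member voxel centres scaled
per-axis by the anisotropic spacing — deliberately not intensity-weighted,
to match the "mean position of all points in the shape" definition and to
stay noise-robust.

The gaze-rotation angle itself is estimated from the rotation of the
centroid-to-lens vector between gazes (`estimate_rotation_deg()`): both
endpoints move with the globe, so a common translation cancels exactly.
This estimator is this package's own choice, validated only on phantoms;
how such angles are measured on real data varies between studies.

## Cohort statistics

`select_one_eye()` removes inter-eye correlation by analysing one eye per
subject, assigned right/left alternately over a seed-shuffled subject
order. Summaries are mean ± SD with a normal-quantile 95% CI
(`mean ± 1.96·sd/√n`); the z-quantile rather than t is used because it is
what reproduces the published interval arithmetic this package checks
itself against. Directions are summarised twice: arithmetically on the
wrapped angles, and circularly (vector-mean direction, circular SD
`sqrt(−2 ln R̄)`); the two diverge for dispersed or antipodal samples and
both are reported rather than adjudicated. Between-gaze contrasts use the
pooled-variance two-sample t-test; biometry associations use Pearson
correlation with the t-transform p-value. Degenerate inputs error
explicitly (zero variance, n < 2) except the one well-defined case:
identical constant samples compare with t = 0, p = 1.

`simulate_cohort()` generates displacement cohorts with known means, SDs,
circular direction distributions and a chosen Pearson correlation between
distance and axial length (distances are generated as a linear function
of axial length plus scaled noise, so the population R is exact). Its
defaults describe a healthy adult cohort — axial length 25.27 ± 1.71 mm,
ocular volume ≈ 7.5 ml, orbital volume 26 ± 3.2 ml, horizontal
displacements ≈ 0.69 mm toward the gaze and vertical ≈ 0.43 mm opposite —
and parameter-recovery tests check that the estimators return what the
generator put in (estimates within two standard errors at n = 200).

## Numerical choices and problem sizes

* Voxel positions are `index × spacing` (zero-based); every module shares
  this convention, so centroid shifts under integer-voxel mask shifts are
  exact.
* Region-growing, components, morphology and hole filling use
  6-connectivity with fixed scan order; ties in auto-seeding resolve to
  the first maximum. All randomness (phantom noise, head motion, eye
  selection, cohort simulation) flows from explicit integer seeds.
* The test suite runs at bench scale — 96×96×48 voxels at the target
  spacing with globes scaled to axial length ≈ 15 mm so the required
  5 mm containment margin holds, and 72×72×44 for orchestration tests —
  chosen so the full suite exercises every stage end-to-end in minutes.
  The acceptance script runs the anatomical scale (axial length
  25.27 mm, 67 slices of 0.6 mm) on a laterally trimmed 160×160×67 grid.
* Phantom geometry validation requires the outer globe plus its largest
  translation to clear the grid by ≥ 5 mm on every axis; violations are
  a hard error ("geometry error"), as is a degenerate semi-axis or a
  fixation angle outside [0°, 45°] (0° is allowed to express identity
  and rotation-null experiments).

## Limitations

* The phantom's orbit is geometric (ellipsoids, slabs, point landmarks);
  it contains no extraocular muscles, eyelid, optic nerve or
  susceptibility artefacts, and noise is Gaussian, not Rician.
* Displacements are analysed in two fixed planes, as 2D quantities;
  torsion and full 3D direction are out of scope.
* DICOM series import is not provided (no DICOM reader in the supported
  dependency set); NIfTI-1 is the interchange format.
* Registration is strictly rigid (6 DOF); scanner-induced scaling or
  deformable effects are not modelled.
* The residual threshold (0.02) and wand tolerance (0.25) are phantom
  defaults; real acquisitions need their own calibration, which is why
  both are surfaced as arguments rather than constants.
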