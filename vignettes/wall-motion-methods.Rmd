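---
title: "Measuring vessel wall deformation with a camera ring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vessel wall deformation with a camera ring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmotion)
```

## The measurement problem

Abdominal aortic aneurysms rupture when the weakened wall can no longer bear
its load, and the pulsatile deformation of the wall is one of the few
mechanical quantities accessible without contact. One way to study it ex vivo
is to film a patient-specific elastic phantom, perfused by a pulsating pump,
with a ring of cameras, and to quantify how the silhouette seen by each
camera swells and relaxes over the cardiac cycle. This package implements
that measurement chain end to end, together with a synthetic scene generator
that provides exact ground truth, so every stage can be validated without any
physical rig.

The chain is: **rectification** (undo lens distortion) →
**segmentation** (Otsu threshold, largest bright object) →
**area measurement** (pixel count of the object) →
**shape deformation factor** (ratio of each frame's area to a motionless
reference frame) → **millimetre displacement** (equivalent-circle
conversion) → **summaries and agreement statistics**.

## The shape deformation factor

For camera $c$ and frame $i$, let $F_{ic}$ be the segmented silhouette area
and $F_c$ the area in that camera's reference frame (the first frame of the
sequence, acquired with the vessel motionless). The shape deformation factor
is

$$n_i = \frac{F_{ic}}{F_c}.$$

It is a pure area ratio: dimensionless, independent of the pixel scale, and
equal to 1 in the reference frame by construction. `deformation_factors()`
computes it and refuses non-positive areas, naming the offending frame.

Published summaries report wall deformation in millimetres, but an area
ratio does not determine a local displacement without a shape assumption.
The package uses the minimal one, concentric circular dilation: the
reference silhouette is assigned its equivalent-circle radius
$r_\mathrm{ref} = \sqrt{F_c/\pi}\cdot s$ (with $s$ the mm-per-pixel scale),
and frame $i$'s displacement is

$$\Delta r_i = r_\mathrm{ref}\,(\sqrt{n_i} - 1),$$

positive for expansion. This is exact for a uniformly dilating circle and is
the area-equivalent mean radial excursion otherwise. Whether published
millimetre values are radii or diameter changes is generally not stated;
this radial convention is this package's choice and is applied consistently
(`factor_to_displacement()`).

Per-cycle amplitudes are max − min displacement within consecutive windows
of one pulsation period (60/pulse-rate seconds, `cycle_amplitudes()`),
matching the "contraction and relaxation" excursion reporting used
clinically; a trailing partial cycle is discarded. The average wall
deformation (AWD) of a subject is the mean ± sample SD (n − 1) of its 4
positions × 4 probes amplitude table (`summarize_wall_deformation()`). The
sample-SD choice is deliberate: the published per-patient SDs reproduce only
with the n − 1 denominator.

## Camera model and rectification

Cameras follow the pinhole model with the five-coefficient Brown–Conrady
distortion (radial $k_1, k_2, k_3$, tangential $p_1, p_2$): normalized
coordinates $x_n = X/Z$, $y_n = Y/Z$ map to

$$x_d = x_n(1 + k_1 r^2 + k_2 r^4 + k_3 r^6) + 2p_1 x_n y_n + p_2(r^2 + 2x_n^2),$$

symmetrically for $y_d$, then to pixels through $(f_x x_d + c_x,\; f_y y_d + c_y)$.
The pixel convention used everywhere is: origin at the centre of the
top-left pixel, x right, y down, 0-based. With zero coefficients the model
is a pure pinhole, and rectification returns its input bit-for-bit.

Undistortion inverts this map by fixed-point iteration in normalized
coordinates (default tolerance $10^{-8}$, 50 iterations; non-convergence is
an error reporting the residual). Rectification resamples by inverse
mapping with bilinear interpolation; out-of-frame sources are filled with 0,
which is safe because the scene is a bright object on a dark background.

Calibration (`calibrate_camera()`) estimates intrinsics and distortion from
at least three views of a planar grid: homography-based closed-form
initialisation of $f_x, f_y, c_x, c_y$, pose extraction per view, then
Levenberg–Marquardt refinement of all intrinsics, the five distortion
coefficients and the per-view poses against the reprojection error. On
noise-free synthetic views the generating parameters are recovered to
better than $10^{-3}$ relative error. Under realistic detection noise the
radial coefficients are identifiable only if the target fills a good part
of the field of view — over a narrow radius range the $r^2$, $r^4$ and
$r^6$ terms are nearly collinear and individual coefficients trade off
against each other even while the fitted distortion field is accurate.

## Segmentation

Frames are converted to gray with the fixed luma weights
0.299/0.587/0.114 (rounded half-up), thresholded with Otsu's method — the
integer threshold in 0..255 maximising the between-class variance of the
256-bin histogram — and binarised with foreground strictly above the
threshold. Ties take the smallest maximising threshold. These conventions
(strict inequality, smallest maximizer) are pinned down because stock
implementations differ in exactly these corners; the test suite checks the
implementation against an exhaustive 256-candidate search on random images.

The object of interest is the largest connected component under
8-connectivity (4-connectivity would split diagonal necks of noisy
silhouettes), with ties broken by the smallest top-left bounding-box
corner. Its **area is the foreground pixel count**, not the polygon area of
the traced contour: the pixel count is integer-exact and is what the
deformation factor consumes. The contour (Moore-neighbour boundary trace)
is retained for the caliper width — the largest point-pair distance of the
boundary — which serves as the silhouette diameter estimate
(`static_diameter()`). No morphological cleanup is applied by default; an
optional small-object removal (`min_object_px`) exists but is off in every
validation run.

## The synthetic scene generator

`render_phantom_sequence()` emulates what one camera of the ring records.
The phantom cross-section is a polygon with radial wall position

$$r(\theta, t) = r_0(\theta) + a(\theta)\,\frac{1 - \cos(2\pi f t)}{2},$$

so frame 0 is motionless and each cycle peaks at the full amplitude
$a(\theta)$. Both $r_0$ and $a$ may be functions of angle; the default is a
43 mm Fourier-perturbed circle (an irregular ~86 mm sac) pulsating at
72 min⁻¹ with a 4 mm amplitude, filmed for 10 cycles at 30 frames/s. Each
camera views the cross-section rotated to its ring angle; the silhouette is
centrally projected at the object distance (0.35 m by default), rasterised,
optionally warped through the lens-distortion model, shaded by a linear
illumination gradient (10% across the width by default, to exercise the
threshold's robustness) and corrupted with seeded additive Gaussian noise
(SD 2 gray levels) clipped to [0, 255].

Design choices worth stating:

* **Silhouette rendering, not 3D elasticity.** Each camera measures a 2D
  silhouette area, which is all the deformation factor consumes, so a
  cross-section slab projected through the pinhole model is sufficient and
  gives closed-form ground truth. A consequence: silhouette area is
  invariant to in-plane rotation, so under the slab model all cameras see
  identical deformation factors up to noise and rasterisation — per-camera
  differences in real data come from genuinely 3D geometry the generator
  does not model.
* **No anti-aliasing.** A pixel is foreground exactly when its centre lies
  inside the silhouette polygon (scanline even-odd rule). This makes pixel
  counts reproducible and lets a square whose edges fall between pixel
  centres rasterise to an exact pixel rectangle, so ground-truth area
  ratios can be met *exactly*, not just approximately.
* **Ground truth is analytic.** True areas are shoelace areas of the
  projected boundary polygon before rasterisation; true factors and
  displacements derive from those. Rasterised pixel counts converge to the
  analytic areas as resolution grows and agree within 1% for silhouette
  radii above ~50 px.
* **Default working resolution 480 × 270** (an aspect-preserving scale-down
  of the native 1920 × 1080), chosen so a full 10-cycle validation runs in
  seconds; the full resolution remains available through `rig_geometry()`.
* **Reproducibility.** The same seed gives bit-identical sequences;
  different seeds change only the noise, never the geometry.

What passing synthetic tests does **not** show about real data: lighting
inhomogeneity beyond a linear ramp, specular highlights on a wet phantom,
refraction by the water-filled container, true 3D surface deformation, and
camera-specific sensor artefacts are all outside the generator. Results on
the synthetic scenes validate the algorithmic chain, not the physical rig.

## The rig geometry

The default ring has nine cameras 0.70 rad apart (covering the circle to
within one spacing), each able to sweep in 0.17 rad steps over a 0.70 rad
range, at object distances of 0.30–0.40 m. The sweep is represented
one-sidedly as offsets $0, s, 2s, 3s$ (all multiples of the step strictly
inside the range), giving $9 \times 4 = 36$ distinct angular stations under
the defaults — the canonical station count for this geometry; a symmetric
±4-step sweep would give 81 distinct stations, which is not how acquisition
sessions are counted. Camera angles map to reporting positions by nearest
cardinal direction: anterior 0°, left 90°, posterior 180°, right 270°
(`position_label()`).

## The two-square verification protocol

Accuracy is verified with two planar squares of known sides (0.05 m and
0.10 m) imaged one after the other, centred and perpendicular to the
optical axis, at 0.30/0.35/0.40 m. The measured deformation factor of the
big-square frame against the small-square reference has true value
$(0.10/0.05)^2 = 4$ exactly. `run_square_protocol()` renders replicate
sequences, runs the full chain and reports mean ± SD and the accuracy
$100(1 - |m - e|/e)$ % (the relative-error complement; the protocol's
accuracy metric is defined here, as published reports never write the
formula). With ideal optics and zero noise the chain recovers 4 exactly at
focal lengths where both squares rasterise to integer pixel sides, and
within 0.5% at the default 480 × 270 configuration.

Replicate-to-replicate spread needs a word. With anti-aliasing off and
~180 gray levels between the modes, additive sensor noise of a few levels
can never flip a pixel across the threshold, so repeated renders of an
identical scene measure identical areas. In the physical protocol the
spread over hundreds of analyses comes from re-placing and re-imaging the
square; the generator models this as seeded sub-pixel jitter of the square
centre (SD 0.5 px, off in the ideal-optics setting). Replicates default to
220 per condition to mirror the protocol's sample size and are configurable
down for quick runs. The "with water" condition is a metadata tag plus a
mild contrast perturbation: immersion was found not to affect acquisition,
so no refraction physics is modelled and the measured ratio is expected to
be — and is — identical under the tag.

## Agreement statistics

`bland_altman()` reports the bias (mean of paired differences), sample SD
of differences and 95% limits of agreement bias ± 1.96 SD; the half-width
1.96 SD is reported as the agreement interval half-range. `students_t()`
is the classic pooled-variance two-sample test (group sizes are equal in
this design; two constant equal samples return t = 0, p = 1 by convention),
and `spearman()` is the Pearson correlation of mid-ranks. Statistics are
computed at full precision; only the reporting layer rounds (two decimals,
four for p). The package ships the published four-patient paired
wall-deformation table (`wall_deformation_reference()`) as a plain-text
fixture; recomputing from it reproduces the published per-patient AWD
means and SDs exactly at two decimals, the overall bias of 0.00 mm, and
left/right per-side bias magnitudes of 0.01 mm.

## Acquisition contract

Real capture used a producer–consumer architecture: a capture thread
feeding a lossless saving queue (bounded only by memory) and a size-1
preview queue whose frames are dropped while the previewer is busy.
Threads and OS priorities are out of scope here; what matters downstream
is the observable contract — every produced frame is saved, in order, and
preview losses never touch the measurement path. `simulate_acquisition()`
replays that contract as a deterministic event simulation (configurable
consumer speeds, explicit overflow error when the saving bound is
exceeded) so the invariants are testable.

## Numerical choices and degenerate inputs

* Undistortion: fixed-point iteration, tol $10^{-8}$ (normalized), max 50
  iterations; divergence is an error, never a silent fallback.
* Otsu: degenerate (constant) images are an error; the threshold is the
  smallest maximizer; foreground is strictly above the threshold.
* Rasterisation: pixel-centre rule, even-odd; polygon edges exactly on a
  pixel centre count that pixel as inside on the entering edge and outside
  on the leaving edge (half-open spans), so abutting polygons never double
  count.
* Deformation: non-positive areas, empty masks, too-short sequences and
  incomplete summary tables are errors naming the offending frame or cell.
* Validation problem sizes: unit tests run single cycles at 240 × 135 or
  480 × 270; the full-chain parameter-recovery check runs the complete
  default study (10 cycles, 30 fps, 72 min⁻¹, 480 × 270) and recovers the
  generated 4 mm radial amplitude within 2% in every cycle.

## Known limitations

* The equivalent-circle displacement is a modelling convention; for
  strongly non-circular dilation patterns it reports the area-equivalent
  mean excursion, not the local wall displacement at a given angle.
* The slab-silhouette generator cannot produce per-camera differences in
  the deformation factor; validating the position-binning logic against
  genuinely 3D motion requires real multi-view data.
* Calibration assumes a planar target and a static camera; extrinsic
  multi-camera bundle adjustment, fisheye models and rolling shutter are
  out of scope.
* Published hardware-specific constants (per-distance square factors such
  as 1.0017, the headline accuracy percentages) characterise the physical
  cameras, not the algorithm, and are deliberately not reproduction
  targets for the synthetic chain.
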