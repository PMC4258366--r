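---
title: "Single-plane model-to-image registration for hip kinematics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-plane model-to-image registration for hip kinematics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipkin)
```

## The measurement problem

Skeletal kinematics measured with skin markers suffer from soft-tissue
artifact. A radiographic alternative is to track the bones themselves: a
subject-specific volumetric bone model (from CT) is posed in a virtual
replica of the radiographic scene, a digitally reconstructed radiograph
(DRR) is rendered, and the six degree-of-freedom pose of the bone is
adjusted until the DRR matches the measured projection. Done frame by frame
over a movement sequence, this yields pelvic and femoral poses, from which
clinical joint angles follow.

`hipkin` implements that pipeline for a single-plane (one detector) setup:

1. a projection model of a point X-ray source and a flat-panel detector,
   with source calibration from fiducials;
2. a ray-casting DRR renderer over a density volume;
3. image-similarity registration (normalized cross-correlation, or an
   exclusive-disjunction silhouette mismatch count) driven by a staged
   derivative-free search;
4. anatomical coordinate frames for pelvis and femur and Euler-angle
   kinematics normalized to the movement cycle;
5. a synthetic phantom generator and an RMS accuracy protocol emulating a
   known-displacement stage experiment, so the whole pipeline is testable
   without any imaging data.

## Coordinate conventions

**World frame.** The upper-left corner of the detector panel is the world
origin; x runs along the panel horizontally (mediolateral), y vertically
(superoinferior), and z = x × y points from the panel toward the source
(right-handed; the panel is the plane z = 0). The default panel is
420 × 420 mm at 0.274 mm/pixel, with the source 1000 mm above the panel
center.

**Poses.** A pose is three translations (mm, world axes) plus three
rotations (degrees) applied intrinsically about the moving x, then y, then
z axis; `R = Rx %*% Ry %*% Rz` acting on model coordinates, followed by the
translation. Composition and inversion go through 4 × 4 homogeneous
matrices, so no sequence ambiguity can accumulate. Rotations pivot about
the *model origin*; bone models and phantoms are therefore stored with
their centroid near the model origin and carry their world placement in
the translation. (Pivoting about a point far from the bone couples
rotations and translations almost degenerately and conditions the
registration search badly — this is why the convention is fixed here.)

**Anatomical frames.** The pelvic frame has its origin at the midpoint of
the bilateral anterior superior iliac spines (ASIS), x toward the subject's
left along the ASIS line, z in the anterior pelvic plane (both ASIS plus a
mid-pubic landmark) pointing superiorly, y = z × x anteriorly. The femoral
frame has its origin at the femoral head center (given, or fitted to head
surface points by least-squares sphere), x parallel to the transepicondylar
axis (lateral to medial), z perpendicular to x in the plane through the
origin and the TEA midpoint, pointing proximally, and y = z × x. Segment
angles decompose the frame's rotation relative to the world by the same
intrinsic x → y → z sequence: for the pelvis (anterior tilt +, upward
obliquity, contralateral rotation +), for the femur (flexion +, adduction
+, internal rotation +). Hip angles decompose the femoral frame expressed
in the pelvic frame — computed from the relative rotation, never as a
difference of segment angles. Left-side data should be mirrored across the
sagittal plane (`pose_mirror_x()`) so one sign convention serves both
sides.

The Euler sequence itself is a convention: no sequence is canonical, and
angle values beyond small ranges depend on it. The x → y → z order used
here puts flexion/tilt first, matching the clinical reading of the axis
labels. The mid-pubic landmark (`PUBIS`) is the minimal third point that
fixes the anterior pelvic plane.

## DRR rendering

Each detector pixel's value is the line integral of the trilinearly
interpolated volume density along the ray from the source to the pixel
center, computed with a fixed-step midpoint rule and clipped to the
volume's bounding box; voxels outside the grid contribute zero. The
default step is half the smallest voxel spacing. Values are left in
line-integral units (density × mm) rather than mapped through an
exponential attenuation law: the correlation metric is invariant to
monotone intensity maps, so the extra nonlinearity would change nothing
while costing dynamic range.

Two consequences checked by the test suite: integrals are exactly linear
in density, and halving the step changes smooth-phantom images by well
under 1%, so the step default is not a sensitive tuning knob. Coarse
search passes decimate *pixels* (render every k-th ray), never the volume,
so the projective geometry stays exact across resolutions.

## Registration

The similarity metric is the Pearson correlation of pixel values (NCC)
between the rendered DRR and the measured frame, maximized over the six
pose parameters; a silhouette mismatch count (XOR of binarized images,
minimized) is available as an alternative. The search is a staged
coarse-to-fine Nelder–Mead simplex: by default pixel decimation 4, 2, 1,
with per-stage evaluation budgets and parameter tolerances down to
0.01 mm / 0.01° — an order below the accuracy the pipeline is expected to
deliver. Each stage restarts the simplex until the pose moves less than
the stage tolerance or the budget is spent. The search is deterministic:
identical inputs give bit-identical poses. Sequences are tracked by
initializing each frame at the previous frame's result.

**Evaluation region.** NCC is evaluated over the whole image by default.
The seemingly natural alternative — evaluating only over the nonzero-DRR
footprint — makes the evaluation region pose-dependent, and under image
noise this biases the depth estimate: shrinking the silhouette (moving the
bone toward the panel) prunes noisy edge pixels and spuriously raises the
correlation. On the synthetic protocol this produced a systematic
out-of-plane error near −1 mm (all noise realizations shifted the same
way), which the fixed whole-image region removes entirely. The support
region remains available (`region = "support"`) for cluttered frames where
locality matters more.

**Windowed rendering.** At every evaluation, rays are cast only inside the
projection of the volume's bounding box (padded by a few pixels); the rest
of the image is exactly zero anyway. This is a pure speed optimization —
it changes no pixel value.

Out-of-plane translation (world z) is searched like any other axis but is
the weakly constrained one: a single-plane view senses depth only through
magnification. The accuracy report therefore separates in-plane from
out-of-plane RMS, and the test suite checks (as a statistical tendency,
not per run) that out-of-plane error exceeds in-plane error.

## Synthetic phantoms and the accuracy protocol

The phantom generator stands in for a cadaveric accuracy experiment in
which bones fixed to a stage are moved to known poses and imaged
repeatedly. Two bone-like phantoms are provided: a femur-like solid
(spherical head — whose center is the exact `HEAD_CENTER` landmark —,
neck, shaft, and two unequal condylar bulges carrying `MED_EPI`/`LAT_EPI`;
deliberately asymmetric so every rotation axis is observable in one
projection) and a pelvis-like flared shell with `LASIS`/`RASIS`/`PUBIS`
protrusion apices. Landmarks are stored exactly as constructed, so
frame-building on phantoms is error-free by design. Smooth phantoms have
Gaussian-tapered edges (default width 3 mm): a binary phantom would make
the correlation metric piecewise-flat at the pixel scale and stall the
simplex.

The default experiment geometry uses the real panel (420 mm, 0.274
mm/pixel) with the pixel pitch coarsened ×8 (about 191 × 191 pixels) and
the phantom centered 500 mm from the panel (magnification 2). The default
accuracy protocol renders a femur-like phantom (96³ voxels at 1.5 mm) at
10 ground-truth poses drawn uniformly within ±10 mm and ±10° of the
reference placement, with 3 independent Gaussian-noise realizations per
pose at σ = 1% of the clean image's intensity range — mirroring three
repeated exposures per stage position — and registers each of the 30
frames starting from the truth offset by +3 mm and +3° on every axis. The
report pools translational residuals over all axes, poses and repeats into
one RMS (with in-plane and out-of-plane also reported separately) and
rotational residuals — the intrinsic x → y → z decomposition of
`R_truth⁻¹ R_est` — over the three axes into another. All randomness
(pose sweep, noise streams) derives from one master seed through per-frame
substreams, so the protocol is bit-reproducible and frames are
statistically independent.

Problem sizes were chosen so the full protocol runs in minutes on one CPU
core: the unit-test suite uses coarser variants (e.g. 48³ voxels at 3 mm
with a ×16-coarsened panel) of the same physical setup.

What passing this protocol does and does not show: the phantom has
realistic scale, smooth density and asymmetric shape, but no cortical /
trabecular texture, no soft-tissue background, no scatter or beam
hardening, and one bone per frame (no occlusion by the contralateral side
or by the other bone of the joint). Real radiographs carry both more
information (bone texture sharpens the similarity optimum) and more
nuisance structure (background gradients, overlapping anatomy). The
synthetic result validates the geometry, the renderer, the optimizer and
the error accounting — not the clinical image quality of any particular
detector.

## Numerical choices and degenerate inputs

* Calibration solves for the source position only (the world frame is
  pinned to the panel), by Nelder–Mead followed by BFGS on the summed
  squared reprojection residuals; ≥ 4 non-coplanar fiducials are required
  and coplanarity is detected by singular-value ratio.
* Sphere fitting uses the algebraic linear least-squares form; coplanar
  point sets are rejected the same way.
* Euler decomposition flags `|ry| > 89°` as gimbal-proximate and still
  returns values; compose-then-decompose is identity to 1e−9° away from
  that band (checked over 1000 random triplets).
* Otsu binarization refuses constant images; projection refuses points at
  or beyond the source plane; cropping refuses all-zero volumes; the
  experiment generator refuses poses that push the phantom outside the
  field of view, naming the offending pose.
* Ties in cycle extrema are broken toward the earliest percent-cycle.
* MetaImage (text header + raw) round-trips spacing and origin exactly;
  NIfTI-1 stores them as 32-bit floats, so sub-micrometre discrepancies
  are possible there. The PNG writer is 8-bit (R library limit); TIFF
  output is 16-bit and is the native frame format.

## Known limitations

Single-plane depth weakness is intrinsic, not an implementation artifact:
expect out-of-plane errors several times the in-plane ones at matched
noise. Joint translations (e.g. femoral head center shift) are not
reported — only rotations. No image-intensifier distortion model is
included (flat panels are assumed distortion-free). The optimizer is a
local search: initialization must be within the capture range (a few
pixels / degrees at the coarsest stage), which frame-to-frame tracking
provides for all but the first frame.
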