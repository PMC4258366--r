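# hipkin

Single-plane 3D-to-2D model-to-image registration for skeletal kinematics.

`hipkin` tracks the six degree-of-freedom pose of a volumetric bone model
(CT-like density volume) in a sequence of radiographic projections from a
flat-panel detector, and turns the tracked pelvis and femur poses into
clinical joint angles. It is aimed at motion-analysis and orthopaedics
researchers who measure hip kinematics radiographically instead of with
skin markers, and at anyone who needs a self-contained, fully synthetic
test bed for 2D/3D registration accuracy.

## What it computes

**Pose recovery.** For each measured frame the package renders a digitally
reconstructed radiograph (DRR) of the posed bone model — the line integral
of trilinearly interpolated density along each source-to-pixel ray — and
maximizes the normalized cross-correlation

NCC(I, D(θ)) = corr(I, D(θ)),  θ = (tx, ty, tz, rx, ry, rz)

between the DRR `D(θ)` and the measured image `I` over the six pose
parameters (translations in mm, intrinsic x→y→z rotations in degrees),
using a staged coarse-to-fine Nelder–Mead search. An exclusive-disjunction
(XOR) silhouette mismatch count is available as an alternative metric.
Sequences are tracked frame-to-frame.

**Kinematics.** Anatomical frames are built from landmarks — the pelvic
frame from both anterior superior iliac spines and the pubis (anterior
pelvic plane), the femoral frame from the head center and the
transepicondylar axis — and segment/hip angles are the intrinsic x→y→z
Euler decomposition of the tracked rotations (pelvic tilt/obliquity/
rotation; femoral and hip flexion/adduction/rotation; flexion, adduction
and internal rotation positive). Angle series are resampled onto a 0–100%
movement cycle.

**Accuracy.** A synthetic phantom generator (femur-like and pelvis-like
smooth density volumes with exactly known landmarks) and a
known-displacement protocol measure pose-recovery accuracy as RMS errors,
split into in-plane, out-of-plane and rotational components.

## Worked example

Track a femur-like phantom through a short synthetic motion and report the
recovery accuracy:

```r
library(hipkin)

v <- make_phantom(phantom_spec("femur_like", grid_size = c(48, 48, 48),
                               spacing = c(3, 3, 3)))
g <- desk_geometry(16)                       # 420 mm panel, coarsened pixels
truths <- lapply(0:3, function(k) pose(210 + 2 * k, 210 - k, 500,
                                       rx = 5 * k, rz = -k))
frames <- lapply(truths, function(p) render_drr(v, p, g)$pixels)

cfg <- registration_config(stages = list(
  list(downsample = 2L, max_evaluations = 400L, tol_mm = 0.1, tol_deg = 0.1),
  list(downsample = 1L, max_evaluations = 150L, tol_mm = 0.01, tol_deg = 0.01)))
res <- track_sequence(v, frames, g, pose(211, 209, 501, 1, 0, 1), cfg)
results_table(res)
#>   frame  tx  ty    tz        rx         ry        rz metric converged
#> 1     1 210 210 500.0 -0.004641  0.0082211 -0.005895      1      TRUE
#> 2     2 212 209 500.1  4.991836 -0.0008979 -1.014866      1     FALSE
#> 3     3 214 208 500.1  9.996548  0.0025420 -2.000434      1      TRUE
#> 4     4 216 207 500.0 14.992561 -0.0032357 -3.042567      1     FALSE

rms_report(res, truths)
#> accuracy report over 4 frames
#>   in-plane RMS:     0.0021 mm
#>   out-of-plane RMS: 0.0573 mm
#>   translation RMS:  0.0331 mm (all axes pooled)
#>   rotation RMS:     0.0139 deg (all axes pooled)
```

The recovered poses match the ground truth to hundredths of a millimetre
in-plane; the out-of-plane (depth) axis is an order of magnitude weaker,
as expected for a single-plane view, where depth is sensed only through
magnification.

Anatomical angles from tracked poses:

```r
ff <- femur_frame(v$landmarks$HEAD_CENTER, v$landmarks$MED_EPI,
                  v$landmarks$LAT_EPI)
pf <- pelvis_frame(c(120, 0, 0), c(-120, 0, 0), c(0, 0, -100))
kin <- compute_kinematics((0:3) / 3.5,
                          pelvis_poses = lapply(1:4, function(k) pose()),
                          femur_poses = lapply(res, `[[`, "pose"),
                          pf, ff)
series <- normalize_cycle(kin)   # 101 points over 0..100% of the cycle
extrema(series, "hip_flexion")
```

## Command line

A thin shell entry point (`inst/cli/hipkin`) exposes the pipelines:

```sh
hipkin phantom  --out DIR [--config cfg.yaml] [--seed N]
hipkin calibrate --fiducials fids.csv --geometry init.yaml --out cal.yaml
hipkin render   --volume v.nii.gz --pose 210,210,500,0,0,0 --geometry g.yaml --out drr.tif
hipkin register --volume v.nii.gz --image frame.tif --geometry g.yaml --init POSE --out result.json
hipkin track    --volume v.nii.gz --images DIR --geometry g.yaml --init POSE --out poses.csv
hipkin angles   --pelvis-poses p.csv --femur-poses f.csv \
                --pelvis-landmarks plm.json --femur-landmarks flm.json --out angles.csv
hipkin evaluate --out report.json [--config cfg.yaml] [--seed N]
```

Volumes are NIfTI or MetaImage with a JSON landmark sidecar; frames are
16-bit TIFF with a linear-scale sidecar; geometry is YAML/JSON; all
randomness flows from one `--seed`.

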