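#' Least-squares sphere fit
#'
#' Fits a sphere to >= 4 non-coplanar points by the algebraic linear
#' least-squares formulation (`|p|^2 = 2 c.p + (r^2 - |c|^2)`), e.g. to
#' estimate the femoral head center from sampled head-surface points.
#'
#' @param points n x 3 matrix of surface points, mm.
#' @return List with `center` (length 3), `radius`, and `rms` (RMS radial
#'   residual, mm).
#' @export
fit_sphere <- function(points) {
  pts <- rbind3(points)
  if (nrow(pts) < 4)
    stop("degenerate configuration: at least 4 points are required")
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("degenerate configuration: points are coplanar")
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  r <- sqrt(rowSums(sweep(pts, 2, center)^2))
  list(center = unname(center), radius = unname(radius),
       rms = sqrt(mean((r - radius)^2)))
}

#' Anatomical coordinate frame
#'
#' Origin plus three orthonormal right-handed axes (columns of `axes`:
#' x mediolateral, y anteroposterior, z proximodistal), in the bone model's
#' coordinates.
#'
#' @param origin Length-3 origin, mm.
#' @param axes 3 x 3 matrix whose columns are the x, y, z axes.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin, axes) {
  origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3, 3)
  stopifnot(length(origin) == 3)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9)
    stop("frame axes must be orthonormal")
  if (det(axes) < 0) stop("frame axes must be right-handed")
  structure(list(origin = origin, axes = axes), class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("anatomical frame at (%.2f, %.2f, %.2f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  for (i in 1:3)
    cat(sprintf("  %s = (%+.4f, %+.4f, %+.4f)\n", c("x", "y", "z")[i],
                x$axes[1, i], x$axes[2, i], x$axes[3, i]))
  invisible(x)
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate direction (zero vector)")
  v / n
}

#' Pelvic anatomical frame from the anterior pelvic plane
#'
#' Origin at the midpoint of the bilateral anterior superior iliac spines
#' (ASIS); x along the bilateral-ASIS line toward the subject's left
#' (RASIS -> LASIS); z in the anterior pelvic plane (the plane of both ASIS
#' and the pubis), perpendicular to x and pointing superiorly (away from the
#' pubis); y = z x x, pointing anteriorly.
#'
#' @param LASIS,RASIS,PUBIS Landmark positions, model mm. `PUBIS` is a
#'   single mid-pubic landmark fixing the anterior pelvic plane.
#' @return An [anatomical_frame()].
#' @export
pelvis_frame <- function(LASIS, RASIS, PUBIS) {
  LASIS <- as.numeric(LASIS); RASIS <- as.numeric(RASIS)
  PUBIS <- as.numeric(PUBIS)
  origin <- (LASIS + RASIS) / 2
  x <- normalize3(LASIS - RASIS)
  w <- origin - PUBIS
  wperp <- w - sum(w * x) * x
  if (sqrt(sum(wperp^2)) < 1e-9)
    stop("degenerate anterior pelvic plane: landmarks are collinear")
  z <- normalize3(wperp)
  y <- cross3(z, x)
  anatomical_frame(origin, cbind(x, y, z))
}

#' Femoral anatomical frame from head center and epicondyles
#'
#' Origin at the femoral head center; x parallel to the transepicondylar
#' axis (TEA), oriented lateral -> medial; z perpendicular to x in the plane
#' through the origin and the TEA midpoint, pointing proximally (from the
#' TEA midpoint toward the head); y = z x x (anterior).
#'
#' @param head_center Femoral head center, model mm — given directly or
#'   estimated with [fit_sphere()].
#' @param MED_EPI,LAT_EPI Medial and lateral epicondyle landmarks, model mm.
#' @return An [anatomical_frame()].
#' @export
femur_frame <- function(head_center, MED_EPI, LAT_EPI) {
  head_center <- as.numeric(head_center)
  MED_EPI <- as.numeric(MED_EPI); LAT_EPI <- as.numeric(LAT_EPI)
  x <- normalize3(MED_EPI - LAT_EPI)
  mid <- (MED_EPI + LAT_EPI) / 2
  w <- head_center - mid
  wperp <- w - sum(w * x) * x
  if (sqrt(sum(wperp^2)) < 1e-9)
    stop("degenerate femoral frame: head center lies on the TEA")
  z <- normalize3(wperp)
  y <- cross3(z, x)
  anatomical_frame(head_center, cbind(x, y, z))
}

#' Segment angles of a tracked bone relative to the world
#'
#' Expresses the anatomical frame under the tracked world pose and
#' decomposes its rotation relative to the world axes by the intrinsic
#' x -> y -> z sequence. For the pelvis the triplet reads (anterior tilt,
#' upward obliquity, contralateral rotation); for the femur (flexion,
#' adduction, internal rotation). Within ~1 degree of gimbal lock
#' (`|second angle| > 89` degrees) the attribute `gimbal` is set to `TRUE`
#' and values are still returned.
#'
#' @param world_pose Tracked [pose()] of the bone model.
#' @param frame The bone's [anatomical_frame()] (model coordinates).
#' @return Named numeric `c(rx, ry, rz)` in degrees, attribute `gimbal`.
#' @export
segment_angles <- function(world_pose, frame) {
  stopifnot(inherits(frame, "anatomical_frame"))
  M <- pose_rotation(as_pose(world_pose)) %*% frame$axes
  matrix_to_euler(M)
}

#' Hip angles: femur relative to pelvis
#'
#' Decomposes the rotation of the femoral anatomical frame expressed in the
#' pelvic anatomical frame (both taken at their tracked world poses) by the
#' intrinsic x -> y -> z sequence: (flexion +, adduction +, internal
#' rotation +). Computed from the relative rotation directly, not as a
#' difference of pelvic and femoral segment angles.
#'
#' @param pelvis_pose,femur_pose Tracked world [pose()]s.
#' @param pelvis_frame,femur_frame The bones' [anatomical_frame()]s.
#' @return Named numeric `c(rx, ry, rz)` in degrees (flexion, adduction,
#'   internal rotation), attribute `gimbal`.
#' @export
hip_angles <- function(pelvis_pose, pelvis_frame, femur_pose, femur_frame) {
  stopifnot(inherits(pelvis_frame, "anatomical_frame"),
            inherits(femur_frame, "anatomical_frame"))
  Rp <- pose_rotation(as_pose(pelvis_pose)) %*% pelvis_frame$axes
  Rf <- pose_rotation(as_pose(femur_pose)) %*% femur_frame$axes
  matrix_to_euler(crossprod(Rp, Rf))
}

kin_channels <- c("pelvic_tilt", "pelvic_obliquity", "pelvic_rotation",
                  "femoral_flexion", "femoral_adduction", "femoral_rotation",
                  "hip_flexion", "hip_adduction", "hip_rotation")

#' Kinematic time series from tracked pelvis and femur poses
#'
#' @param times Frame times, seconds.
#' @param pelvis_poses,femur_poses Lists of [pose()]s, one per frame.
#' @param pelvis_frame,femur_frame [anatomical_frame()]s of the two bones.
#' @return Data frame with `time` and the nine angle channels
#'   `pelvic_tilt, pelvic_obliquity, pelvic_rotation, femoral_flexion,
#'   femoral_adduction, femoral_rotation, hip_flexion, hip_adduction,
#'   hip_rotation` (degrees).
#' @export
compute_kinematics <- function(times, pelvis_poses, femur_poses,
                               pelvis_frame, femur_frame) {
  stopifnot(length(times) == length(pelvis_poses),
            length(times) == length(femur_poses))
  rows <- lapply(seq_along(times), function(k) {
    pp <- segment_angles(pelvis_poses[[k]], pelvis_frame)
    ff <- segment_angles(femur_poses[[k]], femur_frame)
    hh <- hip_angles(pelvis_poses[[k]], pelvis_frame,
                     femur_poses[[k]], femur_frame)
    data.frame(time = times[k],
               pelvic_tilt = pp[["rx"]], pelvic_obliquity = pp[["ry"]],
               pelvic_rotation = pp[["rz"]],
               femoral_flexion = ff[["rx"]], femoral_adduction = ff[["ry"]],
               femoral_rotation = ff[["rz"]],
               hip_flexion = hh[["rx"]], hip_adduction = hh[["ry"]],
               hip_rotation = hh[["rz"]])
  })
  do.call(rbind, rows)
}

#' Normalize a kinematic series to the movement cycle
#'
#' Linearly interpolates every angle channel onto 101 evenly spaced points
#' covering 0-100% of the cycle window `[t_start, t_end]`.
#'
#' @param samples Data frame with a `time` column and numeric angle columns.
#' @param t_start,t_end Cycle window, seconds, inside the sampled range.
#' @return Data frame with `percent_cycle` (0..100) and the interpolated
#'   channels; class `kinematic_series`.
#' @export
normalize_cycle <- function(samples, t_start = min(samples$time),
                            t_end = max(samples$time)) {
  stopifnot(is.data.frame(samples), "time" %in% names(samples),
            nrow(samples) >= 2)
  if (!(t_start < t_end))
    stop("cycle window must satisfy t_start < t_end")
  if (t_start < min(samples$time) - 1e-9 || t_end > max(samples$time) + 1e-9)
    stop("cycle window lies outside the sampled time range")
  xout <- seq(t_start, t_end, length.out = 101)
  out <- data.frame(percent_cycle = seq(0, 100, length.out = 101))
  for (ch in setdiff(names(samples), "time")) {
    out[[ch]] <- approx(samples$time, samples[[ch]], xout = xout,
                        rule = 2)$y
  }
  class(out) <- c("kinematic_series", "data.frame")
  out
}

#' Extreme values of a kinematic channel over the cycle
#'
#' @param series A cycle-normalized series from [normalize_cycle()].
#' @param channel Channel name, e.g. `"hip_flexion"`.
#' @return List with `max`, `at_max` (% cycle), `min`, `at_min`. Ties are
#'   broken toward the earliest % cycle.
#' @export
extrema <- function(series, channel) {
  if (!channel %in% names(series))
    stop("unknown channel: ", channel)
  y <- series[[channel]]
  if (!length(y)) stop("empty series")
  pc <- series$percent_cycle
  imax <- which.max(y); imin <- which.min(y)
  list(max = y[imax], at_max = pc[imax], min = y[imin], at_min = pc[imin])
}

#' Write a cycle-normalized kinematic series and its extrema summary
#'
#' Writes the angle table as CSV (`percent_cycle` plus the nine channels)
#' and, optionally, a JSON summary holding per-channel extrema.
#'
#' @param series A `kinematic_series`.
#' @param path Output CSV path.
#' @param summary_path Optional JSON path for the extrema summary.
#' @return `path`, invisibly.
#' @export
write_kinematics <- function(series, path, summary_path = NULL) {
  write.csv(series, path, row.names = FALSE)
  if (!is.null(summary_path)) {
    chans <- setdiff(names(series), "percent_cycle")
    summ <- lapply(chans, function(ch) extrema(series, ch))
    names(summ) <- chans
    jsonlite::write_json(summ, summary_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}
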