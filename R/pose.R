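#' Six degree-of-freedom rigid pose
#'
#' A pose holds the rigid placement of a bone model in world coordinates:
#' three translations in millimetres along the world axes and three rotations
#' in degrees, applied intrinsically about the moving x, then y, then z axis.
#' Applying a pose to a model point `m` gives the world point
#' `R(rx, ry, rz) %*% m + t`.
#'
#' @param tx,ty,tz Translations, mm.
#' @param rx,ry,rz Rotations, degrees, intrinsic x -> y -> z sequence.
#' @return An object of class `pose`, a named numeric vector of length 6.
#' @examples
#' p <- pose(tx = 5, rx = 30)
#' pose_compose(p, pose_invert(p))
#' @export
pose <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  p <- c(tx = as.numeric(tx), ty = as.numeric(ty), tz = as.numeric(tz),
         rx = as.numeric(rx), ry = as.numeric(ry), rz = as.numeric(rz))
  if (any(!is.finite(p))) stop("pose parameters must be finite")
  structure(p, class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("pose: t = (%.4f, %.4f, %.4f) mm, r = (%.4f, %.4f, %.4f) deg\n",
              x[["tx"]], x[["ty"]], x[["tz"]], x[["rx"]], x[["ry"]], x[["rz"]]))
  invisible(x)
}

as_pose <- function(x) {
  if (inherits(x, "pose")) return(x)
  x <- as.numeric(x)
  stopifnot(length(x) == 6)
  pose(x[1], x[2], x[3], x[4], x[5], x[6])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix from intrinsic x-y-z Euler angles
#'
#' @param rx,ry,rz Angles in degrees.
#' @return A 3x3 rotation matrix equal to `Rx(rx) %*% Ry(ry) %*% Rz(rz)`.
#' @export
euler_to_matrix <- function(rx, ry, rz) {
  a <- deg2rad(rx); b <- deg2rad(ry); c <- deg2rad(rz)
  ca <- cos(a); sa <- sin(a)
  cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  matrix(c(
    cb * cc,                 ca * sc + sa * sb * cc,  sa * sc - ca * sb * cc,
    -cb * sc,                ca * cc - sa * sb * sc,  sa * cc + ca * sb * sc,
    sb,                      -sa * cb,                ca * cb
  ), nrow = 3, ncol = 3)
}

#' Intrinsic x-y-z Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]. Near gimbal lock (`|ry| -> 90` degrees)
#' the x and z angles are not separately identifiable; the returned vector
#' then carries the attribute `gimbal = TRUE`.
#'
#' @param R A 3x3 rotation matrix.
#' @return Named numeric `c(rx, ry, rz)` in degrees.
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  sb <- max(-1, min(1, R[1, 3]))
  b <- asin(sb)
  gimbal <- abs(sb) > sin(deg2rad(89))
  if (abs(sb) < 1 - 1e-12) {
    a <- atan2(-R[2, 3], R[3, 3])
    c <- atan2(-R[1, 2], R[1, 1])
  } else {
    # degenerate: split the remaining rotation arbitrarily into rx, set rz = 0
    a <- atan2(R[3, 2], R[2, 2])
    c <- 0
  }
  out <- c(rx = rad2deg(a), ry = rad2deg(b), rz = rad2deg(c))
  attr(out, "gimbal") <- gimbal
  out
}

#' Rotation matrix of a pose
#' @param p A [pose()].
#' @return 3x3 rotation matrix.
#' @export
pose_rotation <- function(p) {
  p <- as_pose(p)
  euler_to_matrix(p[["rx"]], p[["ry"]], p[["rz"]])
}

#' Homogeneous 4x4 matrix of a pose
#' @param p A [pose()].
#' @return 4x4 homogeneous transform.
#' @export
pose_matrix <- function(p) {
  p <- as_pose(p)
  M <- diag(4)
  M[1:3, 1:3] <- pose_rotation(p)
  M[1:3, 4] <- c(p[["tx"]], p[["ty"]], p[["tz"]])
  M
}

#' Pose from a homogeneous matrix
#' @param M 4x4 rigid homogeneous transform.
#' @return A [pose()].
#' @export
pose_from_matrix <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(4, 4)))
  ang <- matrix_to_euler(M[1:3, 1:3])
  pose(M[1, 4], M[2, 4], M[3, 4], ang[["rx"]], ang[["ry"]], ang[["rz"]])
}

#' Compose two poses
#'
#' `pose_compose(a, b)` applied to a point equals applying `b` first,
#' then `a`.
#'
#' @param a,b Poses.
#' @return A [pose()].
#' @export
pose_compose <- function(a, b) {
  pose_from_matrix(pose_matrix(a) %*% pose_matrix(b))
}

#' Invert a pose
#' @param p A [pose()].
#' @return The pose `q` with `pose_compose(p, q)` the identity.
#' @export
pose_invert <- function(p) {
  R <- pose_rotation(p)
  t <- c(p[["tx"]], p[["ty"]], p[["tz"]])
  ti <- -crossprod(R, t)
  ang <- matrix_to_euler(t(R))
  pose(ti[1], ti[2], ti[3], ang[["rx"]], ang[["ry"]], ang[["rz"]])
}

#' Apply a pose to points
#'
#' @param p A [pose()].
#' @param pts Numeric matrix with one point per row (n x 3), or a length-3
#'   vector.
#' @return Transformed points, same shape as the input.
#' @export
pose_transform_points <- function(p, pts) {
  vec <- is.null(dim(pts))
  pts <- rbind3(pts)
  R <- pose_rotation(p)
  out <- pts %*% t(R)
  out <- sweep(out, 2, c(p[["tx"]], p[["ty"]], p[["tz"]]), "+")
  if (vec) drop(out) else out
}

#' Mirror a pose across the world sagittal (x = 0) plane
#'
#' Left-side acquisitions are mirrored so that one sign convention
#' (adduction +, internal rotation +) serves both sides.
#'
#' @param p A [pose()].
#' @return The mirrored [pose()], i.e. `S %*% M %*% S` with `S = diag(-1,1,1)`.
#' @export
pose_mirror_x <- function(p) {
  S <- diag(c(-1, 1, 1))
  R <- S %*% pose_rotation(p) %*% S
  t <- c(-p[["tx"]], p[["ty"]], p[["tz"]])
  ang <- matrix_to_euler(R)
  pose(t[1], t[2], t[3], ang[["rx"]], ang[["ry"]], ang[["rz"]])
}

# coerce a length-3 vector or n x 3 matrix to n x 3 matrix
rbind3 <- function(pts) {
  if (is.null(dim(pts))) {
    stopifnot(length(pts) == 3)
    matrix(as.numeric(pts), nrow = 1)
  } else {
    stopifnot(ncol(pts) == 3)
    storage.mode(pts) <- "double"
    pts
  }
}
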