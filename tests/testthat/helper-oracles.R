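# Independent oracles, coded separately from the package internals.

# elementary rotation matrices (degrees), composed explicitly
oracle_rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0,  0, cos(a), sin(a),  0, -sin(a), cos(a)), 3, 3)
}
oracle_rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a),  0, 1, 0,  sin(a), 0, cos(a)), 3, 3)
}
oracle_rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0,  -sin(a), cos(a), 0,  0, 0, 1), 3, 3)
}

# intrinsic x -> y -> z: product of the elementary matrices
oracle_rotation <- function(rx, ry, rz) {
  oracle_rot_x(rx) %*% oracle_rot_y(ry) %*% oracle_rot_z(rz)
}

# 4x4 homogeneous matrix of a 6-vector (tx, ty, tz, rx, ry, rz)
oracle_hom <- function(p) {
  M <- diag(4)
  M[1:3, 1:3] <- oracle_rotation(p[4], p[5], p[6])
  M[1:3, 4] <- p[1:3]
  M
}

# brute-force intersection of the ray source->point with the z = 0 plane
oracle_project_flat <- function(source, pt) {
  dir <- pt - source
  tt <- -source[3] / dir[3]
  (source + tt * dir)[1:2]
}

# geodesic rotation angle (degrees) between two rotation matrices
oracle_geodesic_deg <- function(R1, R2) {
  R <- t(R1) %*% R2
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

random_pose_vec <- function(t_range = 50, r_range = 60) {
  c(runif(3, -t_range, t_range), runif(3, -r_range, r_range))
}

as_p <- function(x) pose(x[1], x[2], x[3], x[4], x[5], x[6])

# a coarse femur phantom with the full-size anatomy but few voxels,
# and a matching coarse detector: fast enough for per-test registration
small_femur <- function() {
  make_phantom(phantom_spec("femur_like", grid_size = c(48, 48, 48),
                            spacing = c(3, 3, 3)))
}
small_geometry <- function() desk_geometry(16)

# quick registration config for coarse-grid tests
small_reg_config <- function() {
  # the coarse detector already has 4.4 mm pixels, so start at ds2, not ds4
  registration_config(stages = list(
    list(downsample = 2L, max_evaluations = 400L, tol_mm = 0.1, tol_deg = 0.1),
    list(downsample = 1L, max_evaluations = 150L, tol_mm = 0.01,
         tol_deg = 0.01)))
}

reference_pose <- function(dtx = 0, dty = 0, dtz = 0, rx = 0, ry = 0, rz = 0) {
  pose(210 + dtx, 210 + dty, 500 + dtz, rx, ry, rz)
}
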