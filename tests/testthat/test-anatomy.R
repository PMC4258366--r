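test_that("sphere fitting recovers exact and noisy spheres, rejects planes", {
  c0 <- c(1, 2, 3)
  axis_pts <- rbind(c0 + c(1, 0, 0), c0 - c(1, 0, 0),
                    c0 + c(0, 1, 0), c0 - c(0, 1, 0),
                    c0 + c(0, 0, 1), c0 - c(0, 0, 1))
  fit <- fit_sphere(axis_pts)
  expect_equal(fit$center, c0, tolerance = 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)
  expect_lt(fit$rms, 1e-12)

  set.seed(21)
  th <- runif(200, 0, pi); ph <- runif(200, 0, 2 * pi)
  pts <- cbind(10 + 25 * sin(th) * cos(ph),
               -5 + 25 * sin(th) * sin(ph),
               40 + 25 * cos(th)) + matrix(rnorm(600, sd = 0.01), 200)
  fitn <- fit_sphere(pts)
  expect_lt(max(abs(fitn$center - c(10, -5, 40))), 0.01)

  expect_error(fit_sphere(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                c(1, 1, 0))), "coplanar")
  expect_error(fit_sphere(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
               "4 points")
})

test_that("the pelvic frame follows the anterior pelvic plane construction", {
  f <- pelvis_frame(c(120, 0, 0), c(-120, 0, 0), c(0, 0, -100))
  expect_equal(f$origin, c(0, 0, 0))
  expect_equal(f$axes, diag(3), tolerance = 1e-12)

  # swapping left and right ASIS flips x and y but preserves z
  fs <- pelvis_frame(c(-120, 0, 0), c(120, 0, 0), c(0, 0, -100))
  expect_equal(fs$axes[, 1], -f$axes[, 1])
  expect_equal(fs$axes[, 2], -f$axes[, 2])
  expect_equal(fs$axes[, 3], f$axes[, 3])

  expect_error(pelvis_frame(c(1, 0, 0), c(-1, 0, 0), c(0.25, 0, 0)),
               "collinear")
})

test_that("the femoral frame follows the transepicondylar construction", {
  f <- femur_frame(c(0, 0, 400), c(40, 0, 0), c(-40, 0, 0))
  expect_equal(f$origin, c(0, 0, 400))
  expect_equal(f$axes, diag(3), tolerance = 1e-12)
  # orthogonality is exact by construction
  expect_equal(sum(f$axes[, 3] * f$axes[, 1]), 0)

  expect_error(femur_frame(c(0, 0, 0), c(40, 0, 0), c(-40, 0, 0)),
               "TEA")
})

test_that("frame constructions are equivariant under rigid motions", {
  set.seed(13)
  L <- c(118, 5, 12); R <- c(-122, 8, -4); P <- c(3, 18, -96)
  H <- c(12, 30, 380); M <- c(42, -6, 3); LA <- c(-38, 2, -5)
  f0 <- pelvis_frame(L, R, P)
  g0 <- femur_frame(H, M, LA)
  for (i in 1:100) {
    q <- as_p(random_pose_vec(30, 90))
    Rm <- pose_rotation(q)
    fp <- pelvis_frame(pose_transform_points(q, L),
                       pose_transform_points(q, R),
                       pose_transform_points(q, P))
    expect_lt(max(abs(fp$axes - Rm %*% f0$axes)), 1e-9)
    expect_lt(max(abs(fp$origin - pose_transform_points(q, f0$origin))), 1e-9)
    ff <- femur_frame(pose_transform_points(q, H),
                      pose_transform_points(q, M),
                      pose_transform_points(q, LA))
    expect_lt(max(abs(ff$axes - Rm %*% g0$axes)), 1e-9)
  }
})

test_that("segment angles decompose tracked rotations about anatomical axes", {
  f <- pelvis_frame(c(120, 0, 0), c(-120, 0, 0), c(0, 0, -100))
  expect_equal(as.numeric(segment_angles(pose(), f)), c(0, 0, 0))
  a30 <- segment_angles(pose(rx = 30), f)
  expect_equal(as.numeric(a30), c(30, 0, 0), tolerance = 1e-10)

  # oracle round trip through independently composed rotations
  set.seed(17)
  for (i in 1:50) {
    ang <- c(runif(1, -170, 170), runif(1, -85, 85), runif(1, -170, 170))
    p <- pose(rx = ang[1], ry = ang[2], rz = ang[3])
    got <- segment_angles(p, f)
    expect_equal(as.numeric(got), ang, tolerance = 1e-9)
    expect_false(attr(got, "gimbal"))
  }
  # gimbal flag near ry = 90
  gq <- segment_angles(pose(rx = 10, ry = 89.7, rz = 5), f)
  expect_true(attr(gq, "gimbal"))
})

test_that("hip angles equal the relative-rotation decomposition", {
  pf <- pelvis_frame(c(120, 0, 0), c(-120, 0, 0), c(0, 0, -100))
  ff <- femur_frame(c(0, 0, 400), c(40, 0, 0), c(-40, 0, 0))

  expect_identical(as.numeric(hip_angles(pose(), pf, pose(), ff)),
                   c(0, 0, 0))
  flex90 <- hip_angles(pose(), pf, pose(rx = 90), ff)
  expect_equal(as.numeric(flex90), c(90, 0, 0), tolerance = 1e-10)

  set.seed(19)
  for (i in 1:30) {
    pp <- as_p(random_pose_vec(20, 60))
    fp <- as_p(random_pose_vec(20, 60))
    got <- hip_angles(pp, pf, fp, ff)
    Rrel <- t(pose_rotation(pp) %*% pf$axes) %*%
      (pose_rotation(fp) %*% ff$axes)
    ora <- matrix_to_euler(Rrel)
    if (!attr(ora, "gimbal"))
      expect_equal(as.numeric(got), as.numeric(ora), tolerance = 1e-9)
  }
})

test_that("hip flexion linearizes to femoral flexion minus pelvic tilt", {
  pf <- pelvis_frame(c(120, 0, 0), c(-120, 0, 0), c(0, 0, -100))
  ff <- femur_frame(c(0, 0, 400), c(40, 0, 0), c(-40, 0, 0))
  set.seed(23)
  for (i in 1:20) {
    tilt <- runif(1, -5, 5); flex <- runif(1, -5, 5)
    hip <- hip_angles(pose(rx = tilt), pf, pose(rx = flex), ff)
    expect_lt(abs(hip[["rx"]] - (flex - tilt)), 0.2)
  }
  # anterior pelvic tilt makes hip flexion exceed femoral flexion
  hip <- hip_angles(pose(rx = 4), pf, pose(rx = 20), ff)
  expect_lt(hip[["rx"]] - 20, 0)
  hip2 <- hip_angles(pose(rx = -4), pf, pose(rx = 20), ff)
  expect_gt(hip2[["rx"]], 20)
})

test_that("cycle normalization resamples channels onto 0-100%", {
  t8 <- (0:7) / 3.5                      # 8 frames at 3.5 frames/sec
  s <- data.frame(time = t8, a = rep(4.5, 8), b = seq(0, 10, length.out = 8))
  out <- normalize_cycle(s, 0, 2)
  expect_equal(nrow(out), 101)
  expect_true(all(out$a == 4.5))
  expect_equal(out$b[out$percent_cycle == 50], 5, tolerance = 1e-9)
  expect_equal(out$b[1], s$b[1])
  expect_equal(out$b[101], s$b[8], tolerance = 1e-9)

  expect_error(normalize_cycle(s, 0, 3), "outside")
  expect_error(normalize_cycle(s, 1, 1), "t_start < t_end")
})

test_that("extrema report earliest-cycle ties and analytic peaks", {
  s <- data.frame(time = seq(0, 1, length.out = 51),
                  flat = rep(2, 51),
                  sinus = sin(2 * pi * seq(0, 1, length.out = 51)))
  out <- normalize_cycle(s, 0, 1)
  ef <- extrema(out, "flat")
  expect_equal(ef$max, 2); expect_equal(ef$at_max, 0)
  es <- extrema(out, "sinus")
  expect_lt(abs(es$at_max - 25), 1.01)
  expect_lt(abs(es$at_min - 75), 1.01)

  s2 <- data.frame(time = 0:4, twin = c(0, 3, 0, 3, 0))
  out2 <- normalize_cycle(s2, 0, 4)
  et <- extrema(out2, "twin")
  expect_equal(et$at_max, 25)

  expect_error(extrema(out, "nope"), "unknown channel")
})

test_that("kinematic series build, write and summarize", {
  pf <- pelvis_frame(c(120, 0, 0), c(-120, 0, 0), c(0, 0, -100))
  ff <- femur_frame(c(0, 0, 400), c(40, 0, 0), c(-40, 0, 0))
  times <- (0:6) / 3.5
  pel <- lapply(seq_along(times), function(k) pose(rx = k))
  fem <- lapply(seq_along(times), function(k) pose(rx = 3 * k))
  kin <- compute_kinematics(times, pel, fem, pf, ff)
  expect_equal(kin$pelvic_tilt, 1:7, tolerance = 1e-9)
  expect_equal(kin$femoral_flexion, 3 * (1:7), tolerance = 1e-9)

  series <- normalize_cycle(kin)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_kinematics(series, csv, js)
  back <- read.csv(csv)
  expect_equal(nrow(back), 101)
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(summ$hip_flexion$max, max(series$hip_flexion),
               tolerance = 1e-9)
})
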