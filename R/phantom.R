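#' Synthetic phantom specification
#'
#' Describes a bone-like test phantom: a density volume with exactly known
#' landmark coordinates, used to exercise rendering, registration and
#' kinematics without any imaging data. Except for the sharp-edged `cube`,
#' phantoms are smooth-density (Gaussian-edged) so that the correlation
#' metric has no plateaus at the pixel scale.
#'
#' Kinds:
#' * `femur_like` — a shaft (capsule) with a spherical head whose center is
#'   the `HEAD_CENTER` landmark, a neck, and two unequal condylar bulges
#'   whose lateral apices are `MED_EPI` / `LAT_EPI`; deliberately asymmetric
#'   so all three rotations are observable in a single projection.
#' * `pelvis_like` — a flared ellipsoidal shell with two lateral protrusions
#'   whose apices are `LASIS` / `RASIS` and an anteroinferior protrusion for
#'   `PUBIS`.
#' * `cube` — sharp-edged homogeneous cube (`cube_edge_vox` voxels on a
#'   side), for exact-count and analytic line-integral checks.
#' * `blob` — isotropic Gaussian density, for smooth-field convergence and
#'   equivariance checks.
#'
#' @param kind One of `"femur_like"`, `"pelvis_like"`, `"cube"`, `"blob"`.
#' @param grid_size Voxels per axis, length 3. Default 96^3.
#' @param spacing Voxel spacing, mm. Default 1.5 mm isotropic.
#' @param density Peak density level (arbitrary units).
#' @param edge_mm Gaussian edge width of the smooth phantoms, mm.
#' @param center Model coordinates of the grid center, mm. The default is
#'   the model origin, so pose rotations pivot about the phantom's center;
#'   the world placement (e.g. on the central ray, 500 mm from the panel)
#'   belongs in the pose translation.
#' @param noise_sigma Default projection noise level for
#'   [make_experiment()], as a fraction of the clean image's intensity
#'   range.
#' @param seed Default random seed for noise generation.
#' @param cube_edge_vox Cube edge, voxels (`cube` only).
#' @param blob_sigma Gaussian sigma, mm (`blob` only; default 0.15 x extent, keeping boundary truncation below 0.4% of peak).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("femur_like", "pelvis_like", "cube", "blob"),
                         grid_size = c(96, 96, 96),
                         spacing = c(1.5, 1.5, 1.5),
                         density = 1, edge_mm = 3,
                         center = c(0, 0, 0),
                         noise_sigma = 0.01, seed = 1L,
                         cube_edge_vox = 32, blob_sigma = NULL) {
  kind <- match.arg(kind)
  grid_size <- as.integer(grid_size); spacing <- as.numeric(spacing)
  stopifnot(length(grid_size) == 3, length(spacing) == 3,
            all(grid_size >= 8), all(spacing > 0),
            density > 0, edge_mm > 0, noise_sigma >= 0)
  structure(list(kind = kind, grid_size = grid_size, spacing = spacing,
                 density = density, edge_mm = edge_mm,
                 center = as.numeric(center), noise_sigma = noise_sigma,
                 seed = as.integer(seed), cube_edge_vox = cube_edge_vox,
                 blob_sigma = blob_sigma),
            class = "phantom_spec")
}

# Gaussian-edged membership: 1 inside (d <= 0), Gaussian falloff outside
soft_profile <- function(d, w) ifelse(d <= 0, 1, exp(-0.5 * (d / w)^2))

# signed distance to a sphere
sd_sphere <- function(X, c0, r) {
  sqrt((X[, 1] - c0[1])^2 + (X[, 2] - c0[2])^2 + (X[, 3] - c0[3])^2) - r
}

# signed distance to a capsule (segment a-b with radius r)
sd_capsule <- function(X, a, b, r) {
  ab <- b - a
  len2 <- sum(ab^2)
  pa1 <- X[, 1] - a[1]; pa2 <- X[, 2] - a[2]; pa3 <- X[, 3] - a[3]
  h <- pmin(pmax((pa1 * ab[1] + pa2 * ab[2] + pa3 * ab[3]) / len2, 0), 1)
  sqrt((pa1 - h * ab[1])^2 + (pa2 - h * ab[2])^2 + (pa3 - h * ab[3])^2) - r
}

# approximate signed distance to an ellipsoidal shell of given thickness
sd_shell <- function(X, c0, semi, thickness) {
  f <- sqrt(((X[, 1] - c0[1]) / semi[1])^2 +
            ((X[, 2] - c0[2]) / semi[2])^2 +
            ((X[, 3] - c0[3]) / semi[3])^2)
  abs(f - 1) * min(semi) - thickness / 2
}

#' Generate a synthetic phantom volume
#'
#' Builds the density volume described by a [phantom_spec()]. Landmark
#' coordinates are stored exactly as constructed (they are specified, not
#' estimated), so landmark-dependent frames on phantoms are exact. The
#' construction is deterministic: the same spec always gives bit-identical
#' output.
#'
#' @param spec A [phantom_spec()].
#' @return A [density_volume()] with the kind's landmarks.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size; sp <- spec$spacing
  extent <- (n - 1) * sp
  origin <- spec$center - extent / 2
  gx <- origin[1] + (seq_len(n[1]) - 1) * sp[1]
  gy <- origin[2] + (seq_len(n[2]) - 1) * sp[2]
  gz <- origin[3] + (seq_len(n[3]) - 1) * sp[3]
  X <- cbind(rep(gx, times = n[2] * n[3]),
             rep(rep(gy, each = n[1]), times = n[3]),
             rep(gz, each = n[1] * n[2]))
  w <- spec$edge_mm
  lv <- spec$density
  C <- spec$center
  u <- min(extent) / 142.5   # size scale relative to the default grid
  landmarks <- list()
  if (spec$kind == "cube") {
    half <- spec$cube_edge_vox * sp / 2
    inside <- abs(X[, 1] - C[1]) < half[1] &
              abs(X[, 2] - C[2]) < half[2] &
              abs(X[, 3] - C[3]) < half[3]
    dens <- lv * inside
  } else if (spec$kind == "blob") {
    sig <- spec$blob_sigma %||% (0.15 * min(extent))
    r2 <- (X[, 1] - C[1])^2 + (X[, 2] - C[2])^2 + (X[, 3] - C[3])^2
    dens <- lv * exp(-r2 / (2 * sig^2))
  } else if (spec$kind == "femur_like") {
    head <- C + u * c(10, 6, 44)
    med <- C + u * c(16, 2, -48); rmed <- 14 * u
    lat <- C + u * c(-14, -3, -48); rlat <- 11 * u
    d <- pmin(
      sd_sphere(X, head, 18 * u),
      sd_capsule(X, head, C + u * c(0, 0, 30), 8 * u),        # neck
      sd_capsule(X, C + u * c(0, 0, 30), C + u * c(4, -5, -38), 11 * u),
      sd_sphere(X, med, rmed),
      sd_sphere(X, lat, rlat))
    dens <- lv * soft_profile(d, w)
    landmarks <- list(HEAD_CENTER = head,
                      MED_EPI = med + c(rmed, 0, 0),
                      LAT_EPI = lat - c(rlat, 0, 0))
  } else { # pelvis_like
    ec <- C + u * c(0, 0, 5)
    semi <- u * c(55, 38, 35)
    lasis <- C + u * c(52, 18, 28)
    rasis <- C + u * c(-52, 18, 28)
    pubis <- C + u * c(0, 22, -45)
    prot <- function(apex, r) {
      ctr <- apex - r * normalize3(apex - ec)
      sd_sphere(X, ctr, r)
    }
    d <- pmin(sd_shell(X, ec, semi, 10 * u),
              prot(lasis, 10 * u), prot(rasis, 10 * u), prot(pubis, 9 * u))
    dens <- lv * soft_profile(d, w)
    landmarks <- list(LASIS = lasis, RASIS = rasis, PUBIS = pubis)
  }
  # Gaussian tails never reach zero; truncate negligible density so the
  # phantom has compact support (field-of-view checks, render windowing)
  dens[dens < 1e-6 * lv] <- 0
  v <- density_volume(array(dens, dim = n), sp, origin, landmarks)
  for (nm in names(v$landmarks)) {
    lm <- v$landmarks[[nm]]
    if (any(lm < origin) || any(lm > origin + extent))
      stop("phantom spec places landmark ", nm, " outside the grid")
  }
  v
}

#' Default desk-scale experiment geometry
#'
#' The panel-anchored world frame with a source 1000 mm above the panel
#' center, the 420 mm panel, and the 0.274 mm detector pitch coarsened by an
#' integer factor for desk-scale work (default x8, about 191 x 191 pixels).
#'
#' @param downsample Integer pixel-pitch coarsening factor.
#' @return A [projection_geometry()].
#' @export
desk_geometry <- function(downsample = 8L) {
  projection_geometry(source_position = c(210, 210, 1000),
                      pixel_spacing = c(0.274, 0.274) * as.integer(downsample))
}

#' Render a synthetic experiment: known poses, noisy frames
#'
#' Renders the phantom at each ground-truth pose and produces `n_repeats`
#' noisy frames per pose (zero-mean Gaussian noise with standard deviation
#' `noise_sigma` x the clean image's intensity range), mirroring a
#' known-displacement stage experiment with repeated exposures. Each frame
#' draws from its own seed substream derived from the master seed, so
#' regeneration is bit-identical and noise is independent across frames.
#'
#' @param spec A [phantom_spec()] (or a ready-made [density_volume()]).
#' @param geometry A [projection_geometry()]; default [desk_geometry()].
#' @param pose_table Data frame with columns `tx, ty, tz, rx, ry, rz` — the
#'   ground-truth poses.
#' @param noise_sigma Noise level, fraction of clean-image range; default
#'   from the phantom spec.
#' @param n_repeats Noise realizations per pose (default 3).
#' @param seed Master seed; default from the phantom spec.
#' @param step Ray step for rendering (`NULL`: renderer default).
#' @return An object of class `synthetic_experiment`: `volume`, `geometry`,
#'   `frames` (list, pose-major), `clean` (list of clean renders per pose),
#'   `truth` (data frame: `frame, pose_id, repeat_id, tx..rz`), `poses`
#'   (list of [pose()]s), `noise_sigma`, `n_repeats`, `seed`.
#' @export
make_experiment <- function(spec, geometry = desk_geometry(),
                            pose_table,
                            noise_sigma = NULL, n_repeats = 3L,
                            seed = NULL, step = NULL) {
  v <- if (inherits(spec, "density_volume")) spec else make_phantom(spec)
  if (is.null(noise_sigma))
    noise_sigma <- if (inherits(spec, "phantom_spec")) spec$noise_sigma else 0
  if (is.null(seed))
    seed <- if (inherits(spec, "phantom_spec")) spec$seed else 1L
  stopifnot(is.data.frame(pose_table), nrow(pose_table) >= 1,
            all(c("tx", "ty", "tz", "rx", "ry", "rz") %in% names(pose_table)))
  poses <- lapply(seq_len(nrow(pose_table)), function(i)
    pose(pose_table$tx[i], pose_table$ty[i], pose_table$tz[i],
         pose_table$rx[i], pose_table$ry[i], pose_table$rz[i]))
  check_field_of_view(v, poses, geometry)
  clean <- lapply(poses, function(p)
    render_drr(v, p, geometry, step = step)$pixels)
  npose <- length(poses); n_repeats <- as.integer(n_repeats)
  set.seed(seed)
  frame_seeds <- sample.int(.Machine$integer.max - 1L, npose * n_repeats)
  frames <- vector("list", npose * n_repeats)
  truth <- vector("list", npose * n_repeats)
  k <- 0L
  for (i in seq_len(npose)) {
    rng <- range(clean[[i]])
    for (r in seq_len(n_repeats)) {
      k <- k + 1L
      f <- clean[[i]]
      if (noise_sigma > 0) {
        set.seed(frame_seeds[k])
        f <- f + matrix(rnorm(length(f), sd = noise_sigma * diff(rng)),
                        nrow(f), ncol(f))
      }
      frames[[k]] <- f
      truth[[k]] <- data.frame(frame = k, pose_id = i, repeat_id = r,
                               tx = pose_table$tx[i], ty = pose_table$ty[i],
                               tz = pose_table$tz[i], rx = pose_table$rx[i],
                               ry = pose_table$ry[i], rz = pose_table$rz[i])
    }
  }
  structure(list(volume = v, geometry = geometry, frames = frames,
                 clean = clean, truth = do.call(rbind, truth), poses = poses,
                 noise_sigma = noise_sigma, n_repeats = n_repeats,
                 seed = seed),
            class = "synthetic_experiment")
}

# every pose must keep the phantom's nonzero support on the panel
check_field_of_view <- function(v, poses, g) {
  nz <- which(v$data != 0, arr.ind = TRUE)
  if (!nrow(nz)) return(invisible(TRUE))
  lo <- apply(nz, 2, min); hi <- apply(nz, 2, max)
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  cw <- voxel_centers(v, corners)
  for (i in seq_along(poses)) {
    uv <- tryCatch(project_points(g, pose_transform_points(poses[[i]], cw)),
                   error = function(e) NULL)
    if (is.null(uv) || any(uv < 0) || any(uv[, 1] > g$panel_size[1]) ||
        any(uv[, 2] > g$panel_size[2]))
      stop(sprintf("pose %d pushes the phantom outside the field of view", i))
  }
  invisible(TRUE)
}
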