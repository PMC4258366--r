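#' Normalized cross-correlation of two images
#'
#' Pearson correlation of pixel values over a common evaluation region —
#' the similarity score maximized during pose search. Invariant to affine
#' intensity maps `a -> alpha * a + beta` (alpha > 0) of either image.
#'
#' @param a,b Numeric matrices of identical dimensions (or `drr_image`s).
#' @param mask Optional logical matrix restricting the evaluation region.
#' @return Correlation in `[-1, 1]`.
#' @export
ncc <- function(a, b, mask = NULL) {
  a <- drr_pixels(a); b <- drr_pixels(b)
  if (!identical(dim(a), dim(b)))
    stop("images must have identical dimensions")
  if (!is.null(mask)) {
    a <- a[mask]; b <- b[mask]
    if (length(a) < 2) stop("evaluation region is empty")
  }
  if (sd(a) == 0 || sd(b) == 0)
    stop("undefined correlation: constant image")
  cor(as.numeric(a), as.numeric(b))
}

#' Exclusive-disjunction (XOR) fitness of two silhouettes
#'
#' Counts the pixels covered by exactly one of the two binary masks; lower
#' is better, zero means identical silhouettes.
#'
#' @param a,b Logical matrices of identical dimensions.
#' @return Mismatch count (integer).
#' @export
xor_fitness <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks must have identical dimensions")
  sum(xor(a, b))
}

#' Registration configuration
#'
#' Controls the staged coarse-to-fine derivative-free pose search.
#' Each stage renders DRRs at a pixel decimation factor and runs a
#' Nelder-Mead simplex search (restarted until the pose moves by less than
#' the stage tolerances or the evaluation budget is spent).
#'
#' @param metric `"ncc"` (maximize image correlation, the default) or
#'   `"xor"` (minimize the silhouette mismatch count).
#' @param region For `"ncc"`: `"all"` (default) evaluates the correlation
#'   over the whole image; `"support"` restricts it to the nonzero-DRR
#'   footprint. The support region is pose-dependent, which under image
#'   noise biases the depth estimate toward smaller silhouettes; the fixed
#'   whole-image region has no such bias.
#' @param stages List of stages, each a list with `downsample` (pixel
#'   decimation, int >= 1), `max_evaluations`, `tol_mm` and `tol_deg`
#'   (parameter tolerances).
#' @param perturbations Optional matrix (n x 6) of pose offsets; the first
#'   stage is additionally started from `init + offset` for each row and the
#'   best start wins (multi-start).
#' @param simplex_mm,simplex_deg Initial simplex size for translations /
#'   rotations at the first stage (shrunk at later stages).
#' @param binarize_method Threshold for the `"xor"` metric (see
#'   [binarize()]).
#' @param step Ray step passed to [render_drr()] (`NULL`: renderer default).
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(metric = c("ncc", "xor"),
                                region = c("all", "support"),
                                stages = list(
                                  list(downsample = 4L, max_evaluations = 400L,
                                       tol_mm = 0.1, tol_deg = 0.1),
                                  list(downsample = 2L, max_evaluations = 200L,
                                       tol_mm = 0.02, tol_deg = 0.02),
                                  list(downsample = 1L, max_evaluations = 120L,
                                       tol_mm = 0.01, tol_deg = 0.01)),
                                perturbations = NULL,
                                simplex_mm = 2, simplex_deg = 2,
                                binarize_method = "otsu",
                                step = NULL) {
  metric <- match.arg(metric)
  region <- match.arg(region)
  if (!length(stages)) stop("at least one stage is required")
  for (s in stages) {
    if (is.null(s$downsample) || s$downsample < 1)
      stop("stage downsample must be >= 1")
    if (is.null(s$tol_mm) || s$tol_mm <= 0 || is.null(s$tol_deg) || s$tol_deg <= 0)
      stop("stage tolerances must be positive")
    if (is.null(s$max_evaluations) || s$max_evaluations < 1)
      stop("stage evaluation budget must be positive")
  }
  if (!is.null(perturbations)) {
    perturbations <- matrix(as.numeric(perturbations), ncol = 6)
  }
  structure(list(metric = metric, region = region, stages = stages,
                 perturbations = perturbations,
                 simplex_mm = simplex_mm, simplex_deg = simplex_deg,
                 binarize_method = binarize_method, step = step),
            class = "registration_config")
}

# decimate a full-resolution frame to match a stage's DRR pixel grid
decimate_frame <- function(frame, ds, nu, nv) {
  frame[seq.int(1L, by = ds, length.out = nu),
        seq.int(1L, by = ds, length.out = nv), drop = FALSE]
}

# model-space corners of the volume's nonzero bounding box (8 x 3)
support_corners <- function(v) {
  nz <- which(v$data != 0, arr.ind = TRUE)
  if (!nrow(nz)) return(NULL)
  lo <- apply(nz, 2, min); hi <- apply(nz, 2, max)
  voxel_centers(v, as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                         c(lo[3], hi[3]))))
}

# pixel window (1-based, decimated grid) covering the projected bbox
projected_roi <- function(corners, p, g, ds, nu, nv, pad = 3L) {
  uv <- tryCatch(project_points(g, pose_transform_points(p, corners)),
                 error = function(e) NULL)
  if (is.null(uv)) return(NULL)
  i <- floor(uv[, 1] / (g$pixel_spacing[1] * ds)) + 1
  j <- floor(uv[, 2] / (g$pixel_spacing[2] * ds)) + 1
  roi <- c(max(min(i) - pad, 1), min(max(i) + pad, nu),
           max(min(j) - pad, 1), min(max(j) + pad, nv))
  if (roi[1] > roi[2] || roi[3] > roi[4]) return(NULL)
  as.integer(roi)
}

# stage objective: negative similarity (always minimized)
make_stage_objective <- function(v, frame, g, cfg, stage, corners) {
  ds <- as.integer(stage$downsample)
  np <- panel_pixels(g)
  nu <- np[1] %/% ds; nv <- np[2] %/% ds
  fr <- decimate_frame(frame, ds, nu, nv)
  frb <- if (cfg$metric == "xor") binarize(fr, cfg$binarize_method) else NULL
  function(par) {
    p <- as_pose(par)
    roi <- projected_roi(corners, p, g, ds, nu, nv)
    if (is.null(roi)) return(Inf)
    drr <- render_drr(v, p, g, step = cfg$step, downsample = ds, roi = roi)
    px <- drr$pixels
    if (cfg$metric == "xor") {
      xor_fitness(px > 0, frb)
    } else {
      mask <- if (cfg$region == "support") px > 0 else NULL
      if (!is.null(mask) && sum(mask) < 16) return(Inf)
      val <- tryCatch(ncc(px, fr, mask), error = function(e) NA_real_)
      if (is.na(val)) Inf else -val
    }
  }
}

#' Register one bone to one radiographic frame
#'
#' Recovers the 6-DOF pose of the volume by maximizing DRR/image similarity
#' with a staged coarse-to-fine Nelder-Mead simplex search started at
#' `init` (and at `init + offset` for each configured multi-start
#' perturbation). The search is fully deterministic for fixed inputs.
#'
#' @param v A [density_volume()].
#' @param frame Numeric matrix, the measured image at the geometry's full
#'   pixel grid (`panel_pixels(g)`).
#' @param g A [projection_geometry()].
#' @param init Initial [pose()].
#' @param cfg A [registration_config()].
#' @return An object of class `registration_result`: `pose`, `metric_value`
#'   (similarity at the returned pose, final-stage settings),
#'   `n_evaluations`, `converged`, and a per-stage `trace` data frame.
#' @export
register_frame <- function(v, frame, g, init, cfg = registration_config()) {
  stopifnot(inherits(v, "density_volume"),
            inherits(g, "projection_geometry"),
            inherits(cfg, "registration_config"))
  init <- as_pose(init)
  frame <- drr_pixels(frame)
  np <- panel_pixels(g)
  if (!identical(dim(frame), as.integer(np)))
    stop(sprintf("frame is %d x %d but geometry implies %d x %d pixels",
                 nrow(frame), ncol(frame), np[1], np[2]))
  # the model must project onto the panel at the initial pose
  ds0 <- as.integer(cfg$stages[[1]]$downsample)
  probe <- render_drr(v, init, g, step = cfg$step,
                      downsample = max(ds0, 4L))
  if (all(probe$pixels == 0))
    stop("initialization error: model projects outside the detector at init")

  nev <- 0L
  trace <- list()
  starts <- rbind(as.numeric(init))
  if (!is.null(cfg$perturbations))
    starts <- rbind(starts,
                    sweep(cfg$perturbations, 2, as.numeric(init), "+"))
  best_par <- NULL; best_val <- Inf
  converged <- TRUE
  n_stages <- length(cfg$stages)
  corners <- support_corners(v)
  if (is.null(corners))
    stop("initialization error: volume has no nonzero voxel")
  for (si in seq_len(n_stages)) {
    stage <- cfg$stages[[si]]
    obj <- make_stage_objective(v, frame, g, cfg, stage, corners)
    count_obj <- function(par) { nev <<- nev + 1L; obj(par) }
    shrink <- 2^(-(si - 1))
    scale <- c(rep(cfg$simplex_mm, 3), rep(cfg$simplex_deg, 3)) * shrink
    stage_starts <- if (si == 1) starts else rbind(best_par)
    s_best_par <- NULL; s_best_val <- Inf; s_conv <- FALSE
    for (k in seq_len(nrow(stage_starts))) {
      par <- stage_starts[k, ]
      budget <- as.integer(stage$max_evaluations) %/% nrow(stage_starts)
      used <- 0L
      conv <- FALSE
      fit <- NULL
      repeat {
        fit <- optim(par, count_obj, method = "Nelder-Mead",
                     control = list(maxit = max(budget - used, 20L),
                                    reltol = 1e-12,
                                    parscale = scale))
        used <- used + fit$counts[1]
        moved <- abs(fit$par - par)
        par <- fit$par
        if (max(moved[1:3]) < stage$tol_mm &&
            max(moved[4:6]) < stage$tol_deg) { conv <- TRUE; break }
        if (used >= budget) break
        scale <- pmax(scale / 2, c(rep(stage$tol_mm, 3), rep(stage$tol_deg, 3)))
      }
      # a collapsed simplex (optim's own relative-tolerance stop) implies a
      # parameter step far below the stage tolerance
      if (!conv && fit$convergence == 0) conv <- TRUE
      val <- obj(par)
      if (val < s_best_val) { s_best_val <- val; s_best_par <- par; s_conv <- conv }
    }
    best_par <- s_best_par; best_val <- s_best_val
    converged <- s_conv   # the final stage's tolerance decides
    trace[[si]] <- data.frame(stage = si, downsample = stage$downsample,
                              score = if (cfg$metric == "ncc") -s_best_val else s_best_val,
                              tx = best_par[1], ty = best_par[2], tz = best_par[3],
                              rx = best_par[4], ry = best_par[5], rz = best_par[6])
  }
  metric_value <- if (cfg$metric == "ncc") -best_val else best_val
  structure(list(pose = as_pose(best_par), metric_value = metric_value,
                 n_evaluations = nev, converged = converged,
                 trace = do.call(rbind, trace), config = cfg),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration result (%s = %.6g, %d evaluations, %s)\n",
              x$config$metric, x$metric_value, x$n_evaluations,
              if (x$converged) "converged" else "budget exhausted"))
  print(x$pose)
  invisible(x)
}

#' Track a bone through a frame sequence
#'
#' Registers every frame in order; frame `k > 1` is initialized at the
#' result of frame `k - 1`, so slow inter-frame motion needs only a local
#' search.
#'
#' @param v A [density_volume()].
#' @param frames List of numeric matrices (full-resolution frames).
#' @param g A [projection_geometry()].
#' @param init0 Initial [pose()] for the first frame.
#' @param cfg A [registration_config()].
#' @return List of `registration_result`, one per frame, in frame order.
#' @export
track_sequence <- function(v, frames, g, init0, cfg = registration_config()) {
  out <- vector("list", length(frames))
  init <- as_pose(init0)
  for (k in seq_along(frames)) {
    out[[k]] <- tryCatch(
      register_frame(v, frames[[k]], g, init, cfg),
      error = function(e) stop(sprintf("frame %d: %s", k, conditionMessage(e)),
                               call. = FALSE))
    init <- out[[k]]$pose
  }
  out
}

#' Tracked poses as a data frame
#'
#' @param results List of `registration_result` (e.g. from
#'   [track_sequence()]).
#' @return Data frame with columns `frame, tx, ty, tz, rx, ry, rz, metric,
#'   converged` — the on-disk `poses.csv` layout.
#' @export
results_table <- function(results) {
  do.call(rbind, lapply(seq_along(results), function(k) {
    r <- results[[k]]
    data.frame(frame = k, tx = r$pose[["tx"]], ty = r$pose[["ty"]],
               tz = r$pose[["tz"]], rx = r$pose[["rx"]], ry = r$pose[["ry"]],
               rz = r$pose[["rz"]], metric = r$metric_value,
               converged = r$converged)
  }))
}
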