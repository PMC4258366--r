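#' Single-plane projection geometry
#'
#' Describes a point X-ray source and a flat-panel detector. The world
#' coordinate system is anchored to the panel: the upper-left corner of the
#' detector is the world origin, the panel horizontal (mediolateral) axis is
#' world x, the panel vertical (superoinferior) axis is world y, and world
#' z = x cross y points from the panel toward the source (right-handed).
#'
#' @param source_position World position of the X-ray focal spot, mm.
#' @param detector_origin World position of the panel's upper-left corner, mm.
#' @param detector_axes 3 x 2 matrix whose columns are the orthonormal panel
#'   axes (u horizontal, v vertical) in world coordinates.
#' @param panel_size Active panel area `(width, height)`, mm. Default 420 x 420.
#' @param pixel_spacing Detector pixel pitch `(du, dv)`, mm/pixel.
#'   Default 0.274 x 0.274.
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(source_position = c(210, 210, 1000),
                                detector_origin = c(0, 0, 0),
                                detector_axes = cbind(c(1, 0, 0), c(0, 1, 0)),
                                panel_size = c(420, 420),
                                pixel_spacing = c(0.274, 0.274)) {
  source_position <- as.numeric(source_position)
  detector_origin <- as.numeric(detector_origin)
  detector_axes <- matrix(as.numeric(detector_axes), nrow = 3, ncol = 2)
  stopifnot(length(source_position) == 3, length(detector_origin) == 3,
            length(panel_size) == 2, length(pixel_spacing) == 2)
  if (any(panel_size <= 0) || any(pixel_spacing <= 0))
    stop("panel_size and pixel_spacing must be positive")
  G <- crossprod(detector_axes)
  if (max(abs(G - diag(2))) > 1e-9)
    stop("detector axes must be orthonormal")
  n <- cross3(detector_axes[, 1], detector_axes[, 2])
  if (abs(sum(n * (source_position - detector_origin))) < 1e-9)
    stop("source must not lie in the detector plane")
  structure(list(source_position = source_position,
                 detector_origin = detector_origin,
                 detector_axes = detector_axes,
                 panel_size = as.numeric(panel_size),
                 pixel_spacing = as.numeric(pixel_spacing)),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat("projection geometry\n")
  cat(sprintf("  source:  (%.3f, %.3f, %.3f) mm\n", x$source_position[1],
              x$source_position[2], x$source_position[3]))
  cat(sprintf("  panel:   %g x %g mm, %g x %g mm/pixel (%d x %d pixels)\n",
              x$panel_size[1], x$panel_size[2],
              x$pixel_spacing[1], x$pixel_spacing[2],
              panel_pixels(x)[1], panel_pixels(x)[2]))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

geometry_normal <- function(g) cross3(g$detector_axes[, 1], g$detector_axes[, 2])

#' Detector pixel grid dimensions
#' @param g A [projection_geometry()].
#' @return Integer `(nu, nv)`, `floor(panel_size / pixel_spacing)`.
#' @export
panel_pixels <- function(g) {
  as.integer(floor(g$panel_size / g$pixel_spacing + 1e-9))
}

#' Perspective projection of world points onto the detector
#'
#' Intersects the ray from the source through each point with the detector
#' plane and reports panel coordinates `(u, v)` in mm, measured from the
#' panel's upper-left corner along the panel axes. Points in the detector
#' plane map to their own in-plane coordinates; points at or beyond the
#' source plane have no forward projection and raise an error.
#'
#' @param g A [projection_geometry()].
#' @param pts Points (n x 3 matrix or length-3 vector), world mm.
#' @return n x 2 matrix of `(u, v)` panel coordinates in mm (or a length-2
#'   vector for a single point).
#' @export
project_points <- function(g, pts) {
  vec <- is.null(dim(pts))
  pts <- rbind3(pts)
  n <- geometry_normal(g)
  o <- g$detector_origin
  s <- g$source_position
  ds <- sum(n * (s - o))                    # signed source height over panel
  dp <- as.numeric((sweep(pts, 2, o)) %*% n) # signed point heights
  # a forward projection requires the point strictly below the source plane
  bad <- (dp - ds) * sign(ds) >= -1e-12 * abs(ds)
  if (any(bad))
    stop(sprintf("point(s) %s at or beyond the source plane: not projectable",
                 paste(which(bad), collapse = ", ")))
  tt <- ds / (ds - dp)
  S <- matrix(s, nrow(pts), 3, byrow = TRUE)
  X <- S + (pts - S) * tt
  rel <- sweep(X, 2, o)
  uv <- cbind(u = as.numeric(rel %*% g$detector_axes[, 1]),
              v = as.numeric(rel %*% g$detector_axes[, 2]))
  if (vec) drop(uv) else uv
}

#' Calibrate the source position from fiducials
#'
#' Finds the X-ray source position minimizing the sum of squared 2D
#' reprojection residuals of a fiducial frame with known 3D coordinates and
#' measured panel projections. The world frame is pinned to the panel, so
#' the detector parameters are taken from `initial` and only the source
#' position is estimated.
#'
#' @param fids3d n x 3 matrix of fiducial world coordinates, mm. At least 4
#'   non-coplanar points are required.
#' @param fids2d n x 2 matrix of measured panel coordinates, mm.
#' @param initial A [projection_geometry()] providing the detector frame and
#'   the starting source position.
#' @return A [projection_geometry()] with the fitted source; the attribute
#'   `calibration_rms` holds the root-mean-square reprojection residual in mm
#'   and `n_fiducials` the number of fiducials used.
#' @export
calibrate_geometry <- function(fids3d, fids2d, initial) {
  fids3d <- rbind3(fids3d)
  fids2d <- matrix(as.numeric(fids2d), ncol = 2)
  if (nrow(fids3d) != nrow(fids2d))
    stop("fids3d and fids2d must pair one-to-one")
  if (nrow(fids3d) < 4)
    stop("degenerate configuration: at least 4 fiducials are required")
  ctr <- sweep(fids3d, 2, colMeans(fids3d))
  sv <- svd(ctr)$d
  if (sv[3] < 1e-8 * max(sv[1], 1))
    stop("degenerate configuration: fiducials are coplanar")
  obj <- function(par) {
    g <- initial
    g$source_position <- par
    uv <- tryCatch(project_points(g, fids3d), error = function(e) NULL)
    if (is.null(uv)) return(1e12)
    sum((uv - fids2d)^2)
  }
  fit <- optim(initial$source_position, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-15))
  fit <- optim(fit$par, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-15))
  out <- initial
  out$source_position <- fit$par
  attr(out, "calibration_rms") <- sqrt(fit$value / (2 * nrow(fids3d)))
  attr(out, "n_fiducials") <- nrow(fids3d)
  out
}

#' Read / write projection geometry as YAML or JSON
#'
#' @param g A [projection_geometry()].
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `write_geometry` returns `path` invisibly; `read_geometry` returns
#'   a [projection_geometry()].
#' @export
write_geometry <- function(g, path) {
  doc <- list(source_position = g$source_position,
              detector_origin = g$detector_origin,
              detector_axes = list(u = g$detector_axes[, 1],
                                   v = g$detector_axes[, 2]),
              panel_size = g$panel_size,
              pixel_spacing = g$pixel_spacing)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path, precision = 17)
  } else {
    jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE)
  }
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  projection_geometry(source_position = doc$source_position,
                      detector_origin = doc$detector_origin,
                      detector_axes = cbind(unlist(doc$detector_axes$u),
                                            unlist(doc$detector_axes$v)),
                      panel_size = doc$panel_size,
                      pixel_spacing = doc$pixel_spacing)
}

#' Read / write fiducial sets as CSV
#'
#' Columns: `name, X, Y, Z, u, v` — 3D world coordinates and measured panel
#' projections in mm.
#'
#' @param path CSV file path.
#' @param fids Data frame with columns `name, X, Y, Z, u, v`.
#' @return `read_fiducials` returns that data frame.
#' @export
read_fiducials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "X", "Y", "Z", "u", "v")
  if (!all(need %in% names(df)))
    stop("fiducial CSV must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' @rdname read_fiducials
#' @export
write_fiducials <- function(fids, path) {
  write.csv(fids, path, row.names = FALSE)
  invisible(path)
}
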