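#' Render a digitally reconstructed radiograph (DRR)
#'
#' Casts a ray from the X-ray source through the center of every detector
#' pixel and integrates the trilinearly interpolated density of the posed
#' volume along it (fixed-step midpoint rule). Pixel values are line
#' integrals in density x mm; no attenuation/exponential mapping is applied,
#' since the correlation metric used for registration is invariant to
#' monotone intensity maps. Voxels outside the grid contribute zero, so a
#' volume entirely outside the beam yields an all-zero image.
#'
#' @param v A [density_volume()] (the bone model, in model coordinates).
#' @param p A [pose()] placing the model in world coordinates.
#' @param g A [projection_geometry()].
#' @param step Ray sampling step, mm. Default: half the smallest voxel
#'   spacing.
#' @param downsample Integer >= 1; render every `downsample`-th pixel (pixel
#'   decimation for coarse passes — the projective geometry is unchanged).
#' @param roi Optional pixel window `c(i0, i1, j0, j1)` (1-based, inclusive,
#'   in the decimated grid): only rays inside the window are cast, the rest
#'   of the image is zero. Used by the registration search, which windows
#'   rendering to the projection of the volume's bounding box.
#' @return An object of class `drr_image`: list with `pixels` (nu x nv
#'   matrix, u fastest/horizontal), `pixel_spacing` (mm, after decimation),
#'   `geometry`, `pose`, `downsample`, `step`.
#' @export
render_drr <- function(v, p, g, step = NULL, downsample = 1L, roi = NULL) {
  stopifnot(inherits(v, "density_volume"),
            inherits(g, "projection_geometry"))
  p <- as_pose(p)
  if (is.null(step)) step <- min(v$spacing) / 2
  if (!is.numeric(step) || length(step) != 1 || !is.finite(step) || step <= 0)
    stop("invalid ray step: must be a positive number of mm")
  downsample <- as.integer(downsample)
  if (is.na(downsample) || downsample < 1)
    stop("invalid downsample: must be an integer >= 1")
  np <- panel_pixels(g)
  nu <- np[1] %/% downsample
  nv <- np[2] %/% downsample
  roi0 <- if (is.null(roi)) c(0L, nu - 1L, 0L, nv - 1L)
          else as.integer(roi) - c(1L, 1L, 1L, 1L)
  px <- .render_drr_cpp(as.numeric(v$data), dim(v$data), v$spacing, v$origin,
                        pose_rotation(p),
                        c(p[["tx"]], p[["ty"]], p[["tz"]]),
                        g$source_position, g$detector_origin,
                        g$detector_axes[, 1], g$detector_axes[, 2],
                        g$pixel_spacing[1], g$pixel_spacing[2],
                        nu, nv, downsample, step, roi0)
  structure(list(pixels = px,
                 pixel_spacing = g$pixel_spacing * downsample,
                 geometry = g, pose = p,
                 downsample = downsample, step = step),
            class = "drr_image")
}

#' @export
print.drr_image <- function(x, ...) {
  cat(sprintf("DRR: %d x %d pixels at (%g, %g) mm/pixel, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing[1], x$pixel_spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

drr_pixels <- function(img) {
  if (inherits(img, "drr_image")) img$pixels else as.matrix(img)
}

#' Binarize a projection image
#'
#' Thresholds a DRR or radiograph into a silhouette mask, either at a fixed
#' level or automatically by Otsu's method (via EBImage). The mask feeds the
#' exclusive-disjunction (XOR) fitness used as an alternative registration
#' metric.
#'
#' @param img A `drr_image` or a numeric matrix.
#' @param method `"otsu"` or a single numeric threshold.
#' @return Logical matrix, `TRUE` where the pixel exceeds the threshold.
#' @export
binarize <- function(img, method = "otsu") {
  px <- drr_pixels(img)
  if (is.numeric(method) && length(method) == 1) {
    return(px > method)
  }
  if (!identical(method, "otsu")) stop("unknown binarization method")
  rng <- range(px)
  if (diff(rng) == 0)
    stop("degenerate threshold: image is constant, Otsu is undefined")
  thr <- EBImage::otsu(EBImage::Image(px), range = rng)
  px > thr
}

#' Write / read a DRR as a scaled gray image with a recovery sidecar
#'
#' Pixel values are min-max scaled into gray levels — 16-bit for TIFF (the
#' native format), 8-bit for PNG (the R png writer's depth limit) — and the
#' linear map is recorded in `<path>.json` (`scale`, `offset`, with
#' `value = stored * scale + offset`) so physical line-integral values are
#' recoverable to quantization precision.
#'
#' @param img A `drr_image` or numeric matrix.
#' @param path Output path, `.tif`/`.tiff` or `.png`.
#' @return `write_drr` returns `path` invisibly; `read_drr` returns the
#'   recovered numeric matrix.
#' @export
write_drr <- function(img, path) {
  px <- drr_pixels(img)
  rng <- range(px)
  scale <- if (diff(rng) > 0) diff(rng) / 65535 else 1
  stored <- (px - rng[1]) / (scale * 65535)     # in [0, 1]
  # image rows run down the panel (v), columns across (u)
  m <- t(stored)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 16)
  }
  jsonlite::write_json(list(scale = scale, offset = rng[1]),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_drr
#' @export
read_drr <- function(path) {
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  px <- t(m)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    px <- px * (sc$scale * 65535) + sc$offset
  }
  px
}
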