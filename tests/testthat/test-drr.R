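cube64 <- function() {
  make_phantom(phantom_spec("cube", grid_size = c(64, 64, 64),
                            spacing = c(1.5, 1.5, 1.5), cube_edge_vox = 32))
}

test_that("an empty volume renders to an all-zero image", {
  v <- density_volume(array(0, c(8, 8, 8)), spacing = c(2, 2, 2),
                      origin = c(-8, -8, -8))
  img <- render_drr(v, reference_pose(), desk_geometry(8))
  expect_true(all(img$pixels == 0))
})

test_that("the central-ray integral through a cube equals its chord length", {
  v <- cube64()
  g <- desk_geometry(8)
  step <- 0.75
  img <- render_drr(v, reference_pose(), g, step = step)
  np <- panel_pixels(g)
  # pixel whose center is nearest the panel center (the central ray)
  iu <- which.min(abs((seq_len(np[1]) - 0.5) * img$pixel_spacing[1] - 210))
  iv <- which.min(abs((seq_len(np[2]) - 0.5) * img$pixel_spacing[2] - 210))
  expect_lt(abs(img$pixels[iu, iv] - 48), 2 * step)
})

test_that("rendering is linear in density", {
  v <- cube64()
  g <- desk_geometry(8)
  a <- render_drr(v, reference_pose(), g)$pixels
  v2 <- density_volume(v$data * 2, v$spacing, v$origin)
  b <- render_drr(v2, reference_pose(), g)$pixels
  expect_lt(max(abs(b - 2 * a)), 1e-9 * max(a))
})

test_that("halving the ray step changes a smooth phantom by under 1%", {
  v <- make_phantom(phantom_spec("blob", grid_size = c(48, 48, 48),
                                 spacing = c(3, 3, 3)))
  g <- desk_geometry(8)
  a <- render_drr(v, reference_pose(), g, step = 1.5)$pixels
  b <- render_drr(v, reference_pose(), g, step = 0.75)$pixels
  expect_lt(max(abs(a - b)) / max(b), 0.01)
})

test_that("rendering is equivariant under rigid motion of the volume", {
  # isotropic Gaussian blob: posing the model equals re-centering the blob
  g <- desk_geometry(8)
  a_vol <- make_phantom(phantom_spec("blob", grid_size = c(64, 64, 64),
                                     spacing = c(2, 2, 2)))
  p <- reference_pose(4, -6, 10, rx = 25, ry = -10, rz = 40)
  b_vol <- make_phantom(phantom_spec("blob", grid_size = c(64, 64, 64),
                                     spacing = c(2, 2, 2),
                                     center = c(214, 204, 510)))
  a <- render_drr(a_vol, p, g)$pixels
  b <- render_drr(b_vol, pose(), g)$pixels
  expect_lt(max(abs(a - b)) / max(b), 0.02)
})

test_that("translating the volume shifts the image centroid by the magnification", {
  g <- desk_geometry(8)
  v <- make_phantom(phantom_spec("blob", grid_size = c(48, 48, 48),
                                 spacing = c(3, 3, 3)))
  centroid_u <- function(px) {
    w <- rowSums(px)
    sum((seq_along(w) - 0.5) * w) / sum(w)
  }
  a <- render_drr(v, reference_pose(), g)$pixels
  b <- render_drr(v, reference_pose(dtx = 5), g)$pixels
  mag <- 1000 / (1000 - 500)
  shift_px <- centroid_u(b) - centroid_u(a)
  expect_lt(abs(shift_px - 5 * mag / g$pixel_spacing[1]), 1)
})

test_that("binarization thresholds fixed levels and separates two-valued images", {
  z <- matrix(0, 5, 5)
  expect_false(any(binarize(z, 0.5)))

  two <- matrix(0, 10, 10); two[3:6, 4:8] <- 10
  expect_identical(binarize(two, "otsu"), two == 10)

  expect_error(binarize(matrix(1, 4, 4), "otsu"), "constant")
})

test_that("a rendered cube's silhouette area matches the projected hull", {
  v <- cube64()
  g <- desk_geometry(8)
  p <- reference_pose(rx = 10, rz = 15)
  img <- render_drr(v, p, g)
  mask <- binarize(img, 1.0)   # low fixed threshold: full outer silhouette

  # geometric oracle: area of the projected convex hull of the cube corners
  h <- 24
  corners <- as.matrix(expand.grid(c(-h, h), c(-h, h), c(-h, h)))
  uv <- project_points(g, pose_transform_points(p, corners))
  ch <- grDevices::chull(uv)
  poly <- uv[ch, ]
  n <- nrow(poly)
  area_mm2 <- abs(sum(poly[, 1] * poly[c(2:n, 1), 2] -
                      poly[c(2:n, 1), 1] * poly[, 2])) / 2
  px_area <- prod(img$pixel_spacing)
  perim_px <- sum(sqrt(rowSums((poly - poly[c(2:n, 1), ])^2))) /
    mean(img$pixel_spacing)
  expect_lt(abs(sum(mask) - area_mm2 / px_area), 1.5 * perim_px)
})

test_that("DRR image files round-trip through 16-bit storage", {
  v <- cube64()
  img <- render_drr(v, reference_pose(), desk_geometry(8))
  depth <- c(".tif" = 65535, ".png" = 255)  # png writer is 8-bit
  for (ext in names(depth)) {
    f <- file.path(tempdir(), paste0("drr", ext))
    write_drr(img, f)
    back <- read_drr(f)
    expect_equal(dim(back), dim(img$pixels))
    expect_lt(max(abs(back - img$pixels)),
              diff(range(img$pixels)) / depth[[ext]] + 1e-9)
  }
})
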