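#' Density volume with landmarks
#'
#' A CT-like scalar volume on a regular grid, with voxel-center model
#' coordinates: voxel `(i, j, k)` (1-based array indices) sits at
#' `origin + (c(i, j, k) - 1) * spacing`. Named anatomical landmarks are
#' carried alongside in model coordinates.
#'
#' @param data 3D numeric array of densities (arbitrary CT-like units).
#' @param spacing Voxel spacing, mm, length 3, strictly positive.
#' @param origin Model coordinates of the center of voxel `(1, 1, 1)`, mm.
#' @param landmarks Named list of length-3 numeric vectors, model mm.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           landmarks = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  stopifnot(length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (length(landmarks)) {
    if (is.null(names(landmarks)) || anyDuplicated(names(landmarks)))
      stop("landmark names must be present and unique")
    landmarks <- lapply(landmarks, function(p) {
      p <- as.numeric(p); stopifnot(length(p) == 3); p
    })
  }
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin,
                 landmarks = landmarks),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("density volume: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm; %d landmark(s)%s\n",
              x$origin[1], x$origin[2], x$origin[3], length(x$landmarks),
              if (length(x$landmarks))
                paste0(": ", paste(names(x$landmarks), collapse = ", "))
              else ""))
  invisible(x)
}

#' Model coordinates of voxel centers
#' @param v A [density_volume()].
#' @param idx n x 3 matrix of 1-based array indices.
#' @return n x 3 matrix of model coordinates, mm.
#' @export
voxel_centers <- function(v, idx) {
  idx <- rbind3(idx)
  sweep(sweep(idx - 1, 2, v$spacing, "*"), 2, v$origin, "+")
}

strip_volume_ext <- function(path) {
  sub("\\.(nii\\.gz|nii|mha|mhd)$", "", path, ignore.case = TRUE)
}

landmark_sidecar_path <- function(path) {
  paste0(strip_volume_ext(path), ".landmarks.json")
}

#' Read a density volume (NIfTI or MetaImage)
#'
#' Supports `.nii`/`.nii.gz` (via RNifti) and MetaImage `.mhd`/`.mha`.
#' Landmarks are loaded from a sidecar JSON `<stem>.landmarks.json` of the
#' form `{"landmarks": {"NAME": [x, y, z], ...}}` when present; a missing
#' sidecar yields an empty landmark set.
#'
#' @param path Volume file path.
#' @return A [density_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    im <- RNifti::readNifti(path)
    h <- RNifti::niftiHeader(im)
    spacing <- RNifti::pixdim(im)[1:3]
    origin <- c(h$qoffset_x, h$qoffset_y, h$qoffset_z)
    data <- array(as.numeric(im), dim = dim(im)[1:3])
  } else if (grepl("\\.mhd?a?$", path, ignore.case = TRUE)) {
    mi <- read_metaimage(path)
    data <- mi$data; spacing <- mi$spacing; origin <- mi$origin
  } else {
    stop("unsupported volume format: ", path)
  }
  if (any(spacing <= 0)) stop("volume has non-positive spacing: ", path)
  lmpath <- landmark_sidecar_path(path)
  landmarks <- list()
  if (file.exists(lmpath)) {
    doc <- jsonlite::read_json(lmpath, simplifyVector = TRUE)
    landmarks <- lapply(as.list(doc$landmarks), as.numeric)
  }
  density_volume(data, spacing, origin, landmarks)
}

#' Write a density volume (NIfTI or MetaImage)
#'
#' Format follows the extension. Landmarks, if any, are written to the
#' sidecar JSON next to the volume. MetaImage round trips spacing and origin
#' exactly (text header, double raw data); NIfTI-1 headers store them as
#' 32-bit floats.
#'
#' @param v A [density_volume()].
#' @param path Output path (`.nii`, `.nii.gz`, `.mhd` or `.mha`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "density_volume"))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    im <- RNifti::asNifti(v$data,
      reference = list(pixdim = c(-1, v$spacing, 0, 0, 0, 0),
                       qoffset_x = v$origin[1], qoffset_y = v$origin[2],
                       qoffset_z = v$origin[3], qform_code = 2L),
      datatype = "double")
    RNifti::writeNifti(im, path)
  } else if (grepl("\\.mhd?a?$", path, ignore.case = TRUE)) {
    write_metaimage(v, path)
  } else {
    stop("unsupported volume format: ", path)
  }
  if (length(v$landmarks)) {
    jsonlite::write_json(list(landmarks = v$landmarks),
                         landmark_sidecar_path(path),
                         digits = NA, auto_unbox = FALSE)
  }
  invisible(path)
}

# --- MetaImage (.mhd header + .raw, or single-file .mha) ------------------

metaimage_types <- c(MET_DOUBLE = "double", MET_FLOAT = "float",
                     MET_SHORT = "short", MET_USHORT = "ushort",
                     MET_UCHAR = "uchar", MET_INT = "int")

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (!length(line)) stop("MetaImage header has no ElementDataFile: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  type <- hdr$ElementType %||% "MET_DOUBLE"
  if (!type %in% names(metaimage_types))
    stop("unsupported MetaImage ElementType: ", type)
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MetaImage data is not supported")
  n <- prod(dims)
  what <- switch(type, MET_DOUBLE = , MET_FLOAT = numeric(), integer())
  size <- switch(type, MET_DOUBLE = 8, MET_FLOAT = 4, MET_SHORT = ,
                 MET_USHORT = 2, MET_UCHAR = 1, MET_INT = 4)
  signed <- !type %in% c("MET_USHORT", "MET_UCHAR")
  if (hdr$ElementDataFile == "LOCAL") {
    raw <- readBin(con, what, n = n, size = size, signed = signed,
                   endian = "little")
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath)) stop("MetaImage raw file missing: ", rawpath)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, what, n = n, size = size, signed = signed,
                   endian = "little")
  }
  if (length(raw) != n) stop("MetaImage raw data truncated: ", path)
  list(data = array(as.numeric(raw), dim = dims), spacing = spacing,
       origin = origin)
}

write_metaimage <- function(v, path) {
  local_data <- grepl("\\.mha$", path, ignore.case = TRUE)
  rawname <- paste0(basename(strip_volume_ext(path)), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("DimSize =", paste(dim(v$data), collapse = " ")),
           paste("ElementSpacing =",
                 paste(sprintf("%.17g", v$spacing), collapse = " ")),
           paste("Offset =",
                 paste(sprintf("%.17g", v$origin), collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", if (local_data) "LOCAL" else rawname))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local_data) {
    writeBin(as.numeric(v$data), con, size = 8, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(v$data), rcon, size = 8, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero out sub-threshold voxels
#'
#' Retains the density of voxels at or above `level` and sets all others to
#' zero — a simple bone-extraction step for CT volumes where soft tissue
#' would otherwise contribute to the rendered projections. Landmarks are
#' carried over unchanged.
#'
#' @param v A [density_volume()].
#' @param level Density threshold.
#' @return A [density_volume()].
#' @export
threshold_bone <- function(v, level) {
  stopifnot(inherits(v, "density_volume"))
  d <- v$data
  d[d < level] <- 0
  density_volume(d, v$spacing, v$origin, v$landmarks)
}

#' Crop a volume to its nonzero support
#'
#' Crops to the tight bounding box of nonzero voxels, expanded by `margin`
#' millimetres (rounded up to whole voxels, clamped to the grid). The origin
#' is updated so that model coordinates of retained voxels — and hence
#' landmark positions — are unchanged.
#'
#' @param v A [density_volume()].
#' @param margin Margin in mm, >= 0.
#' @return A cropped [density_volume()].
#' @export
crop_to_mask <- function(v, margin = 0) {
  stopifnot(inherits(v, "density_volume"), margin >= 0)
  nz <- which(v$data != 0, arr.ind = TRUE)
  if (!nrow(nz)) stop("empty mask: volume has no nonzero voxel")
  mvox <- ceiling(margin / v$spacing - 1e-12)
  lo <- pmax(apply(nz, 2, min) - mvox, 1)
  hi <- pmin(apply(nz, 2, max) + mvox, dim(v$data))
  data <- v$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin <- v$origin + (lo - 1) * v$spacing
  density_volume(data, v$spacing, origin, v$landmarks)
}
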