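#' Scalar CT-like volume with voxel geometry
#'
#' A `scalar_volume` couples a 3-D intensity array with its voxel spacing and
#' world origin. All package code works in world millimetres; voxel indices
#' are 0-based in the mapping `world = origin + index * spacing` (axis-aligned
#' grids only: the deformation model never uses oblique direction cosines).
#'
#' @param data 3-D numeric array of intensities (arbitrary CT-like units).
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @return An object of class `scalar_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- scalar_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
#' voxel_to_world(v, rbind(c(0, 0, 0), c(3, 3, 3)))
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stopf("volume data must be a 3-D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stopf("origin must be 3 finite numbers")
  if (any(!is.finite(data))) stopf("volume data must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Map world coordinates (mm) to continuous 0-based voxel indices
#' @param vol a [scalar_volume()].
#' @param pts n x 3 matrix of world points (mm).
#' @return n x 3 matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

#' Map 0-based voxel indices to world coordinates (mm)
#' @inheritParams world_to_voxel
#' @param idx n x 3 matrix of (possibly fractional) 0-based voxel indices.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# World-space bounding box of the voxel-centre lattice.
volume_bounds <- function(vol) {
  rbind(vol$origin, vol$origin + (dim(vol$data) - 1L) * vol$spacing)
}

#' Trilinear interpolation of a volume at world points
#'
#' Points outside the voxel-centre lattice are clamped to the nearest in-volume
#' position (so they take the nearest in-volume value) and flagged.
#'
#' @inheritParams world_to_voxel
#' @return list with `values` (length n) and `clamped` (logical length n).
#' @export
vol_sample <- function(vol, pts) {
  ix <- world_to_voxel(vol, pts)
  dm <- dim(vol$data)
  hi <- dm - 1L
  clamped <- ix[, 1] < 0 | ix[, 2] < 0 | ix[, 3] < 0 |
    ix[, 1] > hi[1] | ix[, 2] > hi[2] | ix[, 3] > hi[3]
  for (a in 1:3) ix[, a] <- pmin(pmax(ix[, a], 0), hi[a])
  i0 <- floor(ix)
  f <- ix - i0
  i0 <- pmin(i0, matrix(rep(hi - 1L, each = nrow(ix)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- ix - i0
  # gather the 8 cell corners via linear indexing (1-based)
  lin <- function(dx, dy, dz) {
    (i0[, 1] + dx) + dm[1] * ((i0[, 2] + dy) + dm[2] * (i0[, 3] + dz)) + 1
  }
  d <- vol$data
  v000 <- d[lin(0, 0, 0)]; v100 <- d[lin(1, 0, 0)]
  v010 <- d[lin(0, 1, 0)]; v110 <- d[lin(1, 1, 0)]
  v001 <- d[lin(0, 0, 1)]; v101 <- d[lin(1, 0, 1)]
  v011 <- d[lin(0, 1, 1)]; v111 <- d[lin(1, 1, 1)]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  list(values = c0 * (1 - fz) + c1 * fz, clamped = clamped)
}

#' Read a volume (NIfTI or MetaImage)
#'
#' Supports `.nii`/`.nii.gz` (via RNifti) and `.mha`/`.mhd`. Files without
#' spacing metadata are refused rather than silently assumed to be 1 mm.
#' Only axis-aligned orientations are supported.
#'
#' @param path file path.
#' @return a [scalar_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0))
      stopf("NIfTI header of %s has no usable voxel spacing", path)
    x <- RNifti::xform(img)
    if (max(abs(x[1:3, 1:3] - diag(sp))) > 1e-6 * max(sp))
      stopf("only axis-aligned volumes are supported (oblique xform in %s)", path)
    scalar_volume(array(as.numeric(img), dim(img)[1:3]), sp, x[1:3, 4])
  } else if (grepl("\\.(mha|mhd)$", lp)) {
    read_metaimage(path)
  } else stopf("unsupported volume format: %s", path)
}

#' Write a volume (NIfTI or MetaImage)
#' @param vol a [scalar_volume()].
#' @param path output path; format chosen by extension (.nii/.nii.gz/.mha/.mhd).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scalar_volume"))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    m <- diag(4); diag(m)[1:3] <- vol$spacing; m[1:3, 4] <- vol$origin
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (grepl("\\.(mha|mhd)$", lp)) {
    write_metaimage(vol, path)
  } else stopf("unsupported volume format: %s", path)
  invisible(path)
}

# --- MetaImage (.mha single-file / .mhd + raw) ------------------------------

met_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
               MET_SHORT = "integer", MET_USHORT = "integer",
               MET_INT = "integer", MET_UINT = "integer",
               MET_FLOAT = "double", MET_DOUBLE = "double")
met_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
               MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stopf("truncated MetaImage header in %s", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stopf("malformed MetaImage header line: %s", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (isTRUE(toupper(hdr[["CompressedData"]] %||% "FALSE") == "TRUE"))
    stopf("compressed MetaImage data is not supported")
  if (is.null(hdr[["DimSize"]])) stopf("MetaImage header missing DimSize")
  dm <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp_key <- hdr[["ElementSpacing"]] %||% hdr[["ElementSize"]]
  if (is.null(sp_key))
    stopf("MetaImage header of %s has no ElementSpacing; refusing to assume 1 mm", path)
  sp <- as.numeric(strsplit(sp_key, "\\s+")[[1]])
  org <- as.numeric(strsplit(hdr[["Offset"]] %||% hdr[["Position"]] %||% "0 0 0",
                             "\\s+")[[1]])
  ty <- hdr[["ElementType"]] %||% "MET_DOUBLE"
  if (!ty %in% names(met_types)) stopf("unsupported MetaImage ElementType %s", ty)
  msb <- toupper(hdr[["ElementByteOrderMSB"]] %||%
                   hdr[["BinaryDataByteOrderMSB"]] %||% "FALSE") == "TRUE"
  n <- prod(dm)
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    raw <- readBin(con, met_types[[ty]], n = n, size = met_sizes[[ty]],
                   signed = !ty %in% c("MET_UCHAR", "MET_USHORT"),
                   endian = if (msb) "big" else "little")
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath)) stopf("MetaImage data file not found: %s", rawpath)
    rcon <- file(rawpath, "rb"); on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, met_types[[ty]], n = n, size = met_sizes[[ty]],
                   signed = !ty %in% c("MET_UCHAR", "MET_USHORT"),
                   endian = if (msb) "big" else "little")
  }
  if (length(raw) != n) stopf("MetaImage data shorter than DimSize implies")
  scalar_volume(array(as.numeric(raw), dm), sp, org)
}

write_metaimage <- function(vol, path) {
  mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (mhd) sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
              else "LOCAL"
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("DimSize =", paste(dim(vol$data), collapse = " ")),
           paste("ElementSpacing =", paste(format(vol$spacing, digits = 17), collapse = " ")),
           paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (!mhd) {
    writeBin(as.numeric(vol$data), con, size = 8L, endian = "little")
    close(con)
  } else {
    close(con)
    rcon <- file(file.path(dirname(path), datafile), "wb")
    writeBin(as.numeric(vol$data), rcon, size = 8L, endian = "little")
    close(rcon)
  }
  invisible(path)
}
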