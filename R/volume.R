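# CT volume container and volumetric file I/O.
#
# Conventions: arrays are indexed (z, y, x), 1-based in R; spacing is the
# voxel edge length in mm per axis (z, y, x); origin is the world coordinate
# (mm) of the centre of voxel (1, 1, 1). Hounsfield units throughout.

#' Construct a CT volume
#'
#' A `ct_volume` is a 3D grid of Hounsfield-unit values with isotropic (or
#' per-axis) voxel spacing in mm and a world origin at the centre of the
#' first voxel. Axis order is fixed as (z, y, x).
#'
#' @param data 3D numeric array of HU values, dimension (nz, ny, nx).
#' @param spacing voxel edge length in mm; a single value (isotropic) or one
#'   per axis. All values must be > 0.
#' @param origin world coordinate (mm) of the centre of voxel (1, 1, 1);
#'   defaults to placing the world origin at the grid centre.
#' @return An object of class `ct_volume` with elements `data`, `spacing`,
#'   `origin`.
#' @examples
#' vol <- ct_volume(array(-1000, c(8, 8, 8)), spacing = 0.5)
#' voxel_volume(vol)  # 0.125 mm^3
#' @export
ct_volume <- function(data, spacing = 1, origin = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  if (any(!is.finite(data)))
    stop("HU values must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ct_volume: %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing : %s mm  (voxel volume %.6g mm^3)\n",
              paste(format(x$spacing), collapse = " x "), voxel_volume(x)))
  cat(sprintf("  origin  : (%s) mm\n", paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  HU range: [%.1f, %.1f]\n", min(x$data), max(x$data)))
  qc <- qc_hu_range(x)
  if (!qc$ok)
    cat(sprintf("  QC: %d voxels outside the expected HU range [-1024, 3072]\n",
                qc$n_outside))
  invisible(x)
}

#' Voxel volume in mm^3
#'
#' @param vol a `ct_volume` (or anything with a `spacing` element).
#' @return Product of the three spacings, in mm^3.
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' Flag HU values outside the plausible CT range
#'
#' CT values are expected within \[-1024, +3072\]; values outside usually
#' indicate a unit or calibration problem and are flagged, not rejected.
#'
#' @param vol a `ct_volume`.
#' @param range plausible HU interval.
#' @return list with `ok` (logical) and `n_outside`.
#' @export
qc_hu_range <- function(vol, range = c(-1024, 3072)) {
  n <- sum(vol$data < range[1] | vol$data > range[2])
  list(ok = n == 0L, n_outside = n)
}

#' Construct a voxel mask
#'
#' A boolean grid congruent with a parent `ct_volume`, tagging a role such
#' as "body", "fat" or "bed".
#'
#' @param data 3D logical array, same dimension as the parent volume.
#' @param label free-text role of the mask.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(data, label = "mask") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask must not contain NA")
  structure(list(data = data, label = as.character(label)[1]),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_mask '%s': %d of %d voxels (%d x %d x %d)\n",
              x$label, n_voxels(x), prod(d), d[1], d[2], d[3]))
  invisible(x)
}

#' Number of voxels set in a mask
#' @param mask a `voxel_mask`.
#' @return integer voxel count.
#' @export
n_voxels <- function(mask) sum(mask$data)

check_congruent <- function(vol, mask, what = "mask") {
  if (!identical(dim(vol$data), dim(mask$data)))
    stop(sprintf("%s shape %s does not match volume shape %s", what,
                 paste(dim(mask$data), collapse = "x"),
                 paste(dim(vol$data), collapse = "x")))
  invisible(TRUE)
}

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) return("metaimage")
  stop("cannot infer volume format from extension of '", path,
       "' (use format = 'nifti' or 'metaimage')")
}

#' Read a volumetric image
#'
#' Reads NIfTI-1 (.nii/.nii.gz) or MetaImage (.mha/.mhd) volumes into a
#' `ct_volume`. Spacing metadata must be present and positive; a file
#' without usable spacing is an error, never silently assumed to be 1 mm.
#' Data are returned in (z, y, x) axis order.
#'
#' @param path file path.
#' @param format "nifti", "metaimage", or NULL to infer from the extension.
#' @return A `ct_volume`.
#' @export
read_volume <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(format)) format <- guess_format(path)
  format <- match.arg(format, c("nifti", "metaimage"))
  if (format == "nifti") read_nifti_volume(path) else read_meta_volume(path)
}

#' Write a volumetric image
#'
#' Writes a `ct_volume` (or a `voxel_mask`, stored as 0/1) to NIfTI-1 or
#' MetaImage. Data, spacing and origin round-trip losslessly within
#' floating-point representation.
#'
#' @param vol a `ct_volume` or `voxel_mask`.
#' @param path output path; parent directory must exist.
#' @param format "nifti", "metaimage", or NULL to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  if (inherits(vol, "voxel_mask"))
    vol <- ct_volume(array(as.double(vol$data), dim(vol$data)), spacing = 1)
  if (!inherits(vol, "ct_volume")) stop("`vol` must be a ct_volume or voxel_mask")
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  if (is.null(format)) format <- guess_format(path)
  format <- match.arg(format, c("nifti", "metaimage"))
  if (format == "nifti") write_nifti_volume(vol, path) else write_meta_volume(vol, path)
  invisible(path)
}

# -- NIfTI via RNifti ---------------------------------------------------------
# NIfTI stores (x, y, z); we permute to and from (z, y, x).

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("missing or non-positive spacing metadata in ", path)
  orig_xyz <- tryCatch(RNifti::origin(img), error = function(e) NULL)
  # RNifti::origin gives the voxel index of the world origin (1-based);
  # world coordinate of voxel (1,1,1) centre is -(origin - 1) * spacing.
  if (is.null(orig_xyz) || length(orig_xyz) < 3L || any(!is.finite(orig_xyz[1:3])))
    orig_xyz <- c(1, 1, 1)
  origin_xyz <- -(orig_xyz[1:3] - 1) * pd[1:3]
  ct_volume(aperm(arr, c(3, 2, 1)),
            spacing = rev(pd[1:3]),
            origin = rev(origin_xyz))
}

write_nifti_volume <- function(vol, path) {
  arr <- aperm(vol$data, c(3, 2, 1))        # to (x, y, z)
  sp <- rev(vol$spacing)
  or <- rev(vol$origin)
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, sp)
  xform <- rbind(cbind(diag(sp), or), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(xform, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xform, code = 2L))
  RNifti::writeNifti(img, path)
}

# -- MetaImage (.mha single-file / .mhd + .raw) -------------------------------
# Plain-text header followed by (or pointing to) raw little-endian voxels in
# x-fastest order, which matches NIfTI's on-disk layout.

meta_type_info <- function(element_type) {
  switch(element_type,
         MET_DOUBLE = list(what = "double", size = 8L, signed = TRUE),
         MET_FLOAT  = list(what = "double", size = 4L, signed = TRUE),
         MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
         MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
         MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
         MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
         stop("unsupported MetaImage ElementType: ", element_type))
}

read_meta_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header in ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr[["NDims"]] %||% "0")
  if (!identical(ndims, 3L)) stop("expected NDims = 3 in ", path)
  if (is.null(hdr[["ElementSpacing"]]))
    stop("missing ElementSpacing metadata in ", path)
  spacing_xyz <- as.numeric(strsplit(trimws(hdr[["ElementSpacing"]]), "\\s+")[[1]])
  if (length(spacing_xyz) != 3L || any(!is.finite(spacing_xyz)) || any(spacing_xyz <= 0))
    stop("missing or non-positive spacing metadata in ", path)
  dims_xyz <- as.integer(strsplit(trimws(hdr[["DimSize"]]), "\\s+")[[1]])
  if (length(dims_xyz) != 3L || any(is.na(dims_xyz)))
    stop("missing or malformed DimSize in ", path)
  offset_xyz <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(trimws(hdr[["Offset"]]), "\\s+")[[1]]) else c(0, 0, 0)
  if (isTRUE(toupper(hdr[["CompressedData"]] %||% "FALSE") == "TRUE"))
    stop("compressed MetaImage data is not supported")
  msb <- toupper(hdr[["BinaryDataByteOrderMSB"]] %||% "FALSE") == "TRUE"
  ti <- meta_type_info(hdr[["ElementType"]] %||% "MET_DOUBLE")
  n <- prod(dims_xyz)
  datafile <- hdr[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    raw <- readBin(con, what = ti$what, n = n, size = ti$size,
                   signed = ti$signed, endian = if (msb) "big" else "little")
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath)) stop("MetaImage data file not found: ", rawpath)
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    raw <- readBin(con2, what = ti$what, n = n, size = ti$size,
                   signed = ti$signed, endian = if (msb) "big" else "little")
  }
  if (length(raw) != n) stop("truncated MetaImage voxel data in ", path)
  arr <- array(as.double(raw), dim = dims_xyz)  # (x, y, z)
  ct_volume(aperm(arr, c(3, 2, 1)),
            spacing = rev(spacing_xyz),
            origin = rev(offset_xyz))
}

write_meta_volume <- function(vol, path) {
  dims_xyz <- rev(dim(vol$data))
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(rev(vol$origin), digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(rev(vol$spacing), digits = 17), collapse = " ")),
    paste("DimSize =", paste(dims_xyz, collapse = " ")),
    "ElementType = MET_DOUBLE")
  arr <- aperm(vol$data, c(3, 2, 1))  # x fastest on disk
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(header, paste("ElementDataFile =", rawname)), path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.vector(arr), con, size = 8L, endian = "little")
  } else {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(c(header, "ElementDataFile = LOCAL"), con)
    writeBin(as.vector(arr), con, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- Reduction ----------------------------------------------------------------

pool_first_axis <- function(a, f) {
  d <- dim(a)
  m <- d[1] %/% f
  if (m * f != d[1]) a <- a[seq_len(m * f), , , drop = FALSE]
  # consecutive groups of f along axis 1 become matrix columns
  pooled <- colSums(matrix(a, nrow = f)) / f
  array(pooled, c(m, d[2], d[3]))
}

#' Reduce a volume by mean pooling
#'
#' Downsamples a `ct_volume` by an integer factor using block mean pooling
#' (the image-reduction step used to keep analysis tractable). Trailing
#' partial blocks along any axis are dropped. Mean pooling preserves the
#' volume-weighted mean HU of fully covered regions, which the downstream
#' density-window segmentation depends on.
#'
#' @param vol a `ct_volume`.
#' @param factor positive integer pooling factor; 1 returns the volume
#'   unchanged.
#' @return A `ct_volume` with spacing multiplied by `factor` and the origin
#'   moved to the centre of the first pooled block.
#' @export
reduce_volume <- function(vol, factor) {
  if (!inherits(vol, "ct_volume")) stop("`vol` must be a ct_volume")
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be a positive integer")
  if (factor == 1L) return(vol)
  if (any(dim(vol$data) < factor)) stop("`factor` exceeds a volume dimension")
  a <- vol$data
  for (axis in 1:3) {
    a <- pool_first_axis(a, factor)
    a <- aperm(a, c(2, 3, 1))
  }
  # three rotations restore (z, y, x) order
  ct_volume(a, spacing = vol$spacing * factor,
            origin = vol$origin + (factor - 1) / 2 * vol$spacing)
}
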