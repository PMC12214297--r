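#' Label volumes
#'
#' A `label_volume` is the raw input of the measurement pipeline: a 3D grid of
#' integer labels (0 = background) together with the geometric metadata that
#' maps voxel indices to physical millimetre coordinates. The physical
#' coordinate of voxel index `(i, j, k)` (1-based) is
#' `origin + (i-1, j-1, k-1) * spacing` (voxel-centre convention), and all
#' downstream geometry is computed in this millimetre space so that
#' anisotropic inputs cannot silently corrupt distances.
#'
#' @param data 3D integer array of labels; 0 is background.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, physical mm coordinate of the centre of
#'   voxel (1,1,1).
#' @param axis_orientation tag recording the anatomical axis convention of
#'   the grid; the package's canonical order is `"LPS->RAS"`-agnostic
#'   `(x, y, z) = (L-R, P-A, I-S)` and readers record the original code here.
#' @return An object of class `label_volume` with fields `data`, `spacing`,
#'   `origin`, `axis_orientation` and logical `isotropic` (TRUE iff the
#'   max/min spacing ratio is at most 1.01).
#' @export
label_volume <- function(data, spacing = c(0.1, 0.1, 0.1), origin = c(0, 0, 0),
                         axis_orientation = "LPI") {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  if (any(data != round(data), na.rm = TRUE))
    stop("label volumes must be integer-valued", call. = FALSE)
  if (any(data < 0)) stop("labels must be non-negative integers", call. = FALSE)
  iso <- (max(spacing) / min(spacing)) <= 1.01
  if (!iso)
    warning("anisotropic voxel spacing (ratio ", format(max(spacing) / min(spacing), digits = 4),
            "); geometry is computed in physical mm, but the study design assumes isotropic grids",
            call. = FALSE)
  structure(
    list(data = array(as.integer(round(data)), dim(data)),
         spacing = spacing, origin = origin,
         axis_orientation = axis_orientation, isotropic = iso),
    class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- sort(unique(as.vector(x$data)))
  cat("<label_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = "/"), " mm",
      if (x$isotropic) " (isotropic)" else " (ANISOTROPIC)", "\n", sep = "")
  cat("  labels: ", paste(labs, collapse = ", "),
      "; origin ", paste(format(x$origin), collapse = ", "), " mm\n", sep = "")
  invisible(x)
}

#' Ossicle label assignment
#'
#' Maps the three ossicles to integer labels of a segmentation volume. The
#' defaults (malleus = 1, incus = 2, stapes = 3) are a package convention;
#' clinical masks should be remapped through this object.
#'
#' @param malleus,incus,stapes distinct non-zero integer labels.
#' @export
ossicle_label_map <- function(malleus = 1L, incus = 2L, stapes = 3L) {
  labs <- c(malleus = as.integer(malleus), incus = as.integer(incus),
            stapes = as.integer(stapes))
  if (any(labs <= 0L) || anyDuplicated(labs))
    stop("ossicle labels must be distinct non-zero integers", call. = FALSE)
  structure(as.list(labs), class = "ossicle_label_map")
}

#' Read a 3D label volume
#'
#' Reads NIfTI (`.nii`, `.nii.gz`) via \pkg{RNifti} or an uncompressed local
#' MetaImage (`.mha`) file, taking voxel spacing and origin from the header
#' and reorienting nothing: the grid is used as stored, with the orientation
#' code recorded on the returned object.
#'
#' @param path file path.
#' @return A [label_volume].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  ext <- tolower(sub("^.*?(\\.nii(\\.gz)?|\\.mha)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    spc <- attr(img, "pixdim")
    if (is.null(spc)) spc <- RNifti::pixdim(img)
    spc <- as.numeric(spc)[seq_len(3)]
    if (any(!is.finite(spc)) || any(spc <= 0))
      stop("missing or invalid voxel spacing in NIfTI header", call. = FALSE)
    dat <- as.array(img)
    if (length(dim(dat)) > 3L) dat <- array(dat, dim(dat)[1:3])
    if (any(dat != round(dat)))
      stop("voxel data are not integer-valued; not a label volume", call. = FALSE)
    orient <- tryCatch(RNifti::orientation(img), error = function(e) "unknown")
    org <- tryCatch({
      xf <- RNifti::xform(img)
      as.numeric(xf[1:3, 4])
    }, error = function(e) c(0, 0, 0))
    label_volume(dat, spacing = spc, origin = org, axis_orientation = orient)
  } else if (ext == ".mha") {
    read_metaimage(path)
  } else {
    stop("unsupported volume format: '", path,
         "' (expected .nii, .nii.gz or .mha)", call. = FALSE)
  }
}

#' Write a 3D label volume
#'
#' Inverse of [read_label_volume()]; the write/read round trip preserves grid
#' values, spacing and origin exactly for integer data.
#'
#' @param vol a [label_volume].
#' @param path output path ending in `.nii`, `.nii.gz` or `.mha`.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  ext <- tolower(sub("^.*?(\\.nii(\\.gz)?|\\.mha)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    arr <- structure(vol$data, pixdim = vol$spacing, pixunits = "mm")
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
  } else if (ext == ".mha") {
    write_metaimage(vol, path)
  } else {
    stop("unsupported output format for '", path, "'", call. = FALSE)
  }
  invisible(path)
}

# Minimal uncompressed MetaImage IO (local raw, MET_SHORT), enough for the
# label-volume contract; intensity volumes and compressed variants are out of
# scope.
read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("malformed MetaImage header", call. = FALSE)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only local-raw MetaImage files are supported", call. = FALSE)
  dm <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spc <- if (!is.null(hdr[["ElementSpacing"]]))
    as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]]) else
      stop("missing ElementSpacing in MetaImage header", call. = FALSE)
  org <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  typ <- hdr[["ElementType"]]
  n <- prod(dm)
  raw <- switch(typ,
    MET_UCHAR = readBin(con, "integer", n, size = 1L, signed = FALSE),
    MET_CHAR = readBin(con, "integer", n, size = 1L, signed = TRUE),
    MET_SHORT = readBin(con, "integer", n, size = 2L, signed = TRUE),
    MET_USHORT = readBin(con, "integer", n, size = 2L, signed = FALSE),
    MET_INT = readBin(con, "integer", n, size = 4L),
    stop("non-integer MetaImage element type '", typ, "'", call. = FALSE))
  label_volume(array(raw, dm), spacing = spc, origin = org, axis_orientation = "MHA")
}

write_metaimage <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(vol$data), collapse = " ")),
           paste("ElementSpacing =", paste(format(vol$spacing, digits = 17), collapse = " ")),
           paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
           "ElementType = MET_SHORT", "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.integer(vol$data), con, size = 2L)
  invisible(path)
}

#' Extract a binary mask for one label
#'
#' @param vol a [label_volume].
#' @param label integer label to extract; if absent an all-zero mask is
#'   returned with a warning.
#' @return A binary [label_volume] (values 0/1) on the same grid.
#' @export
extract_label_mask <- function(vol, label) {
  stopifnot(inherits(vol, "label_volume"))
  m <- vol$data == as.integer(label)
  if (!any(m))
    warning("label ", label, " not present in volume; returning empty mask", call. = FALSE)
  label_volume(array(as.integer(m), dim(vol$data)),
               spacing = vol$spacing, origin = vol$origin,
               axis_orientation = vol$axis_orientation)
}

#' Voxel coordinates of a volume grid axis
#' @keywords internal
grid_axis <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis]
}

# Crop a binary mask volume to its tight bounding box plus `margin_vox`
# voxels of background padding; keeps physical coordinates consistent.
crop_mask <- function(vol, margin_vox = 4L) {
  idx <- which(vol$data != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask", call. = FALSE)
  lo <- pmax(apply(idx, 2, min) - margin_vox, 1L)
  hi <- pmin(apply(idx, 2, max) + margin_vox, dim(vol$data))
  sub <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  label_volume(sub, spacing = vol$spacing,
               origin = vol$origin + (lo - 1) * vol$spacing,
               axis_orientation = vol$axis_orientation)
}
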