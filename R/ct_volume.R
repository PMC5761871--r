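#' CT volume in Hounsfield units
#'
#' Container for a 3D chest CT scan on an isotropic grid. The array is
#' stored `[z, y, x]`: the first dimension is the cranio-caudal slice
#' index, the second the in-slice row, the third the in-slice column
#' (left-right). Indices reported by lungquant functions are 1-based; the
#' world position of a voxel centre is `index * voxel_edge_um`.
#'
#' @param intensities 3D numeric array of HU values. HU must be
#'   representable at least over \[-1024, 3071\]; values are stored as
#'   given (clamping to the \[-1000, 1000\] histogram domain happens only
#'   at histogram time).
#' @param voxel_edge_um positive scalar, edge length of the isotropic
#'   voxel in micrometres (the reference acquisition uses 35 um).
#' @return An object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(-800, dim = c(4, 4, 4)), voxel_edge_um = 35)
#' dim(vol)
#' @export
ct_volume <- function(intensities, voxel_edge_um = 35) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array")
  if (any(dim(intensities) < 1L))
    stop("all three dimensions must be >= 1")
  if (!is.numeric(voxel_edge_um) || length(voxel_edge_um) != 1L ||
      !is.finite(voxel_edge_um) || voxel_edge_um <= 0)
    stop("`voxel_edge_um` must be a positive scalar")
  storage.mode(intensities) <- "double"
  structure(
    list(intensities = intensities, voxel_edge_um = as.numeric(voxel_edge_um)),
    class = "ct_volume"
  )
}

#' @export
dim.ct_volume <- function(x) dim(x$intensities)

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ct_volume> %d x %d x %d voxels @ %.6g um (%.2f mm3 total)\n",
              d[1], d[2], d[3], x$voxel_edge_um,
              prod(d) * (x$voxel_edge_um / 1000)^3))
  cat(sprintf("  HU range: [%.1f, %.1f]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Convert voxel counts to physical volume
#'
#' @param n_voxels nonnegative voxel count(s).
#' @param voxel_edge_um isotropic voxel edge length in micrometres.
#' @return Volume in cubic millimetres: `n * (voxel_edge_um / 1000)^3`.
#' @export
voxels_to_mm3 <- function(n_voxels, voxel_edge_um) {
  n_voxels * (voxel_edge_um / 1000)^3
}

#' Apply the CT rescale transform to stored pixel values
#'
#' CT rasters are commonly stored as unsigned integers together with a
#' linear rescale (slope, intercept) that maps stored values to Hounsfield
#' units, e.g. slope 1 and intercept -1024 map a stored 224 to -800 HU.
#'
#' @param stored numeric vector/array of stored pixel values.
#' @param slope,intercept rescale coefficients.
#' @return `stored * slope + intercept`, in HU.
#' @export
apply_hu_rescale <- function(stored, slope, intercept) {
  if (!is.finite(slope) || !is.finite(intercept))
    stop("rescale slope/intercept must be finite")
  stored * slope + intercept
}

#' Read a CT volume from disk
#'
#' Reads a NIfTI volume (any extension RNifti understands: `.nii`,
#' `.nii.gz`) whose stored values are already Hounsfield units, taking the
#' voxel size from the header. Anisotropic voxels are rejected unless
#' `allow_anisotropic = TRUE` (the mean edge is then used). DICOM series
#' directories are not read directly; convert to NIfTI first (any standard
#' converter applies the rescale slope/intercept, see
#' [apply_hu_rescale()]).
#'
#' @param path path to a NIfTI file.
#' @param allow_anisotropic accept anisotropic voxels, using the mean edge.
#' @return A [ct_volume()].
#' @export
read_ct <- function(path, allow_anisotropic = FALSE) {
  if (dir.exists(path))
    stop("`path` is a directory; DICOM series are not read directly - ",
         "convert the series to NIfTI (HU-valued) and pass the file")
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)[seq_len(3)]
  units <- RNifti::pixunits(img)
  # files without spatial units are taken as mm, the NIfTI convention
  scale <- if ("m" %in% units) 1e6 else if ("um" %in% units) 1 else 1e3
  edges_um <- pix * scale
  if (max(edges_um) - min(edges_um) > 1e-6 * max(edges_um)) {
    if (!allow_anisotropic)
      stop(sprintf("anisotropic voxels (%s um); pass allow_anisotropic = TRUE to use the mean edge",
                   paste(signif(edges_um, 4), collapse = " x ")))
  }
  ct_volume(array(as.numeric(img), dim = dim(img)),
            voxel_edge_um = mean(edges_um))
}

#' Write a CT volume or mask to NIfTI
#'
#' Masks are written as uint8 labels, volumes as floating point HU, with
#' the voxel size recorded in the header (micrometres written as
#' millimetres, the NIfTI convention).
#'
#' @param x a [ct_volume()], [seg_mask()] or plain 3D array.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param voxel_edge_um voxel edge; taken from `x` when it carries one.
#' @return `path`, invisibly.
#' @export
write_ct_nifti <- function(x, path, voxel_edge_um = NULL) {
  if (inherits(x, "ct_volume")) {
    arr <- x$intensities
    voxel_edge_um <- x$voxel_edge_um
    datatype <- "float"
  } else if (inherits(x, "seg_mask")) {
    arr <- array(as.integer(x$voxels), dim = dim(x$voxels))
    datatype <- "uint8"
  } else {
    arr <- x
    datatype <- if (is.logical(arr)) "uint8" else "float"
    if (is.logical(arr)) arr <- array(as.integer(arr), dim = dim(arr))
  }
  if (is.null(voxel_edge_um))
    stop("voxel_edge_um required when writing a bare mask/array")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_edge_um / 1000, 3)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
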