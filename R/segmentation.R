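#' Segmentation mask
#'
#' A boolean voxel grid congruent with its source [ct_volume()], tagged
#' with the anatomical label it represents.
#'
#' @param voxels 3D logical array.
#' @param label one of `"whole_lung"`, `"airway"`, `"left_lung"`,
#'   `"right_lung"`, `"aerated"`, `"tissue"`.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(voxels, label = "whole_lung") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.logical(voxels))
    stop("`voxels` must be a 3D logical array")
  label <- match.arg(label, c("whole_lung", "airway", "left_lung",
                              "right_lung", "aerated", "tissue"))
  structure(list(voxels = voxels, label = label), class = "seg_mask")
}

#' @export
dim.seg_mask <- function(x) dim(x$voxels)

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask '%s'> %s voxels set of %s\n", x$label,
              format(sum(x$voxels), big.mark = ","),
              format(length(x$voxels), big.mark = ",")))
  invisible(x)
}

mask_array <- function(m) if (inherits(m, "seg_mask")) m$voxels else m

check_congruent <- function(a, b, what = "mask") {
  if (!identical(dim(a), dim(b)))
    stop(what, " is not congruent with the volume/mask it applies to")
}

seed_to_linear <- function(seed, d) {
  if (length(seed) != 3L) stop("seed must be an index triple (z, y, x)")
  seed <- as.integer(seed)
  if (any(seed < 1L) || any(seed > d))
    stop("seed out of volume bounds")
  seed[1] + d[1] * ((seed[2] - 1L) + d[2] * (seed[3] - 1L))
}

#' Seeded region growing in an HU window
#'
#' Grows the 6-connected (face-neighbour) component of voxels whose HU
#' lies in `[low_hu, high_hu]` that contains the seed — the "magic wand"
#' operation used to pull the lung out of the thorax with a seed in the
#' bronchus and a window of -1000 to -150 HU. If the seed voxel itself is
#' out of the window the result is an empty mask.
#'
#' @param volume a [ct_volume()].
#' @param seed 1-based voxel index triple `(z, y, x)`.
#' @param low_hu,high_hu inclusive HU window, `low_hu <= high_hu`.
#' @param label label for the returned [seg_mask()].
#' @return A [seg_mask()] of the grown region.
#' @examples
#' vol <- ct_volume(array(-800, dim = c(3, 3, 3)))
#' sum(seeded_region_grow(vol, c(2, 2, 2), -1000, -150)$voxels) # 27
#' @export
seeded_region_grow <- function(volume, seed, low_hu = -1000, high_hu = -150,
                               label = "whole_lung") {
  stopifnot(inherits(volume, "ct_volume"))
  if (low_hu > high_hu) stop("low_hu must be <= high_hu")
  d <- dim(volume)
  s <- seed_to_linear(seed, d)
  hu <- volume$intensities
  if (!is.finite(hu[s])) stop("non-finite HU at seed voxel")
  in_range <- is.finite(hu) & hu >= low_hu & hu <= high_hu
  grown <- .cpp_flood_fill6(as.logical(in_range), d, s - 1L)
  seg_mask(array(grown, dim = d), label = label)
}

shift3 <- function(m, axis, by) {
  # zero-padded shift of a logical array along one axis
  d <- dim(m)
  out <- array(FALSE, dim = d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  if (by > 0) {
    dst[[axis]] <- (1 + by):n
    src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    dst[[axis]] <- 1:(n + by)
    src[[axis]] <- (1 - by):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

dilate6_once <- function(m) {
  m | shift3(m, 1, 1) | shift3(m, 1, -1) |
      shift3(m, 2, 1) | shift3(m, 2, -1) |
      shift3(m, 3, 1) | shift3(m, 3, -1)
}

erode6_once <- function(m) {
  # outside the grid counts as background
  m & shift3(m, 1, 1) & shift3(m, 1, -1) &
      shift3(m, 2, 1) & shift3(m, 2, -1) &
      shift3(m, 3, 1) & shift3(m, 3, -1)
}

dilate6 <- function(m, r) { for (i in seq_len(r)) m <- dilate6_once(m); m }
erode6  <- function(m, r) { for (i in seq_len(r)) m <- erode6_once(m); m }

#' Fill enclosed cavities in a 3D mask
#'
#' Background components with no path (6-connectivity) to the grid
#' boundary are added to the mask.
#'
#' @param m 3D logical array.
#' @return 3D logical array with internal holes filled.
#' @export
fill_holes3d <- function(m) {
  d <- dim(m)
  lab <- array(.cpp_label_components6(!m, d), dim = d)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border != 0L]
  m | (lab != 0L & !(lab %in% border))
}

#' Morphological refinement of a segmentation mask
#'
#' Applies, in order: dilation by `grow_r`, erosion by `shrink_r`, 3D hole
#' filling (cavities not connected to the grid boundary), and smoothing
#' (morphological closing then opening by `smooth_r`). Structuring element
#' is the face-connected unit ball applied iteratively, so a radius-r step
#' reaches voxels within city-block distance r.
#'
#' @param mask a [seg_mask()] or 3D logical array.
#' @param grow_r,shrink_r,smooth_r nonnegative integer radii in voxels.
#' @param fill_holes logical, fill enclosed cavities.
#' @return A refined [seg_mask()] (same label). An empty result is legal
#'   and is reported with a warning.
#' @export
refine_mask <- function(mask, grow_r = 1, shrink_r = 1, fill_holes = TRUE,
                        smooth_r = 1) {
  lab <- if (inherits(mask, "seg_mask")) mask$label else "whole_lung"
  m <- mask_array(mask)
  stopifnot(grow_r >= 0, shrink_r >= 0, smooth_r >= 0)
  m <- dilate6(m, grow_r)
  m <- erode6(m, shrink_r)
  if (fill_holes) m <- fill_holes3d(m)
  if (smooth_r > 0) {
    m <- erode6(dilate6(m, smooth_r), smooth_r)   # closing
    m <- dilate6(erode6(m, smooth_r), smooth_r)   # opening
  }
  if (!any(m)) warning("refined mask is empty")
  seg_mask(m, label = lab)
}

#' Extract the conducting airway and measure local diameters
#'
#' Grows the air lumen from a trachea/bronchus seed within the lung mask,
#' restricted to voxels at or below `air_hu_max`, and assigns every airway
#' voxel an inscribed-sphere diameter from the exact Euclidean distance
#' transform: `local_diameter_um = (2 * d_bg - 1) * voxel_edge_um`, where
#' `d_bg` is the distance (voxel units) to the nearest non-air voxel
#' centre. A single-voxel tube therefore measures exactly one voxel edge.
#'
#' @param volume a [ct_volume()].
#' @param lung lung [seg_mask()] (pre airway exclusion).
#' @param trachea_seed 1-based `(z, y, x)` triple inside the lung mask at
#'   air density.
#' @param air_hu_max HU ceiling for lumen air (default -400).
#' @return An object of class `airway_segment`: list with `voxels`
#'   (logical array), `local_diameter_um` (numeric array, `NA` outside
#'   the airway) and `voxel_edge_um`.
#' @export
extract_airways <- function(volume, lung, trachea_seed, air_hu_max = -400) {
  stopifnot(inherits(volume, "ct_volume"))
  m <- mask_array(lung)
  d <- dim(volume)
  check_congruent(d, dim(m), "lung mask")
  s <- seed_to_linear(trachea_seed, d)
  hu <- volume$intensities
  if (!m[s]) stop("trachea seed is outside the lung mask")
  if (!(is.finite(hu[s]) && hu[s] <= air_hu_max))
    stop("trachea seed is not at air density (HU > air_hu_max)")
  candidate <- m & is.finite(hu) & hu <= air_hu_max
  lumen <- array(.cpp_flood_fill6(as.logical(candidate), d, s - 1L), dim = d)
  edt <- array(.cpp_edt3d(as.logical(lumen), d), dim = d)
  dia <- array(NA_real_, dim = d)
  dia[lumen] <- (2 * edt[lumen] - 1) * volume$voxel_edge_um
  structure(list(voxels = lumen, local_diameter_um = dia,
                 voxel_edge_um = volume$voxel_edge_um),
            class = "airway_segment")
}

#' @export
print.airway_segment <- function(x, ...) {
  n <- sum(x$voxels)
  cat(sprintf("<airway_segment> %d voxels", n))
  if (n > 0)
    cat(sprintf(", local diameter %.0f-%.0f um",
                min(x$local_diameter_um, na.rm = TRUE),
                max(x$local_diameter_um, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' Branch-level airway diameters (local thickness)
#'
#' For each airway voxel, the diameter of the largest inscribed sphere
#' that covers it. On a tubular branch this propagates the centreline
#' (medial-axis) inscribed-sphere diameter to the whole lumen, so a
#' 210-um branch measures 210 um wall-to-wall and is excluded as a unit
#' by [exclude_large_airways()].
#'
#' @param airways an `airway_segment` from [extract_airways()].
#' @return Numeric array of diameters in micrometres (`NA` outside).
#' @export
airway_branch_diameter <- function(airways) {
  stopifnot(inherits(airways, "airway_segment"))
  d <- dim(airways$voxels)
  mv <- as.logical(airways$voxels)
  edt <- .cpp_edt3d(mv, d)
  edt[!mv | !is.finite(edt)] <- 0
  # cover with the centre-to-background-centre radius so the whole lumen
  # cross-section is reached; report the wall-to-wall diameter (2d - 1)
  dia <- pmax(2 * edt - 1, 0)
  th <- .cpp_local_thickness(mv, edt, dia, d)
  out <- array(NA_real_, dim = d)
  out[mv] <- th[mv] * airways$voxel_edge_um
  out
}

#' Exclude large conducting airways from the lung mask
#'
#' Removes airway voxels whose branch-level diameter (local thickness,
#' see [airway_branch_diameter()]) exceeds the cutoff; smaller airways
#' remain part of the parenchymal mask. Never adds voxels.
#'
#' @param lung lung [seg_mask()].
#' @param airways an `airway_segment`.
#' @param diameter_cutoff_um exclusion cutoff, default 200 um.
#' @return A [seg_mask()] with the large-airway lumen removed; the set of
#'   removed voxels is attached as attribute `"excluded"`.
#' @export
exclude_large_airways <- function(lung, airways, diameter_cutoff_um = 200) {
  m <- mask_array(lung)
  check_congruent(dim(m), dim(airways$voxels), "airway mask")
  branch_dia <- airway_branch_diameter(airways)
  big <- airways$voxels & !is.na(branch_dia) & branch_dia > diameter_cutoff_um
  out <- seg_mask(m & !big, label = if (inherits(lung, "seg_mask")) lung$label else "whole_lung")
  attr(out, "excluded") <- big
  out
}

#' Split the lung mask into left and right lungs
#'
#' After large-airway exclusion the two lungs normally fall apart into
#' separate 6-connected components; each component is assigned a side by
#' the sign of its centroid's left-right coordinate relative to the
#' carina's sagittal plane (the column coordinate of the airway
#' centroid). If the mask remains a single component, a user-supplied
#' sagittal split column partitions the voxels instead; with neither, the
#' split fails explicitly.
#'
#' @param lung lung [seg_mask()] with large airways already excluded.
#' @param airways `airway_segment` used to locate the carina plane;
#'   optional when `split_col` is given.
#' @param split_col optional fallback: sagittal plane position in voxel
#'   units along the column (3rd) axis; voxels with column centre below
#'   it go left.
#' @return A list with `left` and `right` [seg_mask()]s and `status`
#'   (`"components"`, `"plane"`, or the function stops with
#'   "split failed" if neither strategy applies).
#' @export
split_left_right <- function(lung, airways = NULL, split_col = NULL) {
  m <- mask_array(lung)
  d <- dim(m)
  if (!any(m)) stop("empty lung mask")
  carina_col <- if (!is.null(airways) && any(airways$voxels)) {
    mean(arrayInd(which(airways$voxels), d)[, 3])
  } else (d[3] + 1) / 2

  lab <- array(.cpp_label_components6(m, d), dim = d)
  ncomp <- max(lab)
  status <- "components"
  side <- NULL
  if (ncomp >= 2) {
    # assign every component by centroid side; tiny debris follows suit
    idx <- arrayInd(which(m), d)
    labv <- lab[m]
    cent <- tapply(idx[, 3], labv, mean)
    left_labels <- as.integer(names(cent))[cent < carina_col]
    left <- array(lab != 0L & (lab %in% left_labels), dim = d)
    right <- m & !left
    if (!any(left) || !any(right)) ncomp <- 1   # all fell on one side
  }
  if (ncomp < 2) {
    if (is.null(split_col))
      stop("split failed: lungs form a single connected component and no split_col was supplied")
    status <- "plane"
    colpos <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
    left <- m & (colpos < split_col)
    right <- m & !(colpos < split_col)
  }
  list(left = seg_mask(left, "left_lung"),
       right = seg_mask(right, "right_lung"),
       status = status)
}
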