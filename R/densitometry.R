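#' Intensity histogram over the standard HU domain
#'
#' Counts of masked voxels per 1-HU bin over \[-1000, 1000\] (2001 bins,
#' bin value = bin centre). Values outside the domain are clamped to its
#' ends before binning; non-integer HU goes to the nearest integer bin
#' (ties toward even).
#'
#' @param volume a [ct_volume()].
#' @param mask a [seg_mask()] or congruent logical array.
#' @return An object of class `intensity_histogram`: list with `bin_hu`
#'   (-1000:1000), `counts` (integer), `source_label`, `voxel_edge_um`.
#'   An empty mask yields all-zero counts with a warning.
#' @export
build_histogram <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"))
  lab <- if (inherits(mask, "seg_mask")) mask$label else "whole_lung"
  m <- mask_array(mask)
  check_congruent(dim(volume), dim(m), "mask")
  hu <- volume$intensities[m]
  if (length(hu) == 0L) {
    warning("empty mask: histogram has all-zero counts")
    counts <- integer(2001)
  } else {
    b <- round(pmin(pmax(hu, -1000), 1000))   # clamp, ties to even
    counts <- tabulate(as.integer(b) + 1001L, nbins = 2001L)
  }
  new_intensity_histogram(counts, source_label = lab,
                          voxel_edge_um = volume$voxel_edge_um)
}

new_intensity_histogram <- function(counts, source_label = "whole_lung",
                                    voxel_edge_um = NA_real_) {
  counts <- as.numeric(counts)
  if (length(counts) != 2001L) stop("histogram must have exactly 2001 bins")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("histogram counts must be finite and nonnegative")
  structure(list(bin_hu = -1000:1000, counts = counts,
                 source_label = source_label,
                 voxel_edge_um = voxel_edge_um),
            class = "intensity_histogram")
}

#' Construct an intensity histogram from counts
#'
#' @param counts nonnegative counts for the 2001 1-HU bins from -1000 to
#'   1000 HU (in that order).
#' @param source_label mask label the histogram summarizes.
#' @param voxel_edge_um voxel size carried along for volume conversion.
#' @return An `intensity_histogram`.
#' @export
intensity_histogram <- function(counts, source_label = "whole_lung",
                                voxel_edge_um = NA_real_) {
  new_intensity_histogram(counts, source_label, voxel_edge_um)
}

#' @export
print.intensity_histogram <- function(x, ...) {
  n <- sum(x$counts)
  cat(sprintf("<intensity_histogram '%s'> %s voxels", x$source_label,
              format(n, big.mark = ",")))
  if (n > 0)
    cat(sprintf(", weighted mean %.1f HU, occupied [%d, %d] HU",
                weighted_mean_hu(x),
                min(x$bin_hu[x$counts > 0]), max(x$bin_hu[x$counts > 0])))
  cat("\n")
  invisible(x)
}

#' @export
plot.intensity_histogram <- function(x, threshold_hu = NULL, ...) {
  plot(x$bin_hu, x$counts, type = "l", xlab = "HU", ylab = "voxels",
       main = paste0("Density histogram (", x$source_label, ")"), ...)
  if (!is.null(threshold_hu)) {
    abline(v = threshold_hu, lty = 2)
    legend("topright", legend = sprintf("threshold %d HU", threshold_hu),
           lty = 2, bty = "n")
  }
  invisible(x)
}

#' Histogram-weighted mean density
#'
#' The count-weighted average HU of a segmented lung:
#' `sum(w_i * x_i) / sum(w_i)` over the 2001 bins.
#'
#' @param hist an `intensity_histogram`.
#' @return Weighted mean in HU.
#' @export
weighted_mean_hu <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  tot <- sum(hist$counts)
  if (tot <= 0) stop("weighted mean undefined: histogram has zero total count")
  sum(hist$counts * hist$bin_hu) / tot
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive the aerated/tissue threshold from a wild-type cohort
#'
#' Pools the control (WT) histograms and returns the pooled central
#' density rounded to integer HU (ties away from zero). The default pools
#' voxel counts bin-wise and takes the pooled weighted mean
#' (voxel-weighted); `method = "mouse_mean"` averages per-mouse weighted
#' means instead, and `method = "mode"` returns the pooled histogram mode
#' (the most abundant density).
#'
#' @param wt_histograms list of `intensity_histogram`s, one or more, each
#'   with positive total count.
#' @param method `"pooled_mean"` (default), `"mouse_mean"` or `"mode"`.
#' @return Integer HU threshold.
#' @export
derive_threshold <- function(wt_histograms,
                             method = c("pooled_mean", "mouse_mean", "mode")) {
  method <- match.arg(method)
  if (inherits(wt_histograms, "intensity_histogram"))
    wt_histograms <- list(wt_histograms)
  if (length(wt_histograms) == 0L) stop("need at least one WT histogram")
  ok <- vapply(wt_histograms, inherits, logical(1), "intensity_histogram")
  if (!all(ok)) stop("all inputs must be intensity_histogram objects")
  totals <- vapply(wt_histograms, function(h) sum(h$counts), numeric(1))
  if (any(totals <= 0)) stop("every WT histogram must have a positive total count")
  pooled <- Reduce(`+`, lapply(wt_histograms, `[[`, "counts"))
  val <- switch(method,
    pooled_mean = sum(pooled * (-1000:1000)) / sum(pooled),
    mouse_mean  = mean(vapply(wt_histograms, weighted_mean_hu, numeric(1))),
    mode        = (-1000:1000)[which.max(pooled)]
  )
  as.integer(round_half_away(val))
}

#' Partition a histogram into aerated and tissue volumes
#'
#' Voxels strictly below the threshold are aerated; voxels at or above it
#' are tissue (the threshold bin — the air/epithelium interface density —
#' is assigned to tissue). Converts voxel counts to mm3 and normalized
#' fractions.
#'
#' @param hist an `intensity_histogram`.
#' @param threshold_hu integer HU threshold in \[-1000, 1000\].
#' @param voxel_edge_um voxel edge in micrometres; defaults to the value
#'   carried by the histogram.
#' @return An object of class `volume_outcomes`.
#' @export
partition_volumes <- function(hist, threshold_hu,
                              voxel_edge_um = hist$voxel_edge_um) {
  stopifnot(inherits(hist, "intensity_histogram"))
  if (threshold_hu < -1000 || threshold_hu > 1000)
    stop("threshold must lie within [-1000, 1000] HU")
  if (is.na(voxel_edge_um))
    stop("voxel_edge_um needed to convert voxels to mm3")
  aer <- sum(hist$counts[hist$bin_hu < threshold_hu])
  tis <- sum(hist$counts[hist$bin_hu >= threshold_hu])
  tot <- aer + tis
  structure(list(
    source_label = hist$source_label,
    threshold_hu = as.integer(threshold_hu),
    weighted_mean_hu = if (tot > 0) weighted_mean_hu(hist) else NA_real_,
    total_voxels = tot, aerated_voxels = aer, tissue_voxels = tis,
    total_mm3 = voxels_to_mm3(tot, voxel_edge_um),
    aerated_mm3 = voxels_to_mm3(aer, voxel_edge_um),
    tissue_mm3 = voxels_to_mm3(tis, voxel_edge_um),
    aerated_fraction = if (tot > 0) aer / tot else NA_real_,
    tissue_fraction = if (tot > 0) tis / tot else NA_real_,
    voxel_edge_um = voxel_edge_um
  ), class = "volume_outcomes")
}

#' @export
print.volume_outcomes <- function(x, ...) {
  cat(sprintf("<volume_outcomes '%s'> threshold %d HU\n",
              x$source_label, x$threshold_hu))
  cat(sprintf("  weighted mean density: %.1f HU\n", x$weighted_mean_hu))
  cat(sprintf("  total:   %9d vox  %8.2f mm3\n", x$total_voxels, x$total_mm3))
  cat(sprintf("  aerated: %9d vox  %8.2f mm3  (%.1f%%)\n",
              x$aerated_voxels, x$aerated_mm3, 100 * x$aerated_fraction))
  cat(sprintf("  tissue:  %9d vox  %8.2f mm3  (%.1f%%)\n",
              x$tissue_voxels, x$tissue_mm3, 100 * x$tissue_fraction))
  invisible(x)
}

#' @export
as.data.frame.volume_outcomes <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(segment = x$source_label, threshold_hu = x$threshold_hu,
             weighted_mean_hu = x$weighted_mean_hu,
             total_voxels = x$total_voxels,
             aerated_voxels = x$aerated_voxels,
             tissue_voxels = x$tissue_voxels,
             total_mm3 = x$total_mm3, aerated_mm3 = x$aerated_mm3,
             tissue_mm3 = x$tissue_mm3,
             aerated_fraction = x$aerated_fraction,
             tissue_fraction = x$tissue_fraction,
             stringsAsFactors = FALSE)
}

#' Computed tomography dose index
#'
#' Integrates a measured axial dose profile `D(z)` over \[-50, +50\] mm
#' and divides by `N * T` (slices times nominal section thickness):
#' trapezoid rule on the supplied samples.
#'
#' @param z_mm strictly increasing sample positions spanning
#'   \[-50, 50\] mm.
#' @param dose nonnegative dose at each position.
#' @param n_slices positive integer `N`.
#' @param section_thickness_mm positive `T` in mm.
#' @return CTDI in the dose units of `dose`.
#' @export
ctdi <- function(z_mm, dose, n_slices, section_thickness_mm) {
  if (length(z_mm) != length(dose) || length(z_mm) < 2L)
    stop("z_mm and dose must be equal-length vectors (>= 2 samples)")
  if (is.unsorted(z_mm, strictly = TRUE)) stop("z positions must be strictly increasing")
  if (any(!is.finite(dose)) || any(dose < 0)) stop("doses must be finite and >= 0")
  if (n_slices * section_thickness_mm <= 0) stop("N * T must be positive")
  if (min(z_mm) > -50 || max(z_mm) < 50)
    stop("dose profile must span [-50, +50] mm")
  keep <- z_mm >= -50 & z_mm <= 50
  # interpolate the end points so the integral covers exactly [-50, 50]
  z <- c(-50, z_mm[keep], 50)
  d <- c(stats::approx(z_mm, dose, xout = -50)$y, dose[keep],
         stats::approx(z_mm, dose, xout = 50)$y)
  dup <- duplicated(z)
  z <- z[!dup]; d <- d[!dup]
  integral <- sum(diff(z) * (head(d, -1) + d[-1]) / 2)
  integral / (n_slices * section_thickness_mm)
}

#' Weighted CTDI
#'
#' `CTDI_w = 1/3 * CTDI_center + 2/3 * CTDI_peripheral`.
#'
#' @param ctdi_center,ctdi_peripheral nonnegative CTDI values.
#' @return Weighted CTDI.
#' @export
ctdi_w <- function(ctdi_center, ctdi_peripheral) {
  if (ctdi_center < 0 || ctdi_peripheral < 0)
    stop("CTDI inputs must be >= 0")
  ctdi_center / 3 + 2 * ctdi_peripheral / 3
}

#' Read / write 1-HU-bin histogram CSVs
#'
#' Two-column CSV (`hu`, `count`); missing bins are treated as zero so a
#' sparse export round-trips. Counts for out-of-domain HU rows are
#' clamp-accumulated onto the -1000 / 1000 edge bins.
#'
#' @param path CSV path.
#' @param source_label,voxel_edge_um metadata attached on read.
#' @return [read_histogram_csv()]: an `intensity_histogram`;
#'   [write_histogram_csv()]: `path`, invisibly.
#' @export
read_histogram_csv <- function(path, source_label = "whole_lung",
                               voxel_edge_um = NA_real_) {
  df <- read.csv(path)
  names(df) <- tolower(names(df))
  if (!all(c("hu", "count") %in% names(df)))
    stop("histogram CSV must have columns 'hu' and 'count'")
  hu <- round(pmin(pmax(df$hu, -1000), 1000))
  counts <- numeric(2001)
  for (i in seq_along(hu)) {
    j <- as.integer(hu[i]) + 1001L
    counts[j] <- counts[j] + df$count[i]
  }
  new_intensity_histogram(counts, source_label, voxel_edge_um)
}

#' @rdname read_histogram_csv
#' @param hist an `intensity_histogram` to write.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "intensity_histogram"))
  write.csv(data.frame(hu = hist$bin_hu, count = hist$counts),
            path, row.names = FALSE)
  invisible(path)
}
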