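#' Recompute the reference cohort statistics from an exported workbook
#'
#' The published cohort ships as a supplementary spreadsheet of raw
#' density histograms and derived per-animal outcomes. After a one-time
#' export of that workbook to plain CSV, this function re-derives the
#' pooled control threshold and the five cross-modality Spearman
#' correlations from it. Expected layout under `dir`:
#'
#' * `wt_histograms/*.csv` — one two-column (`hu`, `count`) histogram
#'   per control (WT) animal (whole lung), for the threshold
#'   derivation;
#' * `ct_left.csv` — per-animal left-lung CT outcomes with columns
#'   `animal_id`, `total_voxels`, `air_voxels`, `tissue_voxels`;
#' * `histo.csv` — per-animal summed histology areas with columns
#'   `animal_id`, `blue_area`, `pink_area`, `white_area`, `total_area`.
#'
#' @param dir directory holding the exported CSVs.
#' @return List with `threshold_hu` (integer, pooled weighted mean of
#'   the WT histograms) and `correlations` (data frame from
#'   [correlate_ct_histology()]).
#' @export
reproduce_reference_statistics <- function(dir) {
  if (!dir.exists(dir)) stop("reference export directory not found: ", dir)
  hist_files <- list.files(file.path(dir, "wt_histograms"),
                           pattern = "\\.csv$", full.names = TRUE)
  threshold <- if (length(hist_files)) {
    derive_threshold(lapply(hist_files, read_histogram_csv))
  } else NA_integer_

  ct_path <- file.path(dir, "ct_left.csv")
  histo_path <- file.path(dir, "histo.csv")
  correlations <- NULL
  if (file.exists(ct_path) && file.exists(histo_path)) {
    ct <- read.csv(ct_path, stringsAsFactors = FALSE)
    hs <- read.csv(histo_path, stringsAsFactors = FALSE)
    ct$total_mm3 <- ct$total_voxels
    ct$aerated_mm3 <- ct$air_voxels
    ct$tissue_mm3 <- ct$tissue_voxels
    ct$aerated_fraction <- ct$air_voxels / ct$total_voxels
    ct$tissue_fraction <- ct$tissue_voxels / ct$total_voxels
    hs$tissue_um2 <- hs$blue_area + hs$pink_area
    hs$total_um2 <- hs$total_area
    hs$white_um2 <- hs$white_area
    hs$white_fraction <- hs$white_area / hs$total_area
    hs$tissue_fraction <- hs$tissue_um2 / hs$total_area
    correlations <- correlate_ct_histology(
      ct[, c("animal_id", "total_mm3", "aerated_mm3", "tissue_mm3",
             "aerated_fraction", "tissue_fraction")],
      hs[, c("animal_id", "total_um2", "tissue_um2", "white_um2",
             "white_fraction", "tissue_fraction")])
  }
  list(threshold_hu = threshold, correlations = correlations)
}
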