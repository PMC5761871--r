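#' Build a pipeline run configuration
#'
#' A validated bag of paths and parameters for [run_pipeline()].
#' Precedence is caller arguments > values loaded from a JSON file >
#' package defaults: load a file with [read_run_config()] and override
#' fields by passing them here.
#'
#' @param out_dir output directory (created if missing).
#' @param ct optional list of CT inputs, one per animal: each a list
#'   with `animal_id`, `path` (HU NIfTI), `seed` (bronchus voxel
#'   `(z, y, x)`), optional `split_col`.
#' @param histo optional list of histology inputs, one per section:
#'   each a list with `animal_id`, `level_index`, `image` (PNG/TIFF),
#'   optional `roi` (PNG mask path), optional `reclass` (PNG mask of
#'   empty-vessel regions, applied White -> Pink).
#' @param training path to the training-pixel CSV (category,R,G,B);
#'   required when `histo` inputs are given.
#' @param hu_low,hu_high,grow_r,shrink_r,fill_holes,smooth_r,airway_cutoff_um,air_hu_max
#'   segmentation parameters (see [quantify_ct()]).
#' @param threshold `"auto"` (derive from the WT animals' pooled
#'   whole-lung histograms) or an integer HU (default -256).
#' @param wt_ids character vector of control animal ids, needed for
#'   `threshold = "auto"`.
#' @param pixel_area_um2 slide pixel area.
#' @param min_total_area_um2 histology inclusion floor.
#' @param correlate compute CT-histology Spearman correlations (left
#'   lung) when both modalities are present.
#' @param rng_seed seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, ct = NULL, histo = NULL, training = NULL,
                       hu_low = -1000, hu_high = -150, grow_r = 1,
                       shrink_r = 1, fill_holes = TRUE, smooth_r = 1,
                       airway_cutoff_um = 200, air_hu_max = -400,
                       threshold = -256, wt_ids = character(),
                       pixel_area_um2 = 1, min_total_area_um2 = 15e6,
                       correlate = TRUE, rng_seed = 1) {
  cfg <- as.list(environment())
  for (entry in cfg$ct) {
    if (is.null(entry$animal_id) || is.null(entry$path) || is.null(entry$seed))
      stop("each ct entry needs animal_id, path and seed")
    if (!file.exists(entry$path)) stop("missing CT file: ", entry$path)
  }
  for (entry in cfg$histo) {
    if (is.null(entry$animal_id) || is.null(entry$image))
      stop("each histo entry needs animal_id and image")
    if (!file.exists(entry$image)) stop("missing slide image: ", entry$image)
  }
  if (length(cfg$histo) && is.null(cfg$training))
    stop("histology inputs require a training CSV")
  if (identical(cfg$threshold, "auto") && length(cfg$wt_ids) == 0)
    stop("threshold = 'auto' requires wt_ids")
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields mirror the [run_config()]
#'   arguments.
#' @param ... overrides applied on top of the file (CLI > file >
#'   defaults).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  over <- list(...)
  for (nm in names(over)) raw[[nm]] <- over[[nm]]
  do.call(run_config, raw)
}

log_stage <- function(stage, msg) {
  message(sprintf("[lungquant:%s] %s", stage, msg))
}

read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' Run the configured CT / histology / correlation pipeline
#'
#' Executes segment -> quantify-ct and/or quantify-histo -> correlate
#' as configured, writing per-animal outcome CSVs, per-lung histogram
#' CSVs, label-map PNGs, mask NIfTIs, a stats JSON and a provenance
#' record. Any stage error aborts with the stage name. Reruns with an
#' identical configuration produce identical CSV/JSON outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the outcome tables and the paths of
#'   everything written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  ct_table <- NULL
  histo_sections <- NULL
  histo_animals <- NULL
  correlations <- NULL

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (length(config$ct)) {
    runs <- stage("segment", {
      lapply(config$ct, function(entry) {
        log_stage("segment", paste("animal", entry$animal_id))
        vol <- read_ct(entry$path)
        res <- quantify_ct(vol, seed = unlist(entry$seed),
                           hu_low = config$hu_low, hu_high = config$hu_high,
                           grow_r = config$grow_r, shrink_r = config$shrink_r,
                           fill_holes = config$fill_holes,
                           smooth_r = config$smooth_r,
                           airway_cutoff_um = config$airway_cutoff_um,
                           air_hu_max = config$air_hu_max,
                           split_col = entry$split_col)
        res$volume <- vol
        res$animal_id <- entry$animal_id
        res
      })
    })
    threshold <- stage("quantify-ct", {
      if (identical(config$threshold, "auto")) {
        wt <- Filter(function(r) r$animal_id %in% config$wt_ids, runs)
        if (!length(wt)) stop("no WT animals found for auto threshold")
        derive_threshold(lapply(wt, function(r) r$histograms$whole))
      } else as.integer(config$threshold)
    })
    ct_table <- stage("quantify-ct", {
      do.call(rbind, lapply(runs, function(r) {
        rows <- lapply(names(r$histograms), function(seg) {
          oc <- partition_volumes(r$histograms[[seg]], threshold,
                                  r$volume$voxel_edge_um)
          cbind(data.frame(animal_id = r$animal_id), as.data.frame(oc))
        })
        do.call(rbind, rows)
      }))
    })
    stage("quantify-ct", {
      for (r in runs) {
        base <- file.path(config$out_dir, r$animal_id)
        write_ct_nifti(r$lung, paste0(base, "_lung_mask.nii.gz"),
                       voxel_edge_um = r$volume$voxel_edge_um)
        for (seg in names(r$histograms))
          write_histogram_csv(r$histograms[[seg]],
                              paste0(base, "_hist_", seg, ".csv"))
      }
      paths$ct_outcomes <- file.path(config$out_dir, "ct_outcomes.csv")
      write.csv(ct_table, paths$ct_outcomes, row.names = FALSE)
    })
  }

  if (length(config$histo)) {
    clf <- stage("quantify-histo",
                 train_classifier(read_training_csv(config$training)))
    histo_sections <- stage("quantify-histo", {
      do.call(rbind, lapply(config$histo, function(entry) {
        log_stage("quantify-histo",
                  paste("animal", entry$animal_id, "level",
                        entry$level_index %||% NA))
        slide <- read_slide(entry$image,
                            pixel_area_um2 = config$pixel_area_um2,
                            animal_id = entry$animal_id)
        roi <- if (!is.null(entry$roi)) read_mask_png(entry$roi) else NULL
        labels <- classify_slide(slide, roi, clf)
        if (!is.null(entry$reclass))
          labels <- reclassify_regions(labels, read_mask_png(entry$reclass),
                                       "White", "Pink")
        base <- file.path(config$out_dir,
                          paste0(entry$animal_id, "_L",
                                 entry$level_index %||% 1L))
        write_slide_png(unclass(labels), paste0(base, "_labels.png"))
        oc <- quantify_areas(labels,
                             min_total_area_um2 = config$min_total_area_um2,
                             animal_id = entry$animal_id,
                             level_index = entry$level_index %||% 1L)
        as.data.frame(oc)
      }))
    })
    histo_animals <- stage("quantify-histo", {
      do.call(rbind, lapply(split(seq_len(nrow(histo_sections)),
                                  histo_sections$animal_id), function(ix) {
        rows <- histo_sections[ix, ]
        ocs <- lapply(seq_len(nrow(rows)), function(i) {
          o <- as.list(rows[i, ])
          o$min_total_area_um2 <- config$min_total_area_um2
          class(o) <- "histo_area_outcomes"
          o
        })
        as.data.frame(aggregate_animal(ocs))
      }))
    })
    paths$histo_sections <- file.path(config$out_dir, "histo_sections.csv")
    paths$histo_animals <- file.path(config$out_dir, "histo_animals.csv")
    write.csv(histo_sections, paths$histo_sections, row.names = FALSE)
    write.csv(histo_animals, paths$histo_animals, row.names = FALSE)
  }

  if (isTRUE(config$correlate) && !is.null(ct_table) &&
      !is.null(histo_animals)) {
    correlations <- stage("correlate", {
      left <- ct_table[ct_table$segment == "left_lung", ]
      correlate_ct_histology(left, histo_animals)
    })
    paths$correlations <- file.path(config$out_dir, "correlations.csv")
    write.csv(correlations, paths$correlations, row.names = FALSE)
  }

  prov <- list(
    package = "lungquant",
    version = as.character(utils::packageVersion("lungquant")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    rng_seed = config$rng_seed,
    config = config[setdiff(names(config), "out_dir")],
    outputs = lapply(paths, basename)
  )
  paths$provenance <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)

  stats_path <- file.path(config$out_dir, "stats.json")
  jsonlite::write_json(
    list(correlations = correlations,
         n_ct_animals = length(config$ct),
         n_histo_sections = length(config$histo)),
    stats_path, auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  paths$stats <- stats_path

  invisible(list(ct = ct_table, histo_sections = histo_sections,
                 histo_animals = histo_animals,
                 correlations = correlations, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
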