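HE_CATEGORIES <- c("Blue", "Pink", "White")

#' H&E RGB slide
#'
#' A stained section stored as an `h x w x 3` array of integer RGB values
#' in \[0, 255\] plus the physical pixel area.
#'
#' @param pixels `h x w x 3` numeric array, channels R, G, B in
#'   \[0, 255\].
#' @param pixel_area_um2 positive pixel area in square micrometres.
#' @param animal_id,section_id,level_index identifiers (three sections
#'   at least 200 um apart are the usual design; `level_index` records
#'   which).
#' @return An object of class `rgb_slide`.
#' @export
rgb_slide <- function(pixels, pixel_area_um2 = 1, animal_id = NA_character_,
                      section_id = NA_character_, level_index = NA_integer_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an h x w x 3 array")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  if (pixel_area_um2 <= 0) stop("pixel_area_um2 must be positive")
  structure(list(pixels = pixels, pixel_area_um2 = pixel_area_um2,
                 animal_id = animal_id, section_id = section_id,
                 level_index = level_index),
            class = "rgb_slide")
}

#' @export
dim.rgb_slide <- function(x) dim(x$pixels)[1:2]

#' @export
print.rgb_slide <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_slide> %d x %d px @ %.3g um2/px", d[1], d[2],
              x$pixel_area_um2))
  if (!is.na(x$animal_id)) cat(sprintf("  animal %s", x$animal_id))
  if (!is.na(x$level_index)) cat(sprintf("  level %d", x$level_index))
  cat("\n")
  invisible(x)
}

#' Read an RGB slide image from PNG or TIFF
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @param pixel_area_um2 physical pixel area.
#' @param ... passed to [rgb_slide()].
#' @return An [rgb_slide()].
#' @export
read_slide <- function(path, pixel_area_um2 = 1, ...) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  rgb_slide(round(img * 255), pixel_area_um2 = pixel_area_um2, ...)
}

#' Write an RGB slide or label map to PNG
#'
#' Label maps are written as an indexed-style grayscale PNG with values
#' 0 (unlabelled), 1 (Blue), 2 (Pink), 3 (White) scaled into the 8-bit
#' range (value = label * 85).
#'
#' @param x an [rgb_slide()] or an integer label matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_slide_png <- function(x, path) {
  if (inherits(x, "rgb_slide")) {
    png::writePNG(x$pixels / 255, path)
  } else {
    png::writePNG(x / 3, path)
  }
  invisible(path)
}

#' Rasterize a polygon ROI into a mask
#'
#' Vertices are in image coordinates (column = x, row = y, y increasing
#' downward, 1-based); a pixel is inside if its centre is inside the
#' polygon (even-odd rule).
#'
#' @param vertices two-column matrix (x, y) of polygon vertices.
#' @param dim_hw image dimensions `c(height, width)`.
#' @return Logical matrix ROI mask.
#' @export
roi_from_polygon <- function(vertices, dim_hw) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2L, nrow(vertices) >= 3L)
  h <- dim_hw[1]; w <- dim_hw[2]
  px <- vertices[, 1]; py <- vertices[, 2]
  n <- nrow(vertices)
  mask <- matrix(FALSE, h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  inside <- matrix(FALSE, h, w)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > ys) != (py[j] > ys)) &
      (xs < (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Training pixels for the H&E classifier
#'
#' @param category character vector of categories (`"Blue"`, `"Pink"`,
#'   `"White"`), one per training pixel.
#' @param rgb numeric matrix with columns R, G, B in \[0, 255\].
#' @return A `data.frame` with columns `category`, `R`, `G`, `B`.
#' @export
training_set <- function(category, rgb) {
  rgb <- as.matrix(rgb)
  stopifnot(ncol(rgb) == 3L, length(category) == nrow(rgb))
  if (!all(category %in% HE_CATEGORIES))
    stop("categories must be Blue, Pink or White")
  data.frame(category = as.character(category),
             R = rgb[, 1], G = rgb[, 2], B = rgb[, 3],
             stringsAsFactors = FALSE)
}

#' Read training pixels from CSV
#'
#' Expects columns `category, R, G, B`.
#'
#' @param path CSV path.
#' @return A training `data.frame` (see [training_set()]).
#' @export
read_training_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df)[tolower(names(df)) == "category"] <- "category"
  need <- c("category", "R", "G", "B")
  if (!all(need %in% names(df)))
    stop("training CSV must have columns category, R, G, B")
  training_set(df$category, as.matrix(df[, c("R", "G", "B")]))
}

#' Train the Bayesian RGB pixel classifier
#'
#' Fits one Gaussian per category (Blue, Pink, White) in RGB space —
#' mean vector and 3x3 covariance with a small ridge `eps` on the
#' diagonal — from manually selected training pixels (at least 15 per
#' category). A pixel is assigned to the category with the largest
#' posterior density (prior x Gaussian likelihood); exact ties break by
#' the fixed order Blue > Pink > White. `mode = "box"` instead stores
#' per-channel min/max ranges per category and assigns pixels to the
#' unique covering box, falling back to the nearest category mean when
#' zero or several boxes cover a pixel.
#'
#' @param training a training `data.frame` (see [training_set()]).
#' @param priors optional named per-category priors; normalized to sum
#'   to 1. Default equal.
#' @param regularization_eps ridge added to each covariance diagonal (on
#'   the 0-255 intensity scale).
#' @param mode `"gaussian"` (default) or `"box"`.
#' @return An object of class `pixel_classifier`.
#' @export
train_classifier <- function(training, priors = NULL,
                             regularization_eps = 1e-3,
                             mode = c("gaussian", "box")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(training),
            all(c("category", "R", "G", "B") %in% names(training)))
  n_per <- table(factor(training$category, levels = HE_CATEGORIES))
  short <- names(n_per)[n_per < 15]
  if (length(short))
    stop("training error: fewer than 15 pixels for category ",
         paste(short, collapse = ", "))
  if (any(n_per == 15))
    warning("exactly 15 training pixels for ",
            paste(names(n_per)[n_per == 15], collapse = ", "),
            "; more are recommended")
  if (is.null(priors)) {
    priors <- setNames(rep(1 / 3, 3), HE_CATEGORIES)
  } else {
    if (is.null(names(priors)) || !all(HE_CATEGORIES %in% names(priors)))
      stop("priors must be named Blue/Pink/White")
    priors <- priors[HE_CATEGORIES] / sum(priors[HE_CATEGORIES])
  }
  fits <- lapply(HE_CATEGORIES, function(cat) {
    x <- as.matrix(training[training$category == cat, c("R", "G", "B")])
    mu <- colMeans(x)
    sigma <- stats::cov(x) + diag(regularization_eps, 3)
    # identical Blue/Pink training sets are legal but degenerate
    list(mean = mu, cov = sigma, inv = solve(sigma),
         logdet = determinant(sigma, logarithm = TRUE)$modulus[1],
         range = apply(x, 2, range), n = nrow(x))
  })
  names(fits) <- HE_CATEGORIES
  for (a in 1:2) for (b in (a + 1):3) {
    if (max(abs(fits[[a]]$mean - fits[[b]]$mean)) < 1e-9 &&
        max(abs(fits[[a]]$cov - fits[[b]]$cov)) < 1e-9)
      warning("categories ", HE_CATEGORIES[a], " and ", HE_CATEGORIES[b],
              " have indistinguishable training data; ties break by the ",
              "fixed order Blue > Pink > White")
  }
  structure(list(fits = fits, priors = priors,
                 regularization_eps = regularization_eps, mode = mode),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> mode = %s, eps = %g\n",
              x$mode, x$regularization_eps))
  for (cat_ in HE_CATEGORIES) {
    f <- x$fits[[cat_]]
    cat(sprintf("  %-5s n = %3d  mean RGB = (%5.1f, %5.1f, %5.1f)  prior = %.3f\n",
                cat_, f$n, f$mean[1], f$mean[2], f$mean[3],
                x$priors[[cat_]]))
  }
  invisible(x)
}

classifier_scores <- function(clf, rgbm) {
  # rgbm: n x 3 matrix; returns n x 3 matrix of log posterior scores
  sc <- matrix(NA_real_, nrow(rgbm), 3, dimnames = list(NULL, HE_CATEGORIES))
  for (cat_ in HE_CATEGORIES) {
    f <- clf$fits[[cat_]]
    d <- sweep(rgbm, 2, f$mean)
    maha <- rowSums((d %*% f$inv) * d)
    sc[, cat_] <- log(clf$priors[[cat_]]) - 0.5 * f$logdet - 0.5 * maha
  }
  sc
}

classify_rgb <- function(clf, rgbm) {
  rgbm <- as.matrix(rgbm)
  if (clf$mode == "gaussian") {
    sc <- classifier_scores(clf, rgbm)
    # first max in Blue > Pink > White order wins ties
    max.col(sc, ties.method = "first")
  } else {
    inbox <- sapply(HE_CATEGORIES, function(cat_) {
      r <- clf$fits[[cat_]]$range
      rgbm[, 1] >= r[1, 1] & rgbm[, 1] <= r[2, 1] &
      rgbm[, 2] >= r[1, 2] & rgbm[, 2] <= r[2, 2] &
      rgbm[, 3] >= r[1, 3] & rgbm[, 3] <= r[2, 3]
    })
    inbox <- matrix(inbox, ncol = 3)
    hits <- rowSums(inbox)
    lab <- max.col(inbox, ties.method = "first")
    amb <- hits != 1L
    if (any(amb)) {
      d2 <- sapply(HE_CATEGORIES, function(cat_) {
        mu <- clf$fits[[cat_]]$mean
        rowSums(sweep(rgbm[amb, , drop = FALSE], 2, mu)^2)
      })
      d2 <- matrix(d2, ncol = 3)
      lab[amb] <- max.col(-d2, ties.method = "first")
    }
    lab
  }
}

#' Classify every ROI pixel of a slide
#'
#' @param slide an [rgb_slide()].
#' @param roi logical matrix congruent with the slide (the lung margin
#'   outline); must select at least one pixel.
#' @param clf a [train_classifier()] fit.
#' @return An integer label matrix of class `he_label_map`: 0 outside
#'   the ROI, 1 = Blue, 2 = Pink, 3 = White inside.
#' @export
classify_slide <- function(slide, roi, clf) {
  stopifnot(inherits(slide, "rgb_slide"), inherits(clf, "pixel_classifier"))
  if (is.null(roi)) roi <- matrix(TRUE, dim(slide)[1], dim(slide)[2])
  if (!identical(dim(roi), dim(slide)))
    stop("ROI is not congruent with the slide")
  if (!any(roi)) stop("empty ROI")
  idx <- which(roi)
  h <- dim(slide)[1]; w <- dim(slide)[2]
  px <- slide$pixels
  rgbm <- cbind(px[, , 1][idx], px[, , 2][idx], px[, , 3][idx])
  lab <- matrix(0L, h, w)
  lab[idx] <- classify_rgb(clf, rgbm)
  structure(lab, class = c("he_label_map", "matrix", "array"),
            pixel_area_um2 = slide$pixel_area_um2)
}

#' Reclassify labelled pixels inside given regions
#'
#' The manual vessel correction: pixels of `from_cat` lying inside
#' `regions` (e.g. empty artery lumens) are relabelled `to_cat`; nothing
#' else changes. The number of changed pixels is attached as attribute
#' `"n_changed"`.
#'
#' @param labels an `he_label_map` from [classify_slide()].
#' @param regions logical matrix of region pixels (within the ROI).
#' @param from_cat,to_cat category names.
#' @return The updated label map.
#' @export
reclassify_regions <- function(labels, regions, from_cat = "White",
                               to_cat = "Pink") {
  stopifnot(inherits(labels, "he_label_map"))
  from_i <- match(match.arg(from_cat, HE_CATEGORIES), HE_CATEGORIES)
  to_i <- match(match.arg(to_cat, HE_CATEGORIES), HE_CATEGORIES)
  if (is.null(regions)) regions <- matrix(FALSE, nrow(labels), ncol(labels))
  if (!identical(dim(regions), dim(labels)))
    stop("regions mask is not congruent with the label map")
  hit <- regions & (unclass(labels) == from_i)
  labels[hit] <- to_i
  attr(labels, "n_changed") <- sum(hit)
  labels
}

#' Quantify category areas from a label map
#'
#' Per-category area = pixel count x pixel area; tissue = Blue + Pink.
#' Slides whose total labelled area falls below `min_total_area_um2` are
#' flagged `excluded` (never silently dropped). The default inclusion
#' floor is 15 mm2 of lung; `min_total_area_um2 = 15` selects the
#' literal 15 um2 floor instead.
#'
#' @param labels an `he_label_map`.
#' @param pixel_area_um2 pixel area; defaults to the value carried by
#'   the label map.
#' @param min_total_area_um2 inclusion floor on total labelled area.
#' @param animal_id,level_index identifiers carried into the result.
#' @return An object of class `histo_area_outcomes`.
#' @export
quantify_areas <- function(labels,
                           pixel_area_um2 = attr(labels, "pixel_area_um2"),
                           min_total_area_um2 = 15e6,
                           animal_id = NA_character_,
                           level_index = NA_integer_) {
  stopifnot(inherits(labels, "he_label_map"))
  if (is.null(pixel_area_um2) || is.na(pixel_area_um2))
    stop("pixel_area_um2 required")
  m <- unclass(labels)
  counts <- c(Blue = sum(m == 1L), Pink = sum(m == 2L), White = sum(m == 3L))
  areas <- counts * pixel_area_um2
  total <- sum(areas)
  fr <- if (total > 0) areas / total else rep(NA_real_, 3)
  structure(list(
    animal_id = animal_id, level_index = level_index,
    blue_um2 = unname(areas["Blue"]), pink_um2 = unname(areas["Pink"]),
    white_um2 = unname(areas["White"]), total_um2 = total,
    tissue_um2 = unname(areas["Blue"] + areas["Pink"]),
    blue_fraction = unname(fr[1]), pink_fraction = unname(fr[2]),
    white_fraction = unname(fr[3]),
    tissue_fraction = unname(fr[1] + fr[2]),
    excluded = total < min_total_area_um2,
    min_total_area_um2 = min_total_area_um2
  ), class = "histo_area_outcomes")
}

#' @export
print.histo_area_outcomes <- function(x, ...) {
  cat("<histo_area_outcomes>")
  if (!is.na(x$animal_id)) cat(sprintf(" animal %s", x$animal_id))
  if (!is.na(x$level_index)) cat(sprintf(" level %d", x$level_index))
  if (isTRUE(x$excluded)) cat("  [EXCLUDED: below minimum lung area]")
  cat("\n")
  cat(sprintf("  Blue  %12.1f um2  (%.1f%%)\n", x$blue_um2, 100 * x$blue_fraction))
  cat(sprintf("  Pink  %12.1f um2  (%.1f%%)\n", x$pink_um2, 100 * x$pink_fraction))
  cat(sprintf("  White %12.1f um2  (%.1f%%)\n", x$white_um2, 100 * x$white_fraction))
  cat(sprintf("  tissue (Blue+Pink) %12.1f um2  (%.1f%%)\n",
              x$tissue_um2, 100 * x$tissue_fraction))
  invisible(x)
}

#' @export
as.data.frame.histo_area_outcomes <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  data.frame(animal_id = x$animal_id, level_index = x$level_index,
             blue_um2 = x$blue_um2, pink_um2 = x$pink_um2,
             white_um2 = x$white_um2, total_um2 = x$total_um2,
             tissue_um2 = x$tissue_um2, blue_fraction = x$blue_fraction,
             pink_fraction = x$pink_fraction,
             white_fraction = x$white_fraction,
             tissue_fraction = x$tissue_fraction, excluded = x$excluded,
             stringsAsFactors = FALSE)
}

#' Aggregate per-section outcomes into one per-animal summary
#'
#' Absolute areas are the unweighted mean of the included sections;
#' fractions are recomputed from the summed areas (not averaged
#' fractions). Both views are consistent because the fractions of the
#' summed areas equal the fractions of the mean areas.
#'
#' @param outcomes list of `histo_area_outcomes` for one animal.
#' @param drop_excluded drop sections flagged below the area floor.
#' @return A `histo_area_outcomes` for the animal (`level_index = NA`).
#' @export
aggregate_animal <- function(outcomes, drop_excluded = TRUE) {
  if (inherits(outcomes, "histo_area_outcomes")) outcomes <- list(outcomes)
  stopifnot(length(outcomes) >= 1L)
  if (drop_excluded) outcomes <- Filter(function(o) !isTRUE(o$excluded), outcomes)
  if (length(outcomes) == 0L)
    stop("all sections for this animal are excluded (below the area floor)")
  sums <- sapply(c("blue_um2", "pink_um2", "white_um2"), function(f)
    sum(vapply(outcomes, `[[`, numeric(1), f)))
  k <- length(outcomes)
  total_sum <- sum(sums)
  fr <- if (total_sum > 0) sums / total_sum else rep(NA_real_, 3)
  structure(list(
    animal_id = outcomes[[1]]$animal_id, level_index = NA_integer_,
    n_sections = k,
    blue_um2 = unname(sums[1]) / k, pink_um2 = unname(sums[2]) / k,
    white_um2 = unname(sums[3]) / k, total_um2 = total_sum / k,
    tissue_um2 = unname(sums[1] + sums[2]) / k,
    blue_fraction = unname(fr[1]), pink_fraction = unname(fr[2]),
    white_fraction = unname(fr[3]),
    tissue_fraction = unname(fr[1] + fr[2]),
    excluded = FALSE,
    min_total_area_um2 = outcomes[[1]]$min_total_area_um2
  ), class = "histo_area_outcomes")
}
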