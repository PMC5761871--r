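#' Evaluate code with a temporary RNG seed
#'
#' Used by all generators so the same spec + seed reproduces the same
#' phantom bit-for-bit without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' CT phantom specification
#'
#' Parameters of the synthetic chest volume: a soft-tissue body, two
#' ellipsoidal lungs filled with an air / alveolar-interface voxel
#' mixture and rimmed by a one-voxel interface shell (the pleural
#' partial-volume layer), a branching conducting airway (one trunk, one
#' bifurcation) with a soft-tissue wall and open distal tips, and
#' ellipsoidal inflammatory lesions merged until a target fraction of
#' the parenchyma is covered. HU class means straddle the -256 HU
#' air/epithelium interface value so threshold derivation and the
#' aerated/tissue partition are both exercised.
#'
#' @param grid_dim volume dimensions `c(z, y, x)`.
#' @param voxel_edge_um isotropic voxel edge (default 35 um).
#' @param body_hu_mean,body_hu_sd soft-tissue background HU.
#' @param lung_air_hu_mean,lung_air_hu_sd alveolar air HU.
#' @param alveolar_wall_fraction fraction of interior lung voxels drawn
#'   as alveolar interface rather than air.
#' @param wall_hu_mean,wall_hu_sd alveolar interface HU (centered on the
#'   -256 HU interface density).
#' @param lesion_fraction target fraction of parenchyma covered by
#'   lesions, in \[0, 1).
#' @param lesion_hu_mean,lesion_hu_sd inflammatory infiltrate HU (also
#'   used for the conducting-airway wall tissue).
#' @param airway_diameter_um lumen diameter of the conducting airway.
#' @param noise_scale multiplier on all HU standard deviations (0 gives
#'   a noise-free phantom).
#' @return An object of class `ct_phantom_spec`.
#' @export
ct_phantom_spec <- function(grid_dim = c(72, 60, 72),
                            voxel_edge_um = 35,
                            body_hu_mean = 40, body_hu_sd = 25,
                            lung_air_hu_mean = -850, lung_air_hu_sd = 60,
                            alveolar_wall_fraction = 0.25,
                            wall_hu_mean = -256, wall_hu_sd = 60,
                            lesion_fraction = 0,
                            lesion_hu_mean = -50, lesion_hu_sd = 40,
                            airway_diameter_um = 300,
                            noise_scale = 1) {
  if (lesion_fraction < 0 || lesion_fraction >= 1)
    stop("lesion_fraction must lie in [0, 1)")
  if (alveolar_wall_fraction < 0 || alveolar_wall_fraction > 1)
    stop("alveolar_wall_fraction must lie in [0, 1]")
  means <- c(body_hu_mean, lung_air_hu_mean, wall_hu_mean, lesion_hu_mean)
  if (any(means < -1000 | means > 1000))
    stop("HU class means must lie within [-1000, 1000]")
  structure(as.list(environment()), class = "ct_phantom_spec")
}

# squared normalized distance to an ellipsoid centre; <= 1 is inside
ellipsoid_mask <- function(d, centre, semi) {
  z <- (seq_len(d[1]) - centre[1]) / semi[1]
  y <- (seq_len(d[2]) - centre[2]) / semi[2]
  x <- (seq_len(d[3]) - centre[3]) / semi[3]
  q <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  q <= 1
}

# voxels within `radius` of the segment p0 -> p1 (voxel coordinates)
cylinder_mask <- function(d, p0, p1, radius) {
  z <- rep(seq_len(d[1]), times = d[2] * d[3])
  y <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  x <- rep(seq_len(d[3]), each = d[1] * d[2])
  v <- p1 - p0
  len2 <- sum(v^2)
  t <- ((z - p0[1]) * v[1] + (y - p0[2]) * v[2] + (x - p0[3]) * v[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  dz <- z - (p0[1] + t * v[1])
  dy <- y - (p0[2] + t * v[2])
  dx <- x - (p0[3] + t * v[3])
  array(dz^2 + dy^2 + dx^2 <= radius^2, dim = d)
}

sphere_mask <- function(d, centre, radius) {
  z <- (seq_len(d[1]) - centre[1])
  y <- (seq_len(d[2]) - centre[2])
  x <- (seq_len(d[3]) - centre[3])
  q <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  q <= radius^2
}

#' Generate a synthetic chest CT volume with ground truth
#'
#' Deterministic given `rng_seed`. Returns the HU volume together with
#' the truth the generator used to build it: parenchyma / airway /
#' lesion / left / right masks, a voxel class map, and the bookkeeping
#' volumes and fractions (including the lesion-plus-wall tissue
#' fraction and the fraction of parenchyma voxels at or above -256 HU).
#'
#' @param spec a [ct_phantom_spec()].
#' @param rng_seed integer seed.
#' @return List with `volume` (a [ct_volume()]) and `truth`.
#' @export
generate_ct_phantom <- function(spec = ct_phantom_spec(), rng_seed = 1) {
  stopifnot(inherits(spec, "ct_phantom_spec"))
  with_seed(rng_seed, {
    d <- spec$grid_dim
    ns <- spec$noise_scale
    n <- prod(d)

    # anatomy layout scales with the grid; the midline gap stays wide
    # enough (~0.11 * nx) that radius-1 smoothing cannot fuse the lungs
    zc <- 0.56 * d[1]; yc <- 0.5 * d[2]
    xl <- 0.28 * d[3]; xr <- 0.72 * d[3]; xm <- 0.5 * d[3]
    semi <- c(0.33 * d[1], 0.27 * d[2], 0.165 * d[3])
    left_env <- ellipsoid_mask(d, c(zc, yc, xl), semi)
    right_env <- ellipsoid_mask(d, c(zc, yc, xr), semi)
    envelope <- left_env | right_env

    r_lumen <- spec$airway_diameter_um / (2 * spec$voxel_edge_um)
    wall_th <- 2
    carina <- c(0.39 * d[1], yc, xm)
    top <- c(max(3, 0.06 * d[1]), yc, xm)
    tipL <- c(zc, yc, xl)
    tipR <- c(zc, yc, xr)
    lumen <- cylinder_mask(d, top, carina, r_lumen) |
      cylinder_mask(d, carina, tipL, r_lumen) |
      cylinder_mask(d, carina, tipR, r_lumen)
    awall <- (cylinder_mask(d, top, carina, r_lumen + wall_th) |
              cylinder_mask(d, carina, tipL, r_lumen + wall_th) |
              cylinder_mask(d, carina, tipR, r_lumen + wall_th)) & !lumen
    # open the distal tips so the lumen communicates with the alveoli
    open_r <- r_lumen + wall_th + 1
    awall <- awall & !sphere_mask(d, tipL, open_r) & !sphere_mask(d, tipR, open_r)

    shell <- envelope & !erode6(envelope, 1)
    interior <- envelope & !shell & !lumen & !awall

    # class map: 0 body, 1 air, 2 interface/wall, 3 lesion,
    #            4 airway lumen, 5 airway wall
    cls <- array(0L, dim = d)
    cls[interior] <- ifelse(runif(sum(interior)) < spec$alveolar_wall_fraction,
                            2L, 1L)
    cls[shell] <- 2L

    # lesions: ellipsoids rejection-sampled inside the eroded envelope
    lesion <- array(FALSE, dim = d)
    parenchyma_n <- sum(envelope & !lumen & !awall)
    target <- spec$lesion_fraction * parenchyma_n
    if (target > 0) {
      # keep lesions clear of the pleural shell and the airway wall so
      # every lesion is a closed cavity inside aerated parenchyma
      allowed <- erode6(envelope, 3) & !dilate6(lumen | awall, 2)
      allowed_idx <- which(allowed)
      it <- 0L
      while (sum(lesion) < target && it < 2000L) {
        it <- it + 1L
        c0 <- arrayInd(sample(allowed_idx, 1L), d)
        ax <- runif(3, 2.5, 6)
        lesion <- lesion | (ellipsoid_mask(d, as.numeric(c0), ax) & allowed)
      }
      if (sum(lesion) < target)
        warning("lesion placement stopped short of the target fraction")
      cls[lesion] <- 3L
    }
    cls[awall & envelope] <- 5L
    cls[awall & !envelope] <- 5L
    cls[lumen] <- 4L

    hu <- array(0, dim = d)
    draw <- function(m, mu, sd) {
      k <- sum(m)
      if (k > 0) hu[m] <<- mu + ns * sd * rnorm(k)
    }
    draw(cls == 0L, spec$body_hu_mean, spec$body_hu_sd)
    draw(cls == 1L, spec$lung_air_hu_mean, spec$lung_air_hu_sd)
    draw(cls == 2L, spec$wall_hu_mean, spec$wall_hu_sd)
    draw(cls == 3L, spec$lesion_hu_mean, spec$lesion_hu_sd)
    draw(cls == 4L, spec$lung_air_hu_mean, spec$lung_air_hu_sd)
    draw(cls == 5L, spec$lesion_hu_mean, spec$lesion_hu_sd)
    # scanners clamp at the density of air; mirror that floor (and the
    # matching ceiling) so no draw escapes the physical HU range
    hu <- pmin(pmax(hu, -1000), 1000)

    vol <- ct_volume(hu, voxel_edge_um = spec$voxel_edge_um)

    lung_truth <- (envelope | (awall & envelope)) & !lumen
    par_mask <- lung_truth
    par_idx <- which(par_mask)
    tissue_classes <- cls[par_idx] %in% c(2L, 3L, 5L)
    seed_vox <- round(c(top[1] + 2, yc, xm))

    truth <- list(
      lung = par_mask,
      left_lung = left_env & par_mask,
      right_lung = right_env & par_mask,
      airway = lumen,
      lesion = lesion,
      class_map = cls,
      trachea_seed = seed_vox,
      carina_col = xm,
      lung_voxels = length(par_idx),
      lung_mm3 = voxels_to_mm3(length(par_idx), spec$voxel_edge_um),
      airway_voxels = sum(lumen),
      lesion_voxels = sum(lesion),
      wall_fraction = mean(cls[par_idx] == 2L),
      lesion_fraction = mean(cls[par_idx] == 3L),
      tissue_fraction = mean(tissue_classes),
      tissue_fraction_hu = mean(hu[par_idx] >= -256),
      spec = spec, rng_seed = rng_seed
    )
    list(volume = vol, truth = truth)
  })
}

#' Run the full CT quantification pipeline on a volume
#'
#' Seeded region growing in the HU window, morphological refinement,
#' airway extraction and >cutoff exclusion, left/right split, histogram
#' densitometry. This is the programmatic equivalent of the `segment` +
#' `quantify-ct` command pair.
#'
#' @param volume a [ct_volume()].
#' @param seed bronchus seed `(z, y, x)`.
#' @param hu_low,hu_high region-growing HU window.
#' @param grow_r,shrink_r,fill_holes,smooth_r refinement parameters
#'   (see [refine_mask()]).
#' @param airway_cutoff_um airway exclusion diameter cutoff.
#' @param air_hu_max HU ceiling for the airway lumen.
#' @param threshold_hu aerated/tissue threshold; `NULL` to return
#'   histograms only (threshold can be derived cohort-wise later).
#' @param split_col optional fallback sagittal split column.
#' @return List with masks (`lung`, `left`, `right`), `airways`,
#'   histograms (`whole`, `left`, `right`) and, when a threshold is
#'   given, `outcomes` (named list of [partition_volumes()] results).
#' @export
quantify_ct <- function(volume, seed, hu_low = -1000, hu_high = -150,
                        grow_r = 1, shrink_r = 1, fill_holes = TRUE,
                        smooth_r = 1, airway_cutoff_um = 200,
                        air_hu_max = -400, threshold_hu = NULL,
                        split_col = NULL) {
  grown <- seeded_region_grow(volume, seed, hu_low, hu_high)
  refined <- refine_mask(grown, grow_r = grow_r, shrink_r = shrink_r,
                         fill_holes = fill_holes, smooth_r = smooth_r)
  airways <- extract_airways(volume, refined, seed, air_hu_max = air_hu_max)
  lung <- exclude_large_airways(refined, airways, airway_cutoff_um)
  sides <- split_left_right(lung, airways, split_col = split_col)
  hists <- list(
    whole = build_histogram(volume, lung),
    left = build_histogram(volume, sides$left),
    right = build_histogram(volume, sides$right)
  )
  out <- list(lung = lung, left = sides$left, right = sides$right,
              split_status = sides$status, airways = airways,
              histograms = hists)
  if (!is.null(threshold_hu)) {
    out$outcomes <- lapply(hists, partition_volumes,
                           threshold_hu = threshold_hu,
                           voxel_edge_um = volume$voxel_edge_um)
  }
  out
}

#' H&E phantom specification
#'
#' Parameters of the synthetic stained-section image: target Blue /
#' Pink / White composition, per-class RGB means and spread, optional
#' empty-vessel lumens (white holes inside tissue, flagged in the truth
#' for reclassification testing) and additive per-channel Gaussian
#' noise.
#'
#' @param image_dim `c(height, width)` in pixels.
#' @param pixel_area_um2 physical pixel area.
#' @param fractions named target fractions `c(blue, pink, white)`
#'   summing to 1.
#' @param blue_rgb,pink_rgb,white_rgb class mean colours (0-255).
#' @param class_sd within-class RGB standard deviation.
#' @param n_vessels number of empty-vessel lumens to carve.
#' @param vessel_radius_px lumen radius in pixels.
#' @param noise_sd additive Gaussian channel noise.
#' @return An object of class `he_phantom_spec`.
#' @export
he_phantom_spec <- function(image_dim = c(160, 160), pixel_area_um2 = 1,
                            fractions = c(blue = 0.10, pink = 0.40,
                                          white = 0.50),
                            blue_rgb = c(70, 70, 160),
                            pink_rgb = c(225, 150, 170),
                            white_rgb = c(245, 245, 245),
                            class_sd = 5, n_vessels = 0,
                            vessel_radius_px = 6, noise_sd = 0) {
  fractions <- fractions[c("blue", "pink", "white")]
  if (any(is.na(fractions)) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be named blue/pink/white and sum to 1")
  if (any(fractions < 0)) stop("fractions must be nonnegative")
  structure(as.list(environment()), class = "he_phantom_spec")
}

smooth_field <- function(h, w, n_bumps, sigma_range) {
  f <- matrix(0, h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  for (i in seq_len(n_bumps)) {
    cy <- runif(1, 1, h); cx <- runif(1, 1, w)
    s <- runif(1, sigma_range[1], sigma_range[2])
    a <- runif(1, 0.5, 1.5) * sample(c(-1, 1), 1)
    f <- f + a * exp(-((ys - cy)^2 + (xs - cx)^2) / (2 * s^2))
  }
  f
}

#' Generate a synthetic H&E slide with ground truth
#'
#' Deterministic given `rng_seed`. Tissue is the upper quantile of a
#' smooth random field (so the target tissue fraction is hit exactly
#' before noise); nuclei are the upper quantile of a second, finer
#' field inside the tissue; optional vessel lumens are white disks
#' carved out of tissue and flagged in the truth. Per-pixel colours are
#' the class means plus within-class spread, then additive channel
#' noise, clamped to \[0, 255\].
#'
#' @param spec a [he_phantom_spec()].
#' @param rng_seed integer seed.
#' @return List with `slide` (an [rgb_slide()]), `roi` (logical matrix,
#'   all `TRUE`), and `truth` (label matrix 1/2/3, vessel mask, exact
#'   fractions).
#' @export
generate_he_phantom <- function(spec = he_phantom_spec(), rng_seed = 1) {
  stopifnot(inherits(spec, "he_phantom_spec"))
  with_seed(rng_seed, {
    h <- spec$image_dim[1]; w <- spec$image_dim[2]
    A <- h * w
    fr <- spec$fractions

    vessel <- matrix(FALSE, h, w)
    vessel_target <- if (spec$n_vessels > 0)
      spec$n_vessels * pi * spec$vessel_radius_px^2 / A else 0
    tissue_target <- fr[["blue"]] + fr[["pink"]] + vessel_target
    if (tissue_target > 0.95)
      stop("unreachable target fractions: tissue plus vessels exceed the frame")

    f1 <- smooth_field(h, w, 40, c(8, 22))
    tissue <- f1 >= quantile(f1, 1 - tissue_target)

    if (spec$n_vessels > 0) {
      ys <- matrix(rep(seq_len(h), times = w), h, w)
      xs <- matrix(rep(seq_len(w), each = h), h, w)
      core <- which(tissue)
      for (i in seq_len(spec$n_vessels)) {
        c0 <- arrayInd(sample(core, 1L), c(h, w))
        disk <- (ys - c0[1])^2 + (xs - c0[2])^2 <= spec$vessel_radius_px^2
        vessel <- vessel | (disk & tissue)
      }
    }

    avail <- tissue & !vessel
    blue_n <- round(fr[["blue"]] * A)
    if (sum(avail) < blue_n + 1)
      stop("unreachable target fractions: blue exceeds available tissue")
    f2 <- smooth_field(h, w, 250, c(1.2, 2.8))
    f2[!avail] <- -Inf
    cut <- sort(f2[avail], decreasing = TRUE)[blue_n]
    blue <- f2 >= cut
    # resolve ties so the blue count is exact
    excess <- sum(blue) - blue_n
    if (excess > 0) blue[sample(which(blue), excess)] <- FALSE

    labels <- matrix(3L, h, w)              # White background
    labels[avail] <- 2L                     # Pink tissue
    labels[blue] <- 1L                      # Blue nuclei
    labels[vessel] <- 3L                    # empty vessels are white

    means <- rbind(spec$blue_rgb, spec$pink_rgb, spec$white_rgb)
    px <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      base <- means[labels, ch]
      noise <- spec$class_sd * rnorm(A) + spec$noise_sd * rnorm(A)
      px[, , ch] <- matrix(pmin(pmax(round(base + noise), 0), 255), h, w)
    }
    slide <- rgb_slide(px, pixel_area_um2 = spec$pixel_area_um2)
    truth_fr <- c(blue = mean(labels == 1L), pink = mean(labels == 2L),
                  white = mean(labels == 3L))
    list(
      slide = slide,
      roi = matrix(TRUE, h, w),
      truth = list(labels = labels, vessel = vessel,
                   fractions = truth_fr,
                   tissue_fraction = truth_fr[["blue"]] + truth_fr[["pink"]],
                   spec = spec, rng_seed = rng_seed)
    )
  })
}

#' Sample training pixels from a slide using truth labels
#'
#' Convenience for the synthetic suite: draws `n_per_class` pixels of
#' each category from a labelled slide, emulating the manual selection
#' of a training set.
#'
#' @param slide an [rgb_slide()].
#' @param labels truth label matrix (1/2/3).
#' @param n_per_class training pixels per category.
#' @param rng_seed integer seed.
#' @return A training `data.frame` (see [training_set()]).
#' @export
sample_training_pixels <- function(slide, labels, n_per_class = 30,
                                   rng_seed = 1) {
  with_seed(rng_seed, {
    px <- slide$pixels
    rows <- lapply(1:3, function(k) {
      idx <- which(labels == k)
      if (length(idx) < n_per_class)
        stop("not enough ", HE_CATEGORIES[k], " pixels to sample training data")
      pick <- sample(idx, n_per_class)
      data.frame(category = HE_CATEGORIES[k],
                 R = px[, , 1][pick], G = px[, , 2][pick], B = px[, , 3][pick],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a synthetic imaging + histology cohort
#'
#' Draws a per-animal latent inflammation burden (genotype and age
#' shifts plus unit Gaussian spread) and maps it to a CT tissue volume
#' and a histology tissue area through monotone transforms with
#' independent readout noise. The noise is sized so the cohort-level
#' Spearman correlation between the two readouts equals `rho_true` in
#' expectation (via the bivariate-normal rank-correlation identity
#' `r_pearson = 2 sin(pi * rho / 6)`).
#'
#' @param n_per_cell animals per genotype x age cell (>= 2).
#' @param rho_true target Spearman correlation of the paired readouts,
#'   in \[-1, 1\].
#' @param genotype_effect latent burden excess of TNF-Tg over WT, in
#'   units of the within-cell SD.
#' @param age_effect linear latent trend per age step.
#' @param ages,genotypes design levels.
#' @param n_total optional total cohort size (e.g. the 43 animals of an
#'   unbalanced 4-6 per cell design); animals are spread across cells as
#'   evenly as possible and `n_per_cell` is ignored.
#' @param rng_seed integer seed.
#' @return List with `table` (long cohort table: animal_id, genotype,
#'   age_months, outcome, value) and `pairs` (animal_id, ct_value,
#'   histo_value).
#' @export
generate_cohort <- function(n_per_cell = 5, rho_true = 0.85,
                            genotype_effect = 2, age_effect = 0,
                            ages = c(3, 4, 5.5, 12),
                            genotypes = c("WT", "TNF-Tg"),
                            n_total = NULL, rng_seed = 1) {
  if (rho_true < -1 || rho_true > 1)
    stop("rho_true must lie within [-1, 1]")
  cells <- expand.grid(age = ages, genotype = genotypes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (is.null(n_total)) {
    if (n_per_cell < 2) stop("n_per_cell must be >= 2")
    sizes <- rep(n_per_cell, nrow(cells))
  } else {
    k <- nrow(cells)
    if (n_total < 2 * k) stop("n_total too small for >= 2 per cell")
    sizes <- rep(n_total %/% k, k)
    extra <- n_total %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  }
  with_seed(rng_seed, {
    design <- cells[rep(seq_len(nrow(cells)), sizes), , drop = FALSE]
    n <- nrow(design)
    mu <- genotype_effect * (design$genotype == genotypes[2]) +
      age_effect * (match(design$age, ages) - 1)
    burden <- mu + rnorm(n)
    r <- 2 * sin(pi * rho_true / 6)
    v_burden <- 1 + stats::var(mu) * (n - 1) / n
    s2 <- if (abs(r) >= 1) 0 else v_burden * (1 - abs(r)) / abs(r)
    sgn <- if (r < 0) -1 else 1
    if (r == 0) {
      ct_lat <- rnorm(n)
      he_lat <- rnorm(n)
    } else {
      ct_lat <- burden + sqrt(s2) * rnorm(n)
      he_lat <- sgn * burden + sqrt(s2) * rnorm(n)
    }
    ct_value <- 100 * exp(0.15 * ct_lat)       # tissue volume scale, mm3-like
    he_value <- 40 * exp(0.20 * he_lat)        # tissue area scale, mm2-like
    animal_id <- sprintf("M%03d", seq_len(n))
    table <- rbind(
      data.frame(animal_id, genotype = design$genotype,
                 age_months = design$age, outcome = "ct_tissue_volume",
                 value = ct_value, stringsAsFactors = FALSE),
      data.frame(animal_id, genotype = design$genotype,
                 age_months = design$age, outcome = "histo_tissue_area",
                 value = he_value, stringsAsFactors = FALSE)
    )
    pairs <- data.frame(animal_id, genotype = design$genotype,
                        age_months = design$age,
                        ct_value, histo_value = he_value,
                        stringsAsFactors = FALSE)
    list(table = table, pairs = pairs)
  })
}
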