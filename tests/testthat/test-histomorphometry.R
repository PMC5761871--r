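test_that("classifier training enforces the 15-pixel floor and priors", {
  tr <- make_training()
  clf <- train_classifier(tr)
  expect_s3_class(clf, "pixel_classifier")
  expect_equal(sum(clf$priors), 1)

  short <- tr[-(1:6), ]           # Blue drops to 14 pixels
  expect_error(train_classifier(short), "Blue")
  expect_warning(train_classifier(make_training(n = 15, seed = 30)),
                 "exactly 15")

  # cluster means map to their own category
  for (cat_ in c("Blue", "Pink", "White")) {
    mu <- clf$fits[[cat_]]$mean
    lab <- classify_rgb_for_test(clf, matrix(mu, 1))
    expect_equal(c("Blue", "Pink", "White")[lab], cat_)
  }

  # identical Blue/Pink training data: deterministic Blue-first tie-break
  dup <- tr
  dup[dup$category == "Pink", c("R", "G", "B")] <-
    dup[dup$category == "Blue", c("R", "G", "B")]
  expect_warning(clf2 <- train_classifier(dup), "indistinguishable")
  lab2 <- classify_rgb_for_test(clf2, matrix(clf2$fits$Blue$mean, 1))
  expect_equal(lab2, 1L)
})

test_that("classifier decisions match the density-evaluation oracle", {
  set.seed(32)
  tr <- make_training(n = 40, sd = 6)
  clf <- train_classifier(tr)
  q <- matrix(round(runif(3000, 0, 255)), ncol = 3)
  expect_identical(classify_rgb_for_test(clf, q),
                   as.integer(gaussian_oracle_labels(clf, q)))
})

test_that("duplicating every training pixel leaves decisions unchanged", {
  tr <- make_training(n = 25, sd = 5, seed = 33)
  clf1 <- train_classifier(tr)
  clf2 <- train_classifier(rbind(tr, tr))
  set.seed(34)
  q <- matrix(round(runif(1500, 0, 255)), ncol = 3)
  expect_identical(classify_rgb_for_test(clf1, q),
                   classify_rgb_for_test(clf2, q))
})

test_that("slide classification labels exactly the ROI", {
  ph <- generate_he_phantom(he_phantom_spec(noise_sd = 4), rng_seed = 5)
  tr <- sample_training_pixels(ph$slide, ph$truth$labels, 30, rng_seed = 6)
  clf <- train_classifier(tr)

  roi <- ph$roi
  roi[1:40, ] <- FALSE
  lab <- classify_slide(ph$slide, roi, clf)
  expect_true(all(unclass(lab)[!roi] == 0L))
  expect_true(all(unclass(lab)[roi] %in% 1:3))
  # conservation: labelled pixels = ROI pixels
  expect_equal(sum(unclass(lab) != 0L), sum(roi))
  expect_error(classify_slide(ph$slide, ph$roi & FALSE, clf), "empty ROI")

  # uniform slide at the White mean is all White
  white <- rgb_slide(array(rep(c(245, 245, 245), each = 100),
                           dim = c(10, 10, 3)))
  labw <- classify_slide(white, matrix(TRUE, 10, 10), clf)
  expect_true(all(unclass(labw) == 3L))
})

test_that("box-mode classification covers every pixel deterministically", {
  tr <- make_training(n = 30, sd = 4, seed = 35)
  clf <- train_classifier(tr, mode = "box")
  set.seed(36)
  q <- matrix(round(runif(900, 0, 255)), ncol = 3)
  lab <- classify_rgb_for_test(clf, q)
  expect_true(all(lab %in% 1:3))
  # pixels inside exactly one training box take that label
  mu <- clf$fits$Blue$mean
  expect_equal(classify_rgb_for_test(clf, matrix(mu, 1)), 1L)
})

test_that("reclassification changes exactly the from-category pixels in region", {
  ph <- generate_he_phantom(he_phantom_spec(n_vessels = 3), rng_seed = 7)
  tr <- sample_training_pixels(ph$slide, ph$truth$labels, 30, rng_seed = 8)
  clf <- train_classifier(tr)
  lab <- classify_slide(ph$slide, ph$roi, clf)

  none <- reclassify_regions(lab, NULL, "White", "Pink")
  expect_identical(as.integer(unclass(none)), as.integer(unclass(lab)))
  expect_equal(attr(none, "n_changed"), 0)

  before_white <- sum(unclass(lab) == 3L)
  expected <- sum(ph$truth$vessel & unclass(lab) == 3L)
  lab2 <- reclassify_regions(lab, ph$truth$vessel, "White", "Pink")
  expect_equal(attr(lab2, "n_changed"), expected)
  expect_equal(sum(unclass(lab2) == 3L), before_white - expected)
  # pixels outside the region or with other labels are untouched
  outside <- !ph$truth$vessel
  expect_identical(unclass(lab2)[outside], unclass(lab)[outside])
  # conservation of the total labelled count
  expect_equal(sum(unclass(lab2) != 0L), sum(unclass(lab) != 0L))
})

test_that("area outcomes sum, normalize and respect the inclusion floor", {
  lab <- matrix(c(rep(1L, 30), rep(2L, 20), rep(3L, 50)), 10, 10)
  class(lab) <- c("he_label_map", "matrix", "array")
  attr(lab, "pixel_area_um2") <- 1
  oc <- quantify_areas(lab, min_total_area_um2 = 0)
  expect_equal(oc$tissue_um2, 50)
  expect_equal(oc$tissue_fraction, 0.5)
  expect_equal(oc$blue_fraction + oc$pink_fraction + oc$white_fraction, 1)
  expect_equal(oc$blue_um2 + oc$pink_um2 + oc$white_um2, oc$total_um2)
  expect_false(oc$excluded)

  flagged <- quantify_areas(lab, min_total_area_um2 = 1e6)
  expect_true(flagged$excluded)
  expect_equal(flagged$total_um2, oc$total_um2)   # flagged, not dropped
})

test_that("per-animal aggregation averages areas and refits fractions", {
  mk <- function(b, p, w) {
    lab <- matrix(c(rep(1L, b), rep(2L, p), rep(3L, w)), nrow = 10)
    class(lab) <- c("he_label_map", "matrix", "array")
    attr(lab, "pixel_area_um2") <- 1
    quantify_areas(lab, min_total_area_um2 = 0, animal_id = "m1")
  }
  s1 <- mk(10, 0, 90); s2 <- mk(30, 20, 50)
  agg <- aggregate_animal(list(s1, s2))
  expect_equal(c(agg$blue_fraction, agg$pink_fraction, agg$white_fraction),
               c(0.2, 0.1, 0.7))
  expect_equal(agg$blue_um2, 20)            # mean of 10 and 30

  same <- aggregate_animal(list(s2, s2, s2))
  expect_equal(same$tissue_fraction, s2$tissue_fraction)
  expect_equal(same$total_um2, s2$total_um2)

  solo <- aggregate_animal(list(s1))
  expect_equal(solo$tissue_um2, s1$tissue_um2)

  s_excl <- mk(4, 3, 3); s_excl$excluded <- TRUE
  expect_error(aggregate_animal(list(s_excl)), "excluded")
})

test_that("polygon ROIs rasterize by pixel-centre containment", {
  sq <- rbind(c(2.5, 2.5), c(7.5, 2.5), c(7.5, 7.5), c(2.5, 7.5))
  m <- roi_from_polygon(sq, c(10, 10))
  expect_equal(sum(m), 25)                  # pixel centres 3..7 in both axes
  expect_true(m[5, 5]); expect_false(m[1, 1])
})
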