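test_that("histogram binning clamps, rounds and conserves counts", {
  vol <- ct_volume(array(-800, dim = c(2, 5, 1)))
  h <- build_histogram(vol, array(TRUE, dim = c(2, 5, 1)))
  expect_equal(h$counts[h$bin_hu == -800], 10)
  expect_equal(sum(h$counts), 10)

  low <- ct_volume(array(-1200, dim = c(2, 2, 2)))
  hl <- build_histogram(low, array(TRUE, dim = c(2, 2, 2)))
  expect_equal(hl$counts[hl$bin_hu == -1000], 8)

  set.seed(21)
  hu <- array(runif(6^3, -1500, 1500), dim = c(6, 6, 6))
  m <- array(runif(6^3) < 0.5, dim = c(6, 6, 6))
  hr <- build_histogram(ct_volume(hu), m)
  expect_equal(sum(hr$counts), sum(m))

  expect_warning(
    he <- build_histogram(ct_volume(hu), array(FALSE, dim = c(6, 6, 6))),
    "empty mask")
  expect_equal(sum(he$counts), 0)
})

test_that("weighted mean density follows the histogram formula", {
  one <- intensity_histogram(replace(integer(2001), 1001 + 123, 7))
  expect_equal(weighted_mean_hu(one), 123)

  sym <- integer(2001); sym[1] <- 1; sym[1001] <- 1
  expect_equal(weighted_mean_hu(intensity_histogram(sym)), -500)

  two <- integer(2001); two[1001 - 900] <- 3; two[1001 - 300] <- 1
  expect_equal(weighted_mean_hu(intensity_histogram(two)), -750)

  expect_error(weighted_mean_hu(intensity_histogram(integer(2001))),
               "undefined")
  # always inside the occupied bin range
  set.seed(22)
  for (i in 1:20) {
    h <- random_histogram()
    wm <- weighted_mean_hu(h)
    occ <- h$bin_hu[h$counts > 0]
    expect_gte(wm, min(occ)); expect_lte(wm, max(occ))
  }
})

test_that("threshold derivation pools WT histograms and is order/split invariant", {
  at <- function(hu, n) {
    counts <- integer(2001); counts[1001 + hu] <- n
    intensity_histogram(counts)
  }
  expect_equal(derive_threshold(list(at(-256, 10), at(-256, 99))), -256L)
  expect_equal(derive_threshold(list(at(-300, 50), at(-200, 50))), -250L)
  expect_error(derive_threshold(list()), "at least one")

  set.seed(23)
  hs <- lapply(1:6, function(i) random_histogram())
  t1 <- derive_threshold(hs)
  t2 <- derive_threshold(rev(hs))
  expect_identical(t1, t2)
  # splitting one mouse's histogram into two with the same bin-wise sum
  half <- hs[[1]]$counts %/% 2
  rest <- hs[[1]]$counts - half
  stopifnot(sum(half) > 0, sum(rest) > 0)
  t3 <- derive_threshold(c(list(intensity_histogram(half),
                                intensity_histogram(rest)), hs[-1]))
  expect_identical(t1, t3)

  # mouse-weighted and mode variants stay available
  expect_equal(derive_threshold(list(at(-300, 10), at(-200, 1000)),
                                method = "mouse_mean"), -250L)
  expect_equal(derive_threshold(list(at(-300, 10), at(-200, 1000)),
                                method = "mode"), -200L)
})

test_that("volume partition respects the tissue-at-threshold convention", {
  below <- integer(2001); below[1001 - 800] <- 50
  oc <- partition_volumes(intensity_histogram(below), -256, 35)
  expect_equal(oc$aerated_fraction, 1)
  expect_equal(oc$tissue_fraction, 0)

  at_thr <- integer(2001); at_thr[1001 - 256] <- 50
  oc2 <- partition_volumes(intensity_histogram(at_thr), -256, 35)
  expect_equal(oc2$tissue_fraction, 1)

  expect_equal(oc$total_mm3, 50 * (35 / 1000)^3)

  # conservation and monotonicity over random histograms
  set.seed(24)
  for (i in 1:25) {
    h <- random_histogram()
    thr <- sample(-900:900, 1)
    a <- partition_volumes(h, thr, 35)
    expect_identical(a$aerated_voxels + a$tissue_voxels, a$total_voxels)
    expect_equal(a$aerated_fraction + a$tissue_fraction, 1)
    b <- partition_volumes(h, min(thr + 100, 1000), 35)
    expect_gte(b$aerated_voxels, a$aerated_voxels)
  }
})

test_that("CTDI integrates the dose profile over [-50, 50] / (N*T)", {
  z <- seq(-60, 60, by = 1)
  expect_equal(ctdi(z, rep(2.5, length(z)), n_slices = 100,
                    section_thickness_mm = 1), 2.5)
  # triangular profile peaking at 0: closed-form area = peak * 50
  tri <- pmax(0, 1 - abs(z) / 50)
  expect_equal(ctdi(z, tri, 50, 1), 50 / 50)
  expect_equal(ctdi(z, rep(0, length(z)), 10, 1), 0)
  expect_error(ctdi(seq(-40, 50), rep(1, 91), 10, 1), "span")

  expect_equal(ctdi_w(0.09, 0.12), 0.11)
  expect_equal(ctdi_w(3, 3), 3)
  expect_equal(ctdi_w(0, 0), 0)
  expect_error(ctdi_w(-1, 1), ">= 0")
})

test_that("histogram CSVs round-trip", {
  h <- random_histogram()
  path <- withr::local_tempfile(fileext = ".csv")
  write_histogram_csv(h, path)
  back <- read_histogram_csv(path, voxel_edge_um = 35)
  expect_equal(back$counts, h$counts)
  expect_equal(back$bin_hu, h$bin_hu)

  # sparse export with out-of-domain rows clamp-accumulates
  sparse <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(hu = c(-1200, -1000, -256, 40),
                       count = c(2, 3, 7, 1)), sparse, row.names = FALSE)
  hs <- read_histogram_csv(sparse)
  expect_equal(hs$counts[hs$bin_hu == -1000], 5)
  expect_equal(hs$counts[hs$bin_hu == -256], 7)
  expect_equal(sum(hs$counts), 13)
})
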