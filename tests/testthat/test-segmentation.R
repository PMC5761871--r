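test_that("region growing returns the seed's in-range connected component", {
  vol <- ct_volume(array(-800, dim = c(3, 3, 3)))
  expect_equal(sum(seeded_region_grow(vol, c(2, 2, 2), -1000, -150)$voxels), 27)

  tube <- ct_volume(array(c(-800, -800, 0, -800, -800), dim = c(1, 1, 5)))
  m <- seeded_region_grow(tube, c(1, 1, 1), -1000, -150)
  expect_identical(which(m$voxels), 1:2)

  solid <- ct_volume(array(0, dim = c(2, 2, 2)))
  expect_equal(sum(seeded_region_grow(solid, c(1, 1, 1), -1000, -150)$voxels), 0)

  expect_error(seeded_region_grow(vol, c(9, 1, 1)), "bounds")
  expect_error(seeded_region_grow(vol, c(1, 1, 1), -100, -400), "low_hu")
  nf <- ct_volume(array(c(NaN, rep(-800, 7)), dim = c(2, 2, 2)))
  expect_error(seeded_region_grow(nf, c(1, 1, 1)), "non-finite")
})

test_that("region growing matches the brute-force BFS oracle on random grids", {
  set.seed(11)
  for (i in 1:25) {
    hu <- array(sample(c(-900, -500, 0), 8^3, replace = TRUE,
                       prob = c(0.4, 0.2, 0.4)), dim = c(8, 8, 8))
    vol <- ct_volume(hu)
    seed <- sample(8, 3, replace = TRUE)
    got <- seeded_region_grow(vol, seed, -1000, -150)$voxels
    expect_identical(got, bfs_flood_fill(hu, seed, -1000, -150))
  }
})

test_that("region growing is idempotent under re-seeding inside the mask", {
  set.seed(12)
  hu <- array(sample(c(-800, 0), 10^3, replace = TRUE), dim = c(10, 10, 10))
  vol <- ct_volume(hu)
  seeds <- which(hu == -800)
  first <- seeded_region_grow(vol, arrayInd(seeds[1], dim(hu))[1, ])
  inside <- which(first$voxels)
  for (s in sample(inside, min(5, length(inside)))) {
    again <- seeded_region_grow(vol, arrayInd(s, dim(hu))[1, ])
    expect_identical(again$voxels, first$voxels)
  }
})

test_that("mask refinement applies grow, shrink, fill and smooth in order", {
  cube <- array(TRUE, dim = c(5, 5, 5))
  cube[3, 3, 3] <- FALSE
  filled <- refine_mask(seg_mask(cube), 0, 0, TRUE, 0)
  expect_equal(sum(filled$voxels), 125)

  any_mask <- array(FALSE, dim = c(4, 4, 4))
  any_mask[2:3, 2:3, 2:3] <- TRUE
  expect_identical(refine_mask(seg_mask(any_mask), 0, 0, FALSE, 0)$voxels,
                   any_mask)

  one <- array(FALSE, dim = c(5, 5, 5))
  one[3, 3, 3] <- TRUE
  expect_equal(sum(refine_mask(seg_mask(one), 1, 0, FALSE, 0)$voxels), 7)
  expect_warning(refine_mask(seg_mask(one), 0, 1, FALSE, 0), "empty")
})

test_that("airway diameters follow the inscribed-sphere convention", {
  tube <- make_tube_volume(radius_vox = 3)
  lung <- seg_mask(array(TRUE, dim = dim(tube$volume)))
  aw <- extract_airways(tube$volume, lung,
                        c(tube$centre[1], tube$centre[2], tube$centre[3]))
  centre_dia <- aw$local_diameter_um[tube$centre[1], tube$centre[2],
                                     tube$centre[3]]
  expect_lt(abs(centre_dia - 210), 35)        # within one voxel edge

  single <- ct_volume(array(c(-1000, rep(0, 26)), dim = c(3, 3, 3)), 35)
  lung1 <- seg_mask(array(TRUE, dim = c(3, 3, 3)))
  aw1 <- extract_airways(single, lung1, c(1, 1, 1))
  expect_equal(aw1$local_diameter_um[1, 1, 1], 35)

  thin <- make_tube_volume(radius_vox = 2)
  aw2 <- extract_airways(thin$volume, lung,
                         c(thin$centre[1], thin$centre[2], thin$centre[3]))
  expect_true(all(aw2$local_diameter_um[aw2$voxels] < 200))

  expect_error(extract_airways(tube$volume, lung, c(1, 1, 1)),
               "not at air density")
})

test_that("large-airway exclusion removes whole branches above the cutoff", {
  wide <- make_tube_volume(radius_vox = 4)   # ~280 um wall-to-wall
  lung <- seg_mask(array(TRUE, dim = dim(wide$volume)))
  aw <- extract_airways(wide$volume, lung,
                        c(wide$centre[1], wide$centre[2], wide$centre[3]))
  bd <- airway_branch_diameter(aw)
  expect_true(all(bd[aw$voxels] > 200))      # thickness propagates to walls
  out <- exclude_large_airways(lung, aw, 200)
  expect_identical(attr(out, "excluded"), aw$voxels)
  expect_true(all(out$voxels == (lung$voxels & !aw$voxels)))

  thin <- make_tube_volume(radius_vox = 2)   # ~140 um: below cutoff
  aw2 <- extract_airways(thin$volume, lung,
                         c(thin$centre[1], thin$centre[2], thin$centre[3]))
  kept <- exclude_large_airways(lung, aw2, 200)
  expect_identical(kept$voxels, lung$voxels)

  all_gone <- exclude_large_airways(lung, aw2, 0)
  expect_true(all(!(all_gone$voxels & aw2$voxels)))

  # never adds voxels
  expect_true(all(kept$voxels <= lung$voxels))
})

test_that("left/right split assigns components by side of the carina", {
  d <- c(10, 10, 20)
  m <- array(FALSE, dim = d)
  m[3:8, 3:8, 2:7] <- TRUE        # left block (low columns)
  m[3:8, 3:8, 14:19] <- TRUE      # right block
  aw <- structure(list(voxels = array(FALSE, dim = d),
                       local_diameter_um = array(NA_real_, dim = d),
                       voxel_edge_um = 35), class = "airway_segment")
  aw$voxels[5, 5, 10] <- TRUE     # carina at the midline
  sp <- split_left_right(seg_mask(m), aw)
  expect_equal(sp$status, "components")
  expect_true(all(which(sp$left$voxels, arr.ind = TRUE)[, 3] <= 7))
  expect_true(all(which(sp$right$voxels, arr.ind = TRUE)[, 3] >= 14))
  # disjoint and exhaustive
  expect_false(any(sp$left$voxels & sp$right$voxels))
  expect_identical(sp$left$voxels | sp$right$voxels, m)
  # mirror symmetry gives equal volumes
  expect_equal(sum(sp$left$voxels), sum(sp$right$voxels))

  bridged <- m
  bridged[5:6, 5:6, 1:20] <- TRUE # one component
  expect_error(split_left_right(seg_mask(bridged), aw), "split failed")
  sp2 <- split_left_right(seg_mask(bridged), aw, split_col = 10.5)
  expect_equal(sp2$status, "plane")
  expect_true(all(which(sp2$left$voxels, arr.ind = TRUE)[, 3] < 10.5))
  expect_identical(sp2$left$voxels | sp2$right$voxels, bridged)
})
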