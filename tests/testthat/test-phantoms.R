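test_that("base phantom has the protocol grid, contrast ordering and determinism", {
  ph <- make_base_phantom(128, 2.08, seed = 1)
  expect_identical(dim(ph$activity), c(128L, 128L))
  expect_identical(dim(ph$mr), c(128L, 128L))
  expect_identical(dim(ph$mumap), c(128L, 128L))
  expect_equal(ph$spacing_mm, 2.08)
  expect_true(all(ph$activity >= 0))
  expect_true(all(ph$mumap >= 0))
  # grey > white > background activity levels
  expect_gt(mean(ph$activity[ph$tissue == 2L]), mean(ph$activity[ph$tissue == 1L]))
  expect_gt(mean(ph$activity[ph$tissue == 1L]), mean(ph$activity[ph$tissue == 0L]))
  # MR has its own contrast (white bright on T1)
  expect_gt(mean(ph$mr[ph$tissue == 1L]), mean(ph$mr[ph$tissue == 2L]))

  # bitwise determinism and seed sensitivity
  expect_identical(make_base_phantom(64, 2.08, seed = 7),
                   make_base_phantom(64, 2.08, seed = 7))
  a <- make_base_phantom(64, 2.08, seed = 1)$activity
  b <- make_base_phantom(64, 2.08, seed = 2)$activity
  expect_gt(mean(a != b), 0.01)

  expect_error(make_base_phantom(16, 2.08, seed = 1), "at least 32")
})

test_that("lesion insertion follows the radius/polarity/mismatch protocol", {
  ph <- make_base_phantom(128, 2.08, seed = 3)
  les <- add_lesions(ph, n_lesions = 10, radius_range_mm = c(2, 10),
                     mismatch_fraction = 0.3, seed = 5)
  expect_equal(nrow(les$lesions), 10)
  expect_true(all(les$lesions$radius_mm >= 2 & les$lesions$radius_mm <= 10))
  expect_length(les$lesion_masks, 10)
  expect_equal(sum(les$lesions$modality != "shared"), 3)
  # all lesion masks lie inside the brain
  brain <- ph$tissue > 0L
  for (m in les$lesion_masks) expect_true(all(brain[m]))
  # zero lesions leaves the sample untouched
  expect_identical(add_lesions(ph, n_lesions = 0, seed = 1), ph)

  # a pet_only lesion alters only activity, an mr_only lesion only MR
  ponly <- which(les$lesions$modality == "pet_only")
  monly <- which(les$lesions$modality == "mr_only")
  for (k in ponly) {
    m <- les$lesion_masks[[k]]
    expect_false(isTRUE(all.equal(les$activity[m], ph$activity[m])))
    expect_equal(les$mr[m], ph$mr[m])
  }
  for (k in monly) {
    m <- les$lesion_masks[[k]]
    expect_equal(les$activity[m], ph$activity[m])
    expect_false(isTRUE(all.equal(les$mr[m], ph$mr[m])))
  }
  expect_error(add_lesions(ph, 1, radius_range_mm = c(0, 300), seed = 1),
               "radius_range")
})

test_that("rasterized lesion area matches the analytic disk area", {
  ph <- make_base_phantom(128, 2.08, seed = 4)
  les <- add_lesions(ph, n_lesions = 1, radius_range_mm = c(6, 6), seed = 9)
  area_px <- sum(les$lesion_masks[[1]])
  expect_lt(abs(area_px - pi * (6 / 2.08)^2) / (pi * (6 / 2.08)^2), 0.15)
})

test_that("rotation augmentation preserves grids, masks and non-negativity", {
  ph <- make_base_phantom(64, 2.08, seed = 6)
  ph <- add_lesions(ph, 5, c(2, 8), seed = 2)
  rots <- augment_rotations(ph, n_rotations = 5, max_abs_deg = 5, seed = 3)
  expect_length(rots, 5)
  for (r in rots) {
    expect_true(abs(r$rotation_deg) <= 5)
    expect_true(all(r$activity >= 0))
    expect_true(all(r$mumap >= 0))
    # lesion masks stay inside the rotated brain mask
    brain <- r$tissue > 0L
    for (m in r$lesion_masks) expect_true(all(brain[m]))
  }
  # zero maximum angle is the identity (bilinear at exact grid points)
  r0 <- augment_rotations(ph, 1, max_abs_deg = 0, seed = 1)[[1]]
  expect_equal(r0$activity, ph$activity, tolerance = 1e-12)

  # +theta then -theta returns interior activity within interpolation error
  r1 <- fbsem:::rotate_phantom(ph, 7)
  r2 <- fbsem:::rotate_phantom(r1, -7)
  interior <- fbsem:::erode_mask(fbsem:::erode_mask(ph$tissue > 0L))
  err <- mean(abs(r2$activity[interior] - ph$activity[interior]))
  expect_lt(err / mean(ph$activity[interior]), 0.15)
})

test_that("100 slices x 5 rotations style augmentation gives the expected count", {
  ph <- make_base_phantom(32, 2.08, seed = 1)
  out <- lapply(1:4, function(s) augment_rotations(ph, 5, 5, seed = s))
  expect_equal(length(unlist(out, recursive = FALSE)), 20)
})
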