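test_that("ROI membership follows the voxel-centre distance rule", {
  img <- random_image(c(11, 11, 11), spacing = rep(1, 3))
  # radius below half the spacing, centred on a voxel centre: one voxel
  one <- roi_voxels(img, spherical_roi(c(5, 5, 5), 0.4))
  expect_equal(nrow(one), 1)
  expect_equal(unname(one[1, ]), c(6, 6, 6))

  # degenerate single-voxel image: the ROI spans every voxel there is
  tiny <- random_image(c(1, 1, 1), spacing = rep(1, 3))
  expect_equal(nrow(roi_voxels(tiny, spherical_roi(c(0, 0, 0), 0.45))), 1)

  # radius 5 mm at 1 mm isotropic: close to (4/3) pi 5^3 voxel centres,
  # and exactly the brute-force enumeration
  roi <- spherical_roi(c(5, 5, 5), 5)
  got <- roi_voxels(img, roi)
  g <- expand.grid(i = 1:11, j = 1:11, k = 1:11)
  inside <- (g$i - 6)^2 + (g$j - 6)^2 + (g$k - 6)^2 <= 25
  expect_equal(nrow(got), sum(inside))
  expect_lt(abs(nrow(got) - 4 / 3 * pi * 125), 4 * pi * 25) # one voxel shell

  expect_error(roi_voxels(img, spherical_roi(c(5, 5, 5), 8)), "extends outside")
  expect_error(roi_voxels(img, spherical_roi(c(-3, 5, 5), 1)), "along x")
})

test_that("ROI extremes are the exact min and max over the ROI", {
  flat <- random_image(c(9, 9, 9), intensities = array(7, c(9, 9, 9)))
  ex <- roi_extremes(flat, spherical_roi(c(4, 4, 4), 3))
  expect_equal(ex, list(i_min = 7, i_max = 7))

  withr::with_seed(42, {
    img <- random_image(c(15, 13, 12), spacing = c(1, 1.2, 0.8))
    roi <- random_roi(img)
    ex <- roi_extremes(img, roi)
    m <- brute_sit_mask(img, roi, 0) # c = 0 selects the whole ROI
    expect_equal(ex$i_min, min(img$intensities[m]))
    expect_equal(ex$i_max, max(img$intensities[m]))
  })
})

test_that("the SIT lower bound is C*(Imax-Imin)+Imin", {
  expect_equal(sit_lower_bound(list(i_min = 0, i_max = 1000), 0.30), 300)
  expect_equal(sit_lower_bound(list(i_min = 200, i_max = 1000), 0.5), 600)
  expect_equal(sit_lower_bound(list(i_min = 123, i_max = 999), 0), 123)
  expect_equal(sit_lower_bound(list(i_min = 123, i_max = 999), 1), 999)
  expect_error(sit_lower_bound(list(i_min = 0, i_max = 1), 1.2), "\\[0, 1\\]")
  expect_error(sit_lower_bound(list(i_min = 2, i_max = 1), 0.5), "invalid")
})

test_that("SIT segmentation matches the exhaustive per-voxel oracle", {
  withr::with_seed(101, {
    for (trial in 1:25) {
      dims <- sample(5:20, 3, replace = TRUE)
      img <- random_image(dims, spacing = runif(3, 0.5, 2))
      roi <- random_roi(img)
      cc <- runif(1)
      mask <- segment_sit(img, roi, cc)
      expect_identical(mask$member, brute_sit_mask(img, roi, cc))
    }
  })
})

test_that("SIT limit cases: C = 0 keeps the ROI, C = 1 keeps the argmax", {
  withr::with_seed(7, {
    img <- random_image(c(14, 14, 14))
    roi <- spherical_roi(c(6.5, 6.5, 6.5), 5)
    m0 <- segment_sit(img, roi, 0)
    vox <- roi_voxels(img, roi)
    expect_equal(which(m0$member, arr.ind = TRUE), vox, ignore_attr = TRUE)

    m1 <- segment_sit(img, roi, 1)
    sel <- which(m1$member)
    expect_equal(length(sel), 1) # continuous intensities: unique maximum
    expect_equal(img$intensities[sel],
                 max(img$intensities[m0$member]))
  })
})

test_that("masks are nested and non-increasing in C and stay inside the ROI", {
  ctr <- (c(48, 48, 48) - 1) / 2 * 0.98
  spec <- phantom_spec(c(48, 48, 48), rep(0.98, 3),
                       list(nodule_spec("n", ctr, 120, "hemisphere")),
                       nodule_signal = 100, background_mean = 20,
                       background_texture_sd = 5, blur_fwhm = 1.2,
                       noise_model = "rician", noise_sd = 6, seed = 9L)
  img <- compose_phantom(spec)$image
  roi <- spherical_roi(ctr, 2 * (3 * 120 / (4 * pi))^(1 / 3))
  grid <- c(0.2, 0.3, 0.4, 0.5)
  masks <- lapply(grid, function(cc) segment_sit(img, roi, cc))
  vols <- vapply(masks, mask_volume, 0)
  expect_true(all(diff(vols) <= 0))
  for (i in seq_len(length(grid) - 1)) {
    expect_true(all(masks[[i]]$member[masks[[i + 1]]$member]))
  }
  roi_m <- array(FALSE, c(48, 48, 48))
  roi_m[roi_voxels(img, roi)] <- TRUE
  for (m in masks) expect_true(all(roi_m[m$member]))
})

test_that("binary noiseless phantoms segment to the same volume for any interior C", {
  ph <- binary_phantom(volume = 150, signal = 100)
  ctr <- (c(48, 48, 48) - 1) / 2 * 0.98
  roi <- spherical_roi(ctr, 2 * (3 * 150 / (4 * pi))^(1 / 3))
  vols <- vapply(c(0.05, 0.3, 0.5, 0.7, 0.95),
                 function(cc) mask_volume(segment_sit(ph$image, roi, cc)), 0)
  expect_true(all(vols == vols[1]))
})

test_that("26-connected labelling and largest-component filtering behave", {
  m <- array(FALSE, c(8, 8, 8))
  m[2:4, 2:4, 2:4] <- TRUE      # 27 voxels
  m[6, 6, 6] <- TRUE            # corner-touching singleton chain
  m[7, 7, 7] <- TRUE            # 26-connected to (6,6,6)
  lab <- label_components_26(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[6, 6, 6], lab[7, 7, 7]) # diagonal adjacency connects
  keep <- sitvolumetry:::keep_largest_component(m)
  expect_equal(sum(keep), 27)
  expect_identical(sitvolumetry:::keep_largest_component(keep), keep)

  # tie: two equal blocks -> lexicographically first seed wins
  t2 <- array(FALSE, c(8, 8, 8))
  t2[1:2, 1:2, 1:2] <- TRUE
  t2[6:7, 6:7, 6:7] <- TRUE
  kept <- sitvolumetry:::keep_largest_component(t2)
  expect_true(kept[1, 1, 1] && !kept[6, 6, 6])
})

test_that("the CT surrogate thresholds and keeps the largest component", {
  # air-only ROI -> empty mask, warned not errored
  air <- random_image(c(12, 12, 12),
                      intensities = array(-1000, c(12, 12, 12)))
  expect_warning(
    m <- segment_ct_surrogate(air, spherical_roi(c(5, 5, 5), 4)),
    "empty"
  )
  expect_equal(mask_volume(m), 0)

  # binary phantom in HU: exactly the majority-occupancy voxels
  arr <- array(-1000, c(24, 24, 24))
  ctr <- (c(24, 24, 24) - 1) / 2 * 0.98
  occ <- rasterize_nodule(nodule_spec("n", ctr, 120, "hemisphere"),
                          c(24, 24, 24), rep(0.98, 3), 4)
  hu <- -1000 + 1020 * occ # nodule +20 HU
  img <- volumetric_image(hu, rep(0.98, 3))
  roi <- spherical_roi(ctr, 2 * (3 * 120 / (4 * pi))^(1 / 3))
  m <- segment_ct_surrogate(img, roi, hu_cut = -400)
  expect_identical(m$member, occ >= (600 / 1020) &
                     sitvolumetry:::roi_mask(img, roi))

  # blurred phantom agrees with a brute-force threshold scan
  img_b <- volumetric_image(gaussian_blur(hu, 1.5, rep(0.98, 3)), rep(0.98, 3))
  m_b <- segment_ct_surrogate(img_b, roi, hu_cut = -400)
  brute <- sitvolumetry:::roi_mask(img_b, roi) & img_b$intensities >= -400
  brute <- sitvolumetry:::keep_largest_component(brute)
  expect_identical(m_b$member, brute)
})

test_that("keep_largest leaves a unique-max SIT mask intact", {
  arr <- array(5, c(10, 10, 10))
  arr[5, 5, 5] <- 10
  img <- volumetric_image(arr, rep(1, 3))
  roi <- spherical_roi(c(4.5, 4.5, 4.5), 4)
  expect_no_warning(m <- segment_sit(img, roi, 1, keep_largest = TRUE))
  expect_equal(sum(m$member), 1)
})
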