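test_that("sampled volume sets span the requested range reproducibly", {
  v <- sample_nodule_volumes(22, 16, 561, seed = 11)
  expect_length(v, 22)
  expect_equal(min(v), 16)
  expect_equal(max(v), 561)
  expect_true(all(v >= 16 & v <= 561))
  expect_identical(v, sample_nodule_volumes(22, 16, 561, seed = 11))
  expect_false(identical(v, sample_nodule_volumes(22, 16, 561, seed = 12)))

  expect_equal(sort(sample_nodule_volumes(2, 16, 561, seed = 1)), c(16, 561))
  eps <- 1e-6
  expect_true(all(abs(sample_nodule_volumes(5, 100, 100 + eps, seed = 1) - 100) < 1e-3))

  expect_error(sample_nodule_volumes(0, 16, 561), "positive integer")
  expect_error(sample_nodule_volumes(5, -1, 561), "positive")
  expect_error(sample_nodule_volumes(5, 561, 16), "smaller")
})

test_that("default study draw reproduces the manufactured design", {
  v <- default_nodule_volumes(seed = 3)
  expect_length(v, 22)
  expect_equal(sum(v < 50), 4)
  expect_equal(min(v), 16)
  expect_equal(max(v), 561)
  # property holds across seeds, not just one draw
  for (s in 4:8) expect_equal(sum(default_nodule_volumes(seed = s) < 50), 4)
})

test_that("rasterized occupancy integrates to the analytic volume", {
  vox <- 0.98^3
  sp <- nodule_spec("a", c(10, 10, 10), 4 / 3 * pi * 27, shape = "sphere")
  occ <- rasterize_nodule(sp, c(24, 24, 24), rep(0.98, 3), supersample = 4)
  expect_true(all(occ >= 0 & occ <= 1))
  expect_lt(abs(sum(occ) * vox / 113.097 - 1), 0.005)

  # hemisphere of the same radius carries half the occupancy
  hem <- nodule_spec("h", c(10, 10, 10.2), 100, "hemisphere")
  sph <- nodule_spec("s", c(10, 10, 10.2), 200, "sphere")
  o_h <- rasterize_nodule(hem, c(32, 32, 32), rep(0.7, 3), 4)
  o_s <- rasterize_nodule(sph, c(32, 32, 32), rep(0.7, 3), 4)
  expect_lt(abs(sum(o_h) / sum(o_s) - 0.5), 0.0025)

  # sub-voxel sphere: occupancy concentrated in one voxel
  v_tiny <- 4 / 3 * pi * 0.098^3
  tiny <- nodule_spec("t", c(9.8, 9.8, 9.8), v_tiny, "sphere")
  o_t <- rasterize_nodule(tiny, c(24, 24, 24), rep(0.98, 3), supersample = 64)
  expect_equal(sum(o_t > 0), 1)
  expect_lt(abs(sum(o_t) * 0.98^3 / v_tiny - 1), 0.03)

  expect_error(
    rasterize_nodule(nodule_spec("e", c(1, 10, 10), 500, "sphere"),
                     c(24, 24, 24), rep(0.98, 3)),
    "outside grid"
  )
})

test_that("composition is deterministic and degradation-free limits hold", {
  ph <- binary_phantom(volume = 150, signal = 100)
  vals <- unique(as.vector(ph$image$intensities))
  expect_setequal(vals, c(0, 100))
  expect_equal(nrow(ph$truth), 1)
  expect_equal(ph$truth$volume_mm3, 150)

  ctr <- (c(48, 48, 48) - 1) / 2 * 0.98
  spec <- phantom_spec(c(48, 48, 48), rep(0.98, 3),
                       list(nodule_spec("n", ctr, 150, "hemisphere")),
                       nodule_signal = 100, background_mean = 20,
                       background_texture_sd = 5, blur_fwhm = 1.2,
                       noise_model = "rician", noise_sd = 6, seed = 77L)
  a <- compose_phantom(spec)
  b <- compose_phantom(spec)
  expect_identical(a$image$intensities, b$image$intensities)

  # noise-free, blur-free image is affine in occupancy
  occ <- rasterize_nodule(nodule_spec("n", ctr, 150, "hemisphere"),
                          c(48, 48, 48), rep(0.98, 3), 4)
  spec0 <- phantom_spec(c(48, 48, 48), rep(0.98, 3),
                        list(nodule_spec("n", ctr, 150, "hemisphere")),
                        nodule_signal = 100, background_mean = 30,
                        background_texture_sd = 0, blur_fwhm = 0,
                        noise_sd = 0, seed = 1L)
  img0 <- compose_phantom(spec0)$image$intensities
  expect_equal(img0, 70 * occ + 30, tolerance = 1e-12)
})

test_that("blur strictly lowers the peak of a finite nodule", {
  ctr <- (c(48, 48, 48) - 1) / 2 * 0.98
  peaks <- vapply(c(0, 1.2, 2.4, 3.6), function(fw) {
    spec <- phantom_spec(c(48, 48, 48), rep(0.98, 3),
                         list(nodule_spec("n", ctr, 40, "hemisphere")),
                         nodule_signal = 100, background_mean = 0,
                         background_texture_sd = 0, blur_fwhm = fw,
                         noise_sd = 0, seed = 1L)
    max(compose_phantom(spec)$image$intensities)
  }, 0)
  expect_true(all(diff(peaks) < -1e-6))
})

test_that("multi-nodule phantoms keep nodules disjoint with one truth row each", {
  spacing <- rep(0.98, 3)
  centres <- list(c(12, 12, 12), c(35, 12, 12), c(23, 35, 12))
  nds <- lapply(seq_along(centres), function(i) {
    nodule_spec(paste0("n", i), centres[[i]], 60, "hemisphere")
  })
  spec <- phantom_spec(c(48, 48, 48), spacing, nds, nodule_signal = 100,
                       blur_fwhm = 0, noise_sd = 0, seed = 5L)
  ph <- compose_phantom(spec)
  expect_equal(nrow(ph$truth), 3)
  expect_identical(ph$truth$id, c("n1", "n2", "n3"))
  occs <- lapply(nds, rasterize_nodule, grid_shape = c(48, 48, 48),
                 spacing = spacing, supersample = 4L)
  expect_equal(max(occs[[1]] * occs[[2]] + occs[[1]] * occs[[3]] +
                     occs[[2]] * occs[[3]]), 0)
  # composed image is the superposition of the individual occupancies
  expect_equal(ph$image$intensities,
               100 * (occs[[1]] + occs[[2]] + occs[[3]]), tolerance = 1e-12)
})

test_that("phantom images and ground truth round-trip through disk", {
  ph <- binary_phantom(volume = 90, grid = c(24, 24, 24))
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir, "case1")
  img <- read_volume(paths[["image"]])
  expect_equal(img$spacing, ph$image$spacing, tolerance = 1e-6)
  expect_equal(img$intensities, ph$image$intensities, tolerance = 1e-6,
               ignore_attr = TRUE)
  tr <- utils::read.csv(paths[["truth"]])
  expect_equal(tr$volume_mm3, 90)
})

test_that("phantom spec invariants are enforced", {
  nd <- list(nodule_spec("x", c(5, 5, 5), 50))
  expect_error(phantom_spec(c(16, 16, 16), c(1, -1, 1), nd, 100), "positive")
  expect_error(phantom_spec(c(16, 16, 16), rep(1, 3), nd, 100, blur_fwhm = -1), ">= 0")
  expect_error(phantom_spec(c(16, 16, 16), rep(1, 3), nd, 100, noise_sd = -1), ">= 0")
  expect_error(phantom_spec(c(16, 16, 16), rep(1, 3), nd,
                            nodule_signal = 10, background_mean = 20),
               "exceed")
  expect_error(nodule_spec("x", c(5, 5, 5), -3), "positive")
})
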