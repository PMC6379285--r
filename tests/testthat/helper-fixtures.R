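# Fixtures and independent oracles used across the suite. Oracles are
# deliberately written along a different code path than the implementation
# (row-wise data frames and explicit sums instead of array algebra).

# a random test image with its own geometry
random_image <- function(dims, spacing = rep(1, 3), origin = c(0, 0, 0),
                         intensities = NULL) {
  arr <- if (is.null(intensities)) {
    array(runif(prod(dims), 0, 1000), dim = dims)
  } else {
    intensities
  }
  volumetric_image(arr, spacing = spacing, origin = origin)
}

# exhaustive per-voxel SIT oracle: enumerate every voxel as a data-frame
# row, apply the ROI distance test and the threshold rule literally
brute_sit_mask <- function(image, roi, c_frac) {
  d <- dim(image$intensities)
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  wx <- image$origin[1] + (g$i - 1) * image$spacing[1]
  wy <- image$origin[2] + (g$j - 1) * image$spacing[2]
  wz <- image$origin[3] + (g$k - 1) * image$spacing[3]
  in_roi <- (wx - roi$center[1])^2 + (wy - roi$center[2])^2 +
    (wz - roi$center[3])^2 <= roi$radius^2
  vals <- image$intensities[cbind(g$i, g$j, g$k)]
  i_min <- min(vals[in_roi]); i_max <- max(vals[in_roi])
  bound <- c_frac * (i_max - i_min) + i_min
  sel <- in_roi & vals >= bound & vals <= i_max
  out <- array(FALSE, dim = d)
  out[cbind(g$i, g$j, g$k)[sel, , drop = FALSE]] <- TRUE
  out
}

# a random ROI guaranteed to sit inside the image extent and to contain at
# least one voxel centre (anchored near a voxel centre)
random_roi <- function(image) {
  d <- dim(image$intensities)
  ext_lo <- image$origin - image$spacing / 2
  ext_hi <- image$origin + (d - 0.5) * image$spacing
  mid_vox <- round((d + 1) / 2)
  ctr <- image$origin + (mid_vox - 1) * image$spacing +
    runif(3, -0.1, 0.1) * min(image$spacing)
  max_r <- min(pmin(ctr - ext_lo, ext_hi - ctr))
  spherical_roi(ctr, runif(1, 0.4, 0.95) * max_r)
}

# independent moment oracles for the agreement statistics
oracle_lin_ccc <- function(x, y) {
  n <- length(x)
  sx2 <- sum(x^2) / n - (sum(x) / n)^2
  sy2 <- sum(y^2) / n - (sum(y) / n)^2
  sxy <- sum(x * y) / n - sum(x) * sum(y) / n^2
  rho_c <- 2 * sxy / (sx2 + sy2 + (sum(x) / n - sum(y) / n)^2)
  rho <- sxy / sqrt(sx2 * sy2)
  list(rho = rho, c_b = rho_c / rho, rho_c = rho_c)
}

oracle_rma <- function(x, y) {
  n <- length(x)
  sx2 <- sum(x^2) / n - (sum(x) / n)^2
  sy2 <- sum(y^2) / n - (sum(y) / n)^2
  sxy <- sum(x * y) / n - sum(x) * sum(y) / n^2
  slope <- sign(sxy) * sqrt(sy2 / sx2)
  list(slope = slope, intercept = sum(y) / n - slope * sum(x) / n)
}

oracle_bland_altman <- function(x, y) {
  d <- 100 * (y - x) / x
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  list(bias = m, sd = s, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

# noise-free binary phantom (supersample 1 -> occupancy in {0, 1}):
# intensities take exactly two values, 0 and `signal`
binary_phantom <- function(volume = 150, signal = 100, shape = "hemisphere",
                           grid = c(48, 48, 48), spacing = rep(0.98, 3)) {
  ctr <- (grid - 1) / 2 * spacing
  spec <- phantom_spec(grid, spacing,
                       list(nodule_spec("b", ctr, volume, shape)),
                       nodule_signal = signal, background_mean = 0,
                       background_texture_sd = 0, blur_fwhm = 0,
                       noise_sd = 0, seed = 1L)
  compose_phantom(spec, supersample = 1L)
}

# cases with a planted threshold optimum: blur-degraded noiseless nodules
# plus a hyperintense core voxel chosen so that the C = 0.30 lower bound
# falls exactly on the half-maximum edge iso-level (the volumetrically
# neutral level for a blurred step edge)
planted_cases <- function(volumes = c(80, 150, 300, 450), signal = 100,
                          grid = c(64, 64, 64), spacing = rep(0.98, 3),
                          c_star = 0.30) {
  lapply(volumes, function(v) {
    ctr <- (grid - 1) / 2 * spacing
    occ <- rasterize_nodule(nodule_spec("p", ctr, v, "sphere"),
                            grid, spacing, supersample = 4L)
    arr <- signal * gaussian_blur(occ, 1.2, spacing)
    hot <- round(ctr / spacing) + 1
    arr[hot[1], hot[2], hot[3]] <- (signal / 2) / c_star
    img <- volumetric_image(arr, spacing)
    r_eq <- (3 * v / (4 * pi))^(1 / 3)
    list(image = img, roi = spherical_roi(ctr, 2 * r_eq), volume_true = v)
  })
}
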