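#' Nodule specification for the digital phantom
#'
#' Describes one artificial nodule of exactly known volume. Hemispheres
#' emulate nodules moulded in a hemispherical reservoir and sit with their
#' flat face on the plane `z = center[3]`, dome towards +z; `center` is the
#' centre of the flat face (for spheres, the sphere centre).
#'
#' @param id Character label.
#' @param center Length-3 numeric, world mm.
#' @param volume_true True volume, mm^3 (> 0).
#' @param shape `"hemisphere"` (default) or `"sphere"`.
#' @return An object of class `nodule_spec`.
#' @export
nodule_spec <- function(id, center, volume_true, shape = c("hemisphere", "sphere")) {
  shape <- match.arg(shape)
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center))) {
    stop("`center` must be 3 finite values (mm)")
  }
  if (!is.numeric(volume_true) || length(volume_true) != 1L || volume_true <= 0) {
    stop("`volume_true` must be a single positive volume (mm^3)")
  }
  structure(
    list(id = as.character(id), center = center,
         volume_true = as.numeric(volume_true), shape = shape),
    class = "nodule_spec"
  )
}

# radius (mm) of the solid realising a nodule_spec volume
nodule_radius <- function(volume_true, shape) {
  switch(shape,
    sphere = (3 * volume_true / (4 * pi))^(1 / 3),
    hemisphere = (3 * volume_true / (2 * pi))^(1 / 3),
    stop("unknown shape: ", shape)
  )
}

#' Phantom specification
#'
#' Full recipe for one synthetic volume: grid geometry, nodules, intensity
#' model and degradation (partial-volume blur, textured background, modality
#' noise). `nodule_signal` is the absolute intensity of solid nodule
#' material (arbitrary units for the MRI arm, HU for the CT arm) and must
#' exceed `background_mean`.
#'
#' @param grid_shape Integer length-3, grid size in voxels.
#' @param spacing Numeric length-3, voxel spacing mm.
#' @param nodules List of [nodule_spec] objects.
#' @param nodule_signal Nodule plateau intensity.
#' @param background_mean Mean background intensity.
#' @param background_texture_sd Standard deviation of the correlated
#'   background texture (same units as intensity), measured after smoothing.
#' @param texture_corr_mm Correlation length (Gaussian sigma, mm) of the
#'   background texture.
#' @param blur_fwhm Point-spread blur FWHM, mm (>= 0).
#' @param noise_model `"rician"` (MRI magnitude) or `"gaussian"` (CT).
#' @param noise_sd Noise standard deviation (>= 0); `0` disables noise.
#' @param clip_floor Lower clip applied to the background field before
#'   composition (0 for magnitude MRI; about -1024 for CT HU).
#' @param seed Integer seed; fixed seed gives bit-identical phantoms.
#' @param origin World position of voxel (1,1,1), mm.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, spacing, nodules,
                         nodule_signal, background_mean = 0,
                         background_texture_sd = 0, texture_corr_mm = 3,
                         blur_fwhm = 0,
                         noise_model = c("rician", "gaussian"),
                         noise_sd = 0, clip_floor = 0,
                         seed = 1L, origin = c(0, 0, 0)) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  if (any(spacing <= 0)) stop("`spacing` must be positive componentwise")
  if (blur_fwhm < 0) stop("`blur_fwhm` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (background_texture_sd < 0) stop("`background_texture_sd` must be >= 0")
  if (!is.list(nodules) || !all(vapply(nodules, inherits, TRUE, "nodule_spec"))) {
    stop("`nodules` must be a list of nodule_spec objects")
  }
  if (nodule_signal <= background_mean) {
    stop("`nodule_signal` must exceed `background_mean`")
  }
  structure(
    list(grid_shape = grid_shape, spacing = spacing, nodules = nodules,
         nodule_signal = as.numeric(nodule_signal),
         background_mean = as.numeric(background_mean),
         background_texture_sd = as.numeric(background_texture_sd),
         texture_corr_mm = as.numeric(texture_corr_mm),
         blur_fwhm = as.numeric(blur_fwhm),
         noise_model = noise_model, noise_sd = as.numeric(noise_sd),
         clip_floor = as.numeric(clip_floor),
         seed = as.integer(seed), origin = as.numeric(origin)),
    class = "phantom_spec"
  )
}

#' Sample nodule volumes spanning a stated range
#'
#' Draws `n` volumes log-uniformly between `v_min` and `v_max` so that the
#' decades of the range are covered evenly. The two bounds are always
#' included (first two entries), so the printed range of the manufactured
#' set is spanned exactly.
#'
#' @param n Number of volumes (>= 1).
#' @param v_min,v_max Volume bounds, mm^3, `0 < v_min < v_max`.
#' @param seed Integer seed; draws are reproducible for a fixed seed.
#' @return Numeric vector of `n` volumes in `[v_min, v_max]`.
#' @export
#' @examples
#' v <- sample_nodule_volumes(22, 16, 561, seed = 1)
#' range(v)
sample_nodule_volumes <- function(n, v_min, v_max, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer")
  }
  if (v_min <= 0 || v_max <= 0) stop("volume bounds must be positive")
  if (v_min >= v_max) stop("`v_min` must be smaller than `v_max`")
  n <- as.integer(n)
  withr::with_seed(as.integer(seed), {
    head <- c(v_min, v_max)[seq_len(min(n, 2L))]
    rest <- if (n > 2L) exp(runif(n - 2L, log(v_min), log(v_max))) else numeric()
    c(head, rest)
  })
}

#' Default study volume set
#'
#' Volume draw matching the design of the emulated agar-nodule experiment:
#' `n` nodules between `v_min` and `v_max` mm^3 of which exactly `n_small`
#' fall below `small_cut` (the minimum-volume analysis filter). Each stratum
#' is log-uniform with its extreme endpoint forced (`v_min` in the small
#' stratum, `v_max` in the large one).
#'
#' @param n Total nodules manufactured (default 22).
#' @param n_small Nodules below `small_cut` (default 4).
#' @param v_min,v_max Overall volume range, mm^3 (defaults 16 and 561).
#' @param small_cut Volume filter boundary, mm^3 (default 50).
#' @param seed Integer seed.
#' @return Numeric vector of `n` volumes, small stratum first.
#' @export
default_nodule_volumes <- function(n = 22L, n_small = 4L, v_min = 16,
                                   v_max = 561, small_cut = 50, seed = 1L) {
  n <- as.integer(n); n_small <- as.integer(n_small)
  stopifnot(n >= 2L, n_small >= 1L, n - n_small >= 1L,
            v_min < small_cut, small_cut <= v_max)
  withr::with_seed(as.integer(seed), {
    small <- c(v_min,
               if (n_small > 1L) exp(runif(n_small - 1L, log(v_min), log(small_cut))))
    n_large <- n - n_small
    large <- c(v_max,
               if (n_large > 1L) exp(runif(n_large - 1L, log(small_cut), log(v_max))))
    # keep the small stratum strictly below and the large at/above the cut
    small <- pmin(small, small_cut * (1 - 1e-9))
    c(small, large)
  })
}

#' Rasterize a nodule to a per-voxel occupancy grid
#'
#' Computes, for every voxel, the fraction of the voxel lying inside the
#' analytic nodule shape by regular subvoxel sampling (`supersample`^3
#' points per voxel). The occupancy sum times the voxel volume converges to
#' the analytic volume as `supersample` grows; this is the digital analogue
#' of moulding a nodule of exactly known volume.
#'
#' @param spec A [nodule_spec].
#' @param grid_shape Integer length-3, voxels.
#' @param spacing Numeric length-3, mm.
#' @param supersample Subvoxel sampling factor per axis (>= 1).
#' @param origin World mm of voxel (1,1,1).
#' @return 3D array of inside-fractions in `[0, 1]`.
#' @export
#' @examples
#' sp <- nodule_spec("a", c(10, 10, 10), 113.097, shape = "sphere")
#' occ <- rasterize_nodule(sp, c(24, 24, 24), c(0.98, 0.98, 0.98), supersample = 4)
#' sum(occ) * 0.98^3 # close to 113.097
rasterize_nodule <- function(spec, grid_shape, spacing, supersample = 4L,
                             origin = c(0, 0, 0)) {
  stopifnot(inherits(spec, "nodule_spec"))
  supersample <- as.integer(supersample)
  if (supersample < 1L) stop("`supersample` must be >= 1")
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  r <- nodule_radius(spec$volume_true, spec$shape)
  ctr <- spec$center

  # physical bounds of the solid
  lo_mm <- ctr - c(r, r, if (spec$shape == "hemisphere") 0 else r)
  hi_mm <- ctr + r
  ext_lo <- origin - spacing / 2
  ext_hi <- origin + (grid_shape - 0.5) * spacing
  if (any(lo_mm < ext_lo) || any(hi_mm > ext_hi)) {
    stop("nodule extends outside grid (radius ", signif(r, 4), " mm at centre ",
         paste(signif(ctr, 4), collapse = ", "), ")")
  }

  occ <- array(0, dim = grid_shape)
  # voxel index range overlapping the solid
  lo_ix <- pmax(1L, floor((lo_mm - origin) / spacing - 0.5) + 1L)
  hi_ix <- pmin(grid_shape, ceiling((hi_mm - origin) / spacing + 0.5) + 1L)
  ix <- lapply(1:3, function(a) lo_ix[a]:hi_ix[a])
  cx <- origin[1] + (ix[[1]] - 1) * spacing[1]
  cy <- origin[2] + (ix[[2]] - 1) * spacing[2]
  cz <- origin[3] + (ix[[3]] - 1) * spacing[3]

  off <- ((seq_len(supersample) - 0.5) / supersample - 0.5)
  offs <- expand.grid(ox = off * spacing[1], oy = off * spacing[2],
                      oz = off * spacing[3])
  count <- array(0, dim = c(length(cx), length(cy), length(cz)))
  r2 <- r^2
  slab <- spacing[3] / supersample
  for (s in seq_len(nrow(offs))) {
    dx2 <- (cx + offs$ox[s] - ctr[1])^2
    dy2 <- (cy + offs$oy[s] - ctr[2])^2
    dz <- cz + offs$oz[s] - ctr[3]
    inside <- outer(outer(dx2, dy2, "+"), dz^2, "+") <= r2
    if (spec$shape == "hemisphere") {
      # antialias the flat face: weight each sub-sample by the fraction of
      # its z sub-slab lying above the cut plane, instead of a binary test
      # (a binary test quantizes the face position to 1/supersample of a
      # voxel and biases the volume)
      w <- pmin(1, pmax(0, 0.5 + dz / slab))
      w[w > 1 - 1e-9] <- 1 # snap float-noise slivers at the face
      w[w < 1e-9] <- 0
      count <- count + sweep(inside * 1, 3, w, "*")
    } else {
      count <- count + inside
    }
  }
  occ[ix[[1]], ix[[2]], ix[[3]]] <- count / nrow(offs)
  occ
}

#' Compose a degraded phantom image with its ground truth
#'
#' Builds `blur((nodule_signal - background_mean) * occupancy +
#' background_field) + noise`, where the background field is
#' `background_mean` plus correlated Gaussian texture (clipped at
#' `clip_floor`), the blur is Gaussian with the stated FWHM, and the noise
#' is Rician (magnitude MRI) or additive Gaussian (CT). Solid nodule
#' material therefore images at `nodule_signal` before degradation. A fixed
#' seed yields a bit-identical image.
#'
#' @param spec A [phantom_spec].
#' @param supersample Rasterization supersampling factor.
#' @return List with elements `image` (a [volumetric_image]) and `truth`
#'   (a tibble with columns id, volume_mm3, cx_mm, cy_mm, cz_mm, shape,
#'   seed — one row per nodule).
#' @export
compose_phantom <- function(spec, supersample = 4L) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  occ <- array(0, dim = d)
  for (nd in spec$nodules) {
    occ <- occ + rasterize_nodule(nd, d, spec$spacing, supersample,
                                  spec$origin)
  }
  occ <- pmin(occ, 1)

  img <- withr::with_seed(spec$seed, {
    bg <- array(spec$background_mean, dim = d)
    if (spec$background_texture_sd > 0) {
      tex <- array(rnorm(prod(d)), dim = d)
      tex <- gaussian_blur(tex, spec$texture_corr_mm * 2 * sqrt(2 * log(2)),
                           spec$spacing)
      tex <- tex * (spec$background_texture_sd / sd(tex))
      bg <- bg + tex
    }
    bg <- pmax(bg, spec$clip_floor)
    field <- (spec$nodule_signal - spec$background_mean) * occ + bg
    field <- gaussian_blur(field, spec$blur_fwhm, spec$spacing)
    if (spec$noise_sd > 0) {
      if (spec$noise_model == "rician") {
        n1 <- array(rnorm(prod(d), sd = spec$noise_sd), dim = d)
        n2 <- array(rnorm(prod(d), sd = spec$noise_sd), dim = d)
        field <- sqrt((field + n1)^2 + n2^2)
      } else {
        field <- field + array(rnorm(prod(d), sd = spec$noise_sd), dim = d)
      }
    }
    field
  })

  truth <- tibble::tibble(
    id = vapply(spec$nodules, `[[`, "", "id"),
    volume_mm3 = vapply(spec$nodules, `[[`, 0, "volume_true"),
    cx_mm = vapply(spec$nodules, function(n) n$center[1], 0),
    cy_mm = vapply(spec$nodules, function(n) n$center[2], 0),
    cz_mm = vapply(spec$nodules, function(n) n$center[3], 0),
    shape = vapply(spec$nodules, `[[`, "", "shape"),
    seed = spec$seed
  )
  list(
    image = volumetric_image(img, spec$spacing, spec$origin),
    truth = truth
  )
}

#' Write a phantom image and its ground-truth table to disk
#'
#' The image goes to `<dir>/<name>.nii.gz` (NIfTI-1, spacing and origin in
#' the affine) and the truth table to `<dir>/<name>_truth.csv`.
#'
#' @param phantom Result of [compose_phantom()].
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, name = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(name, ".nii.gz"))
  csv_path <- file.path(dir, paste0(name, "_truth.csv"))
  write_volume(phantom$image, img_path)
  utils::write.csv(phantom$truth, csv_path, row.names = FALSE)
  invisible(c(image = img_path, truth = csv_path))
}
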