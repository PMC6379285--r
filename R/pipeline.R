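#' Phantom study configuration
#'
#' Collects every tunable of the end-to-end phantom experiment with
#' defaults matching the emulated agar-nodule study design: 22 hemispheres
#' between 16 and 561 mm^3 (4 below the 50 mm^3 analysis filter), an
#' MRI-like arm at (0.98 mm)^3 in 96^3 per-nodule subgrids, a CT-like arm
#' at anisotropic 0.7 x 0.7 x 1.25 mm, threshold grid {0.20, 0.30, 0.40,
#' 0.50}, ROI radius twice the sphere-equivalent radius of the true volume.
#'
#' @param n_nodules Nodules manufactured.
#' @param n_small Nodules below `min_volume`.
#' @param volume_range Length-2, overall volume range mm^3.
#' @param min_volume Analysis filter boundary, mm^3.
#' @param shape Nodule shape, `"hemisphere"` or `"sphere"`.
#' @param mri,ct Named lists of [phantom_spec] parameters for each arm
#'   (grid_shape, spacing, nodule_signal, background_mean,
#'   background_texture_sd, texture_corr_mm, blur_fwhm, noise_model,
#'   noise_sd, clip_floor). Entries given here override the defaults.
#' @param roi_margin_factor ROI radius as a multiple of the nodule's
#'   sphere-equivalent radius.
#' @param c_grid SIT thresholds compared during calibration.
#' @param hu_cut CT surrogate attenuation cut, HU.
#' @param default_c Threshold used downstream when no calibration is run.
#' @param supersample Rasterization supersampling factor.
#' @param seed Master seed; all per-nodule seeds derive from it.
#' @param volumes Optional explicit volume vector overriding the stratified
#'   draw.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(n_nodules = 22L, n_small = 4L,
                              volume_range = c(16, 561), min_volume = 50,
                              shape = "hemisphere",
                              mri = list(), ct = list(),
                              roi_margin_factor = 2, c_grid = c(0.20, 0.30, 0.40, 0.50),
                              hu_cut = -400, default_c = 0.30,
                              supersample = 4L, seed = 1L, volumes = NULL) {
  mri_defaults <- list(
    grid_shape = c(96L, 96L, 96L), spacing = c(0.98, 0.98, 0.98),
    nodule_signal = 100, background_mean = 20, background_texture_sd = 5,
    texture_corr_mm = 3, blur_fwhm = 1.2, noise_model = "rician",
    noise_sd = 6, clip_floor = 0
  )
  ct_defaults <- list(
    grid_shape = c(128L, 128L, 76L), spacing = c(0.7, 0.7, 1.25),
    nodule_signal = 20, background_mean = -1000, background_texture_sd = 30,
    texture_corr_mm = 3, blur_fwhm = 1.5, noise_model = "gaussian",
    noise_sd = 20, clip_floor = -1024
  )
  mri <- utils::modifyList(mri_defaults, mri)
  ct <- utils::modifyList(ct_defaults, ct)
  stopifnot(length(volume_range) == 2L, volume_range[1] > 0,
            volume_range[1] < volume_range[2],
            roi_margin_factor > 1, all(c_grid >= 0 & c_grid <= 1))
  structure(
    list(n_nodules = as.integer(n_nodules), n_small = as.integer(n_small),
         volume_range = as.numeric(volume_range),
         min_volume = as.numeric(min_volume), shape = shape,
         mri = mri, ct = ct,
         roi_margin_factor = as.numeric(roi_margin_factor),
         c_grid = sort(as.numeric(c_grid)), hu_cut = as.numeric(hu_cut),
         default_c = as.numeric(default_c),
         supersample = as.integer(supersample), seed = as.integer(seed),
         volumes = if (!is.null(volumes)) as.numeric(volumes)),
    class = "experiment_config"
  )
}

#' Write / read an experiment configuration (YAML)
#'
#' The YAML mirror round-trips the configuration losslessly.
#'
#' @param config An [experiment_config].
#' @param path YAML file path.
#' @return `path` invisibly (write); the configuration (read).
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

# phantom_spec for one nodule centred in its own subgrid
single_nodule_spec <- function(id, volume, shape, arm, supersample, seed) {
  centre <- (arm$grid_shape - 1) / 2 * arm$spacing
  nd <- nodule_spec(id, centre, volume, shape)
  phantom_spec(
    grid_shape = arm$grid_shape, spacing = arm$spacing, nodules = list(nd),
    nodule_signal = arm$nodule_signal, background_mean = arm$background_mean,
    background_texture_sd = arm$background_texture_sd,
    texture_corr_mm = arm$texture_corr_mm, blur_fwhm = arm$blur_fwhm,
    noise_model = arm$noise_model, noise_sd = arm$noise_sd,
    clip_floor = arm$clip_floor, seed = seed
  )
}

#' Run the full phantom volumetry experiment
#'
#' End to end: generates per-nodule MRI-like and CT-like phantoms of
#' exactly known volume, applies the minimum-volume filter to the ground
#' truth, segments the MRI arm at every threshold in the grid and the CT
#' arm with the fixed-cut surrogate, measures volumes and diameters,
#' computes per-threshold concordance against truth (the calibration sweep)
#' and against CT, selects the threshold maximising Lin's `rho_c`, and runs
#' percent Bland-Altman agreement at the selected threshold. A fixed seed
#' yields an identical report.
#'
#' @param config An [experiment_config].
#' @param progress Emit per-nodule progress messages.
#' @return Object of class `study_report`; see Details. Key elements:
#'   `ground_truth`, `measurements` (long tibble), `concordance_truth`,
#'   `concordance_ct`, `selected_c`, `agreement`, `counts`, `provenance`.
#' @export
run_phantom_experiment <- function(config = experiment_config(),
                                   progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  n <- config$n_nodules
  vols <- config$volumes %||% default_nodule_volumes(
    n = n, n_small = config$n_small,
    v_min = config$volume_range[1], v_max = config$volume_range[2],
    small_cut = config$min_volume, seed = config$seed
  )
  if (length(vols) != n) stop("volume vector length does not match n_nodules")
  ids <- sprintf("N%02d", seq_len(n))
  c_grid <- config$c_grid
  mri_centre <- (config$mri$grid_shape - 1) / 2 * config$mri$spacing
  ct_centre <- (config$ct$grid_shape - 1) / 2 * config$ct$spacing

  ground_truth <- tibble::tibble(
    id = ids, volume_true = vols, shape = config$shape,
    cx_mm = mri_centre[1], cy_mm = mri_centre[2], cz_mm = mri_centre[3],
    analyzed = vols >= config$min_volume,
    seed_mri = config$seed * 10000L + seq_len(n),
    seed_ct = config$seed * 10000L + 5000L + seq_len(n)
  )
  flt <- filter_min_volume(data.frame(volume_true = vols),
                           config$min_volume)
  analyzed_idx <- which(ground_truth$analyzed)
  stopifnot(length(analyzed_idx) + flt$excluded == n)

  sit_vol <- matrix(NA_real_, length(analyzed_idx), length(c_grid),
                    dimnames = list(ids[analyzed_idx], paste0("c_", c_grid)))
  sit_avg <- sit_vol
  ct_vol <- rep(NA_real_, length(analyzed_idx))
  ct_avg <- ct_vol

  for (a in seq_along(analyzed_idx)) {
    i <- analyzed_idx[a]
    if (progress) message("nodule ", ids[i], " (", signif(vols[i], 4), " mm^3)")
    r_eq <- (3 * vols[i] / (4 * pi))^(1 / 3)
    r_roi <- config$roi_margin_factor * r_eq

    mri <- compose_phantom(
      single_nodule_spec(ids[i], vols[i], config$shape, config$mri,
                         config$supersample, ground_truth$seed_mri[i]),
      supersample = config$supersample
    )
    roi <- spherical_roi(mri_centre, r_roi)
    for (j in seq_along(c_grid)) {
      mask <- segment_sit(mri$image, roi, c_grid[j])
      sit_vol[a, j] <- mask_volume(mask)
      sit_avg[a, j] <- if (any(mask$member)) average_diameter(mask) else 0
    }

    ct <- compose_phantom(
      single_nodule_spec(ids[i], vols[i], config$shape, config$ct,
                         config$supersample, ground_truth$seed_ct[i]),
      supersample = config$supersample
    )
    ct_mask <- segment_ct_surrogate(ct$image, spherical_roi(ct_centre, r_roi),
                                    config$hu_cut)
    ct_vol[a] <- mask_volume(ct_mask)
    ct_avg[a] <- if (any(ct_mask$member)) average_diameter(ct_mask) else 0
  }

  truth_a <- vols[analyzed_idx]
  concordance_truth <- concordance_by_c(truth_a, sit_vol, c_grid)
  concordance_ct <- concordance_by_c(ct_vol, sit_vol, c_grid)
  selected_c <- concordance_truth$c[which.max(concordance_truth$rho_c)]
  jsel <- match(selected_c, c_grid)

  measurements <- rbind(
    do.call(rbind, lapply(seq_along(c_grid), function(j) tibble::tibble(
      id = ids[analyzed_idx], method = "sit_mri", c = c_grid[j],
      volume_mm3 = sit_vol[, j],
      eq_diam_mm = equivalent_diameter(sit_vol[, j]),
      avg_diam_mm = sit_avg[, j]
    ))),
    tibble::tibble(
      id = ids[analyzed_idx], method = "ct_surrogate", c = NA_real_,
      volume_mm3 = ct_vol, eq_diam_mm = equivalent_diameter(ct_vol),
      avg_diam_mm = ct_avg
    )
  )

  agreement <- list(
    sit_vs_truth = list(
      concordance = unclass(lin_ccc(truth_a, sit_vol[, jsel])),
      rma = unclass(rma_fit(truth_a, sit_vol[, jsel])),
      bland_altman = unclass(bland_altman_percent(truth_a, sit_vol[, jsel]))
    ),
    sit_vs_ct = list(
      concordance = unclass(lin_ccc(ct_vol, sit_vol[, jsel])),
      rma = unclass(rma_fit(ct_vol, sit_vol[, jsel])),
      bland_altman = unclass(bland_altman_percent(ct_vol, sit_vol[, jsel]))
    )
  )

  structure(
    list(
      ground_truth = ground_truth,
      measurements = measurements,
      concordance_truth = concordance_truth,
      concordance_ct = concordance_ct,
      selected_c = selected_c,
      agreement = agreement,
      counts = list(manufactured = n, excluded = flt$excluded,
                    analyzed = length(analyzed_idx)),
      provenance = list(
        seed = config$seed,
        config_hash = rlang::hash(unclass(config)),
        package_version = as.character(packageVersion("sitvolumetry"))
      )
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    "<study_report> %d nodules manufactured, %d excluded (< min volume), %d analyzed\n",
    x$counts$manufactured, x$counts$excluded, x$counts$analyzed
  ))
  cat(sprintf("  selected C = %.2f\n", x$selected_c))
  ba <- x$agreement$sit_vs_truth$bland_altman
  cat(sprintf("  SIT vs truth: bias %.2f%%, LoA [%.2f%%, %.2f%%], rho_c %.4f\n",
              ba$bias, ba$loa_low, ba$loa_high,
              x$agreement$sit_vs_truth$concordance$rho_c))
  invisible(x)
}

#' Serialise a study report to JSON
#'
#' Full-precision, deterministic JSON: the same report serialises to the
#' same bytes.
#'
#' @param report A `study_report`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Measure a single nodule on one image
#'
#' Applies SIT segmentation at a given threshold (default 0.30, the
#' calibrated value) to one case, and reports volume and diameters; when a
#' reference volume is supplied, the percent difference against it is
#' reported both raw and rounded half-away-from-zero to an integer percent.
#'
#' @param image A [volumetric_image] or a path to a NIfTI file.
#' @param center,radius ROI sphere centre (mm) and radius (mm); or pass
#'   `roi` directly.
#' @param roi Optional [spherical_roi] (overrides `center`/`radius`).
#' @param c SIT threshold fraction.
#' @param reference_volume Optional reference volume, mm^3.
#' @param keep_largest Passed to [segment_sit()].
#' @return Object of class `nodule_measurement`: list with `method`,
#'   `volume_mm3`, `eq_diam_mm`, `avg_diam_mm`, and (when a reference is
#'   given) `reference_mm3`, `percent_difference_raw`,
#'   `percent_difference`.
#' @export
run_single_case <- function(image, center = NULL, radius = NULL, roi = NULL,
                            c = 0.30, reference_volume = NULL,
                            keep_largest = FALSE) {
  if (is.character(image)) image <- read_volume(image)
  roi <- roi %||% spherical_roi(center, radius)
  mask <- segment_sit(image, roi, c, keep_largest = keep_largest)
  vol <- mask_volume(mask)
  out <- list(
    method = "sit_mri", c = c, volume_mm3 = vol,
    eq_diam_mm = equivalent_diameter(vol),
    avg_diam_mm = if (any(mask$member)) average_diameter(mask) else 0
  )
  if (!is.null(reference_volume)) {
    pd <- percent_difference(vol, reference_volume)
    out$reference_mm3 <- reference_volume
    out$percent_difference_raw <- pd
    out$percent_difference <- round_half_away(pd)
  }
  structure(out, class = "nodule_measurement")
}

#' @export
print.nodule_measurement <- function(x, ...) {
  cat(sprintf(
    "<nodule_measurement> %s (C = %.2f): %.1f mm^3, eq diam %.1f mm, avg diam %.1f mm\n",
    x$method, x$c, x$volume_mm3, x$eq_diam_mm, x$avg_diam_mm
  ))
  if (!is.null(x$percent_difference)) {
    cat(sprintf("  vs reference %.1f mm^3: %+d%% (raw %+.2f%%)\n",
                x$reference_mm3, as.integer(x$percent_difference),
                x$percent_difference_raw))
  }
  invisible(x)
}
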