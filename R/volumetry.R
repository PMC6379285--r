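#' Mask volume
#'
#' Voxel-count volumetry: number of member voxels times the voxel volume
#' `spacing[1] * spacing[2] * spacing[3]`.
#'
#' @param mask A [nodule_mask], or a logical 3D array (then `spacing` is
#'   required).
#' @param spacing Voxel spacing in mm; taken from the mask object when
#'   omitted.
#' @return Volume in mm^3.
#' @export
#' @examples
#' mask_volume(array(TRUE, c(10, 10, 10)), spacing = c(0.98, 0.98, 0.98))
mask_volume <- function(mask, spacing = NULL) {
  if (inherits(mask, "nodule_mask")) {
    spacing <- spacing %||% mask$spacing
    member <- mask$member
  } else {
    if (is.null(spacing)) stop("`spacing` is required for a bare array mask")
    member <- mask
  }
  sum(member) * prod(as.numeric(spacing))
}

#' Sphere-equivalent diameter of a volume
#'
#' Diameter of the sphere of equal volume, `(6 V / pi)^(1/3)`. This is the
#' unambiguous volume-derived size, distinct from the caliper-style
#' [average_diameter()].
#'
#' @param volume Volume in mm^3 (>= 0).
#' @return Diameter in mm.
#' @export
#' @examples
#' equivalent_diameter(113.097) # ~6 mm
equivalent_diameter <- function(volume) {
  if (any(volume < 0)) stop("`volume` must be non-negative")
  (6 * volume / pi)^(1 / 3)
}

#' Average diameter (long/short axis mean) of a mask
#'
#' Caliper-style size on the in-plane slice of maximal area (axial by
#' default): the long axis is the maximal Feret diameter of the slice, the
#' short axis the maximal extent perpendicular to it, and the result is
#' their mean — the convention under which the mean of long and short axes
#' reflects three-dimensional tumour volume. Each axis is measured between
#' voxel centres plus one mean in-plane voxel width, so a single-voxel mask
#' measures the mean in-plane spacing.
#'
#' @param mask A [nodule_mask] or logical 3D array.
#' @param spacing Voxel spacing mm (taken from the mask object if omitted).
#' @param plane Axis index normal to the measurement plane (3 = axial).
#' @return Average diameter in mm.
#' @export
average_diameter <- function(mask, spacing = NULL, plane = 3L) {
  if (inherits(mask, "nodule_mask")) {
    spacing <- spacing %||% mask$spacing
    member <- mask$member
  } else {
    if (is.null(spacing)) stop("`spacing` is required for a bare array mask")
    member <- mask
  }
  spacing <- as.numeric(spacing)
  if (!any(member)) stop("cannot measure an empty mask")
  plane <- as.integer(plane)
  stopifnot(plane %in% 1:3)

  counts <- apply(member, plane, sum)
  k <- which.max(counts)
  in_axes <- setdiff(1:3, plane)
  slice <- switch(plane,
                  member[k, , ], member[, k, ], member[, , k])
  pts <- which(slice, arr.ind = TRUE)
  xy <- cbind(pts[, 1] * spacing[in_axes[1]], pts[, 2] * spacing[in_axes[2]])
  pad <- mean(spacing[in_axes])
  if (nrow(xy) == 1L) return(pad)

  dmat <- as.matrix(stats::dist(xy))
  long <- max(dmat)
  pair <- which(dmat == long, arr.ind = TRUE)[1, ]
  u <- xy[pair[2], ] - xy[pair[1], ]
  u <- u / sqrt(sum(u^2))
  v <- c(-u[2], u[1])
  proj <- xy %*% v
  short <- max(proj) - min(proj)
  ((long + pad) + (short + pad)) / 2
}

#' Percent difference between two volumes
#'
#' `100 * (v_test - v_ref) / v_ref`. The raw value is returned; reporting
#' layers round it half-away-from-zero to an integer percent (see
#' [run_single_case()]).
#'
#' @param v_test Measured volume, mm^3.
#' @param v_ref Reference volume, mm^3 (> 0).
#' @return Percent difference (signed, unrounded).
#' @export
#' @examples
#' percent_difference(121, 110) # 10
percent_difference <- function(v_test, v_ref) {
  if (any(v_ref <= 0)) stop("`v_ref` must be strictly positive")
  100 * (v_test - v_ref) / v_ref
}

#' Growth call between two scans
#'
#' A nodule is called growing when its volume increased by at least 25%
#' between baseline and follow-up (the screening criterion for
#' indeterminate nodules); the boundary value counts as growth.
#'
#' @param v_baseline Baseline volume, mm^3 (> 0).
#' @param v_followup Follow-up volume, mm^3 (> 0).
#' @param threshold_pct Growth threshold in percent (default 25).
#' @return Logical.
#' @export
#' @examples
#' assess_growth(100, 125) # TRUE
assess_growth <- function(v_baseline, v_followup, threshold_pct = 25) {
  if (any(v_baseline <= 0) || any(v_followup <= 0)) {
    stop("volumes must be strictly positive")
  }
  percent_difference(v_followup, v_baseline) >= threshold_pct
}

#' Volume doubling time
#'
#' `VDT = interval * log(2) / log(v_followup / v_baseline)` in days;
#' negative for shrinking nodules. A VDT below 400 days is the conventional
#' malignancy-suspicion cut-off. Equal volumes leave the doubling time
#' undefined and raise an error of class `sitvolumetry_vdt_undefined`.
#'
#' @inheritParams assess_growth
#' @param interval_days Scan interval in days (> 0).
#' @return Doubling time in days.
#' @export
#' @examples
#' volume_doubling_time(100, 200, 400) # 400
volume_doubling_time <- function(v_baseline, v_followup, interval_days) {
  if (any(v_baseline <= 0) || any(v_followup <= 0)) {
    stop("volumes must be strictly positive")
  }
  if (any(interval_days <= 0)) stop("`interval_days` must be strictly positive")
  if (any(v_followup == v_baseline)) {
    abort("volume unchanged: doubling time undefined",
          class = "sitvolumetry_vdt_undefined")
  }
  interval_days * log(2) / log(v_followup / v_baseline)
}

#' Minimum-volume analysis filter
#'
#' Drops nodules whose true volume falls below `min_volume` (default
#' 50 mm^3, the size under which doubling-time assessment is not required);
#' the boundary value is kept.
#'
#' @param records Data frame with a `volume_true` column (mm^3), one row per
#'   nodule.
#' @param min_volume Filter boundary, mm^3.
#' @return List with `records` (kept rows) and `excluded` (count dropped).
#' @export
#' @examples
#' filter_min_volume(data.frame(volume_true = c(16, 49, 50, 100)))
filter_min_volume <- function(records, min_volume = 50) {
  stopifnot(is.data.frame(records), "volume_true" %in% names(records))
  keep <- records$volume_true >= min_volume
  list(records = records[keep, , drop = FALSE], excluded = sum(!keep))
}
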