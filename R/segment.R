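#' Voxels inside a spherical ROI
#'
#' ROI membership uses the voxel-centre convention: a voxel belongs to the
#' ROI exactly when its centre (world mm) lies within `radius` of the ROI
#' centre. The sphere must lie fully inside the image extent.
#'
#' @param image A [volumetric_image].
#' @param roi A [spherical_roi].
#' @return Integer matrix (one row per voxel, columns i, j, k; 1-based array
#'   indices) of the ROI voxels, in array order.
#' @seealso [roi_extremes()], [segment_sit()]
#' @export
roi_voxels <- function(image, roi) {
  m <- roi_mask(image, roi)
  which(m, arr.ind = TRUE)
}

# logical ROI membership grid; validates that the sphere is inside the image
roi_mask <- function(image, roi) {
  stopifnot(inherits(image, "volumetric_image"), inherits(roi, "spherical_roi"))
  ext <- image_extent(image)
  lo_viol <- roi$center - roi$radius < ext$lo
  hi_viol <- roi$center + roi$radius > ext$hi
  if (any(lo_viol) || any(hi_viol)) {
    ax <- c("x", "y", "z")[which(lo_viol | hi_viol)[1]]
    stop("ROI extends outside the image along ", ax,
         ": sphere [", paste(signif(roi$center - roi$radius, 5), collapse = ", "),
         "] .. [", paste(signif(roi$center + roi$radius, 5), collapse = ", "),
         "] vs extent [", paste(signif(ext$lo, 5), collapse = ", "),
         "] .. [", paste(signif(ext$hi, 5), collapse = ", "), "] mm")
  }
  d <- dim(image$intensities)
  dx2 <- (image$origin[1] + (seq_len(d[1]) - 1) * image$spacing[1] - roi$center[1])^2
  dy2 <- (image$origin[2] + (seq_len(d[2]) - 1) * image$spacing[2] - roi$center[2])^2
  dz2 <- (image$origin[3] + (seq_len(d[3]) - 1) * image$spacing[3] - roi$center[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= roi$radius^2
}

#' Intensity extremes inside an ROI
#'
#' Records the exact minimum and maximum voxel intensity over the ROI,
#' the two anchors of the signal-intensity-threshold rule.
#'
#' @inheritParams roi_voxels
#' @return List with elements `i_min` and `i_max`.
#' @export
roi_extremes <- function(image, roi) {
  m <- roi_mask(image, roi)
  if (!any(m)) stop("ROI contains no voxel centres")
  vals <- image$intensities[m]
  list(i_min = min(vals), i_max = max(vals))
}

#' Lower intensity bound of the SIT rule
#'
#' For ROI extremes `I_min`, `I_max` and threshold fraction `C`, the lower
#' inclusion bound is `C * (I_max - I_min) + I_min`. At `C = 0` every ROI
#' voxel qualifies; raising `C` discards progressively lower-intensity
#' voxels.
#'
#' @param extremes List with `i_min` and `i_max` (see [roi_extremes()]).
#' @param c Threshold fraction in `[0, 1]`.
#' @return The lower intensity bound (scalar).
#' @export
#' @examples
#' sit_lower_bound(list(i_min = 0, i_max = 1000), 0.30) # 300
sit_lower_bound <- function(extremes, c) {
  if (!is.numeric(c) || length(c) != 1L || c < 0 || c > 1) {
    stop("`c` must be a single fraction in [0, 1]")
  }
  if (extremes$i_min > extremes$i_max) stop("invalid extremes: i_min > i_max")
  c * (extremes$i_max - extremes$i_min) + extremes$i_min
}

#' Signal-intensity-threshold (SIT) segmentation
#'
#' Inside a spherical ROI, all voxels with intensity between
#' `C * (I_max - I_min) + I_min` and `I_max` (both bounds inclusive) are
#' considered part of the nodule, where `I_min`/`I_max` are the raw ROI
#' intensity extremes. Optionally the mask is reduced to its largest
#' 26-connected component (off by default; the plain threshold rule is the
#' reference behaviour).
#'
#' An empty result is legal (e.g. `C = 1` on a flat ROI) and is returned
#' with a warning rather than an error.
#'
#' @inheritParams roi_voxels
#' @param c Threshold fraction in `[0, 1]`.
#' @param keep_largest If `TRUE`, keep only the largest 26-connected
#'   component (ties broken towards the component whose first voxel comes
#'   earliest in lexicographic (i, j, k) order).
#' @return A [nodule_mask].
#' @export
segment_sit <- function(image, roi, c = 0.30, keep_largest = FALSE) {
  m <- roi_mask(image, roi)
  if (!any(m)) stop("ROI contains no voxel centres")
  vals <- image$intensities[m]
  bound <- sit_lower_bound(list(i_min = min(vals), i_max = max(vals)), c)
  member <- m & (image$intensities >= bound)
  if (keep_largest) member <- keep_largest_component(member)
  if (!any(member)) {
    warning("SIT segmentation produced an empty mask (c = ", c, ")")
  }
  nodule_mask(member, image$spacing, image$origin)
}

#' Fixed-threshold CT segmentation surrogate
#'
#' Stand-in for an automatic CT lung-lesion tool: ROI voxels at or above a
#' fixed attenuation cut (default -400 HU), reduced to the largest
#' 26-connected component.
#'
#' @inheritParams roi_voxels
#' @param hu_cut Attenuation threshold in HU-like units.
#' @return A [nodule_mask].
#' @export
segment_ct_surrogate <- function(image, roi, hu_cut = -400) {
  m <- roi_mask(image, roi)
  if (!any(m)) stop("ROI contains no voxel centres")
  member <- m & (image$intensities >= hu_cut)
  member <- keep_largest_component(member)
  if (!any(member)) {
    warning("CT surrogate segmentation produced an empty mask (cut = ",
            hu_cut, " HU)")
  }
  nodule_mask(member, image$spacing, image$origin)
}

#' Label 26-connected components of a 3D mask
#'
#' Breadth-first labelling under 26-connectivity (faces, edges and corners
#' adjacent). Labels are assigned in increasing order of each component's
#' first voxel in lexicographic (i, j, k) order.
#'
#' @param member Logical 3D array.
#' @return Integer array of the same shape; 0 outside the mask, component
#'   labels 1, 2, ... inside.
#' @export
label_components_26 <- function(member) {
  stopifnot(is.logical(member), length(dim(member)) == 3L)
  d <- dim(member)
  lab <- array(0L, dim = d)
  if (!any(member)) return(lab)

  nb <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]

  # seeds scanned in lexicographic (i, j, k) order
  vox <- which(member, arr.ind = TRUE)
  ord <- order(vox[, 1], vox[, 2], vox[, 3])
  seeds_lin <- (vox[ord, 3] - 1L) * d[1] * d[2] + (vox[ord, 2] - 1L) * d[1] + vox[ord, 1]

  nlab <- 0L
  for (s in seeds_lin) {
    if (lab[s] != 0L) next
    nlab <- nlab + 1L
    lab[s] <- nlab
    frontier <- s
    while (length(frontier)) {
      fi <- arrayInd(frontier, d)
      cand_i <- rep(fi[, 1], each = nrow(nb)) + nb[, 1]
      cand_j <- rep(fi[, 2], each = nrow(nb)) + nb[, 2]
      cand_k <- rep(fi[, 3], each = nrow(nb)) + nb[, 3]
      ok <- cand_i >= 1L & cand_i <= d[1] &
            cand_j >= 1L & cand_j <= d[2] &
            cand_k >= 1L & cand_k <= d[3]
      lin <- (cand_k[ok] - 1L) * d[1] * d[2] + (cand_j[ok] - 1L) * d[1] + cand_i[ok]
      lin <- unique(lin[member[lin] & lab[lin] == 0L])
      lab[lin] <- nlab
      frontier <- lin
    }
  }
  lab
}

# reduce a logical mask to its largest 26-connected component; ties go to
# the component seeded earliest in lexicographic order (lowest label)
keep_largest_component <- function(member) {
  if (!any(member)) return(member)
  lab <- label_components_26(member)
  sizes <- tabulate(lab[lab > 0L])
  member & (lab == which.max(sizes))
}
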