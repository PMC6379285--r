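#' Volumetric image container
#'
#' A `volumetric_image` is the common currency of all segmentation and
#' phantom operations: a 3D scalar intensity grid together with its voxel
#' spacing and world origin in millimetres. World coordinates follow the
#' voxel-centre convention: voxel `(i, j, k)` (1-based array indices) sits at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param intensities 3D numeric array of voxel intensities (finite).
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm
#'   (strictly positive).
#' @param origin Numeric length-3 vector, world position (mm) of the centre
#'   of voxel `(1, 1, 1)`.
#' @return An object of class `volumetric_image`.
#' @export
#' @examples
#' img <- volumetric_image(array(0, c(8, 8, 8)), spacing = c(0.98, 0.98, 0.98))
#' dim(img$intensities)
volumetric_image <- function(intensities, spacing, origin = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("`intensities` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive finite values (mm)")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite values (mm)")
  }
  if (any(!is.finite(intensities))) {
    stop("`intensities` must be finite everywhere")
  }
  structure(
    list(intensities = intensities, spacing = spacing, origin = origin),
    class = "volumetric_image"
  )
}

#' @export
print.volumetric_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<volumetric_image> %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf(
    "  origin (%.4g, %.4g, %.4g) mm, intensity range [%.4g, %.4g]\n",
    x$origin[1], x$origin[2], x$origin[3],
    min(x$intensities), max(x$intensities)
  ))
  invisible(x)
}

#' Spherical region of interest
#'
#' A sphere in world coordinates (mm) placed around one nodule so that it
#' contains the entire nodule plus a margin of background. The sphere must
#' lie fully inside the image extent of any image it is applied to.
#'
#' @param center Numeric length-3, sphere centre in world mm.
#' @param radius Positive scalar, sphere radius in mm.
#' @return An object of class `spherical_roi`.
#' @export
#' @examples
#' spherical_roi(center = c(25, 25, 25), radius = 8)
spherical_roi <- function(center, radius) {
  center <- as.numeric(center)
  radius <- as.numeric(radius)
  if (length(center) != 3L || any(!is.finite(center))) {
    stop("`center` must be 3 finite values (mm)")
  }
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0) {
    stop("`radius` must be a single positive value (mm)")
  }
  structure(list(center = center, radius = radius), class = "spherical_roi")
}

#' @export
print.spherical_roi <- function(x, ...) {
  cat(sprintf(
    "<spherical_roi> centre (%.4g, %.4g, %.4g) mm, radius %.4g mm\n",
    x$center[1], x$center[2], x$center[3], x$radius
  ))
  invisible(x)
}

#' Binary nodule mask
#'
#' Segmentation output: a logical 3D grid aligned to the source image
#' (same array shape, spacing and origin).
#'
#' @param member Logical 3D array, `TRUE` for voxels belonging to the nodule.
#' @param spacing,origin Geometry copied from the source image.
#' @return An object of class `nodule_mask`.
#' @export
nodule_mask <- function(member, spacing, origin = c(0, 0, 0)) {
  if (!is.array(member) || length(dim(member)) != 3L || !is.logical(member)) {
    stop("`member` must be a logical 3D array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (mm)")
  }
  structure(
    list(member = member, spacing = spacing, origin = as.numeric(origin)),
    class = "nodule_mask"
  )
}

#' @export
print.nodule_mask <- function(x, ...) {
  cat(sprintf(
    "<nodule_mask> %s voxels set of %s, voxel volume %.4g mm^3\n",
    format(sum(x$member)), format(length(x$member)), prod(x$spacing)
  ))
  invisible(x)
}

# World extent of an image: voxel volumes span half a voxel beyond the
# outermost voxel centres.
image_extent <- function(image) {
  d <- dim(image$intensities)
  lo <- image$origin - image$spacing / 2
  hi <- image$origin + (d - 0.5) * image$spacing
  list(lo = lo, hi = hi)
}

#' Read a NIfTI-1 volume
#'
#' Reads a scalar 3D NIfTI file into a [volumetric_image], taking the voxel
#' spacing from the header `pixdim` and the origin from the translation part
#' of the xform affine.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volumetric_image].
#' @export
read_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume: ", path)
  sp <- RNifti::pixdim(nii)[1:3]
  aff <- RNifti::xform(nii)
  volumetric_image(arr, spacing = sp, origin = aff[1:3, 4])
}

#' Write a volume or mask as NIfTI-1
#'
#' Spacing and origin are stored in the header affine (sform/qform code 2).
#' Masks are written as uint8.
#'
#' @param x A [volumetric_image] or [nodule_mask].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "nodule_mask")) {
    arr <- array(as.integer(x$member), dim = dim(x$member))
    datatype <- "uint8"
  } else if (inherits(x, "volumetric_image")) {
    arr <- x$intensities
    datatype <- "double"
  } else {
    stop("`x` must be a volumetric_image or nodule_mask")
  }
  aff <- diag(c(x$spacing, 1))
  aff[1:3, 4] <- x$origin
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- x$spacing
  RNifti::qform(nii) <- structure(aff, code = 2L)
  RNifti::sform(nii) <- structure(aff, code = 2L)
  RNifti::writeNifti(nii, path, datatype = datatype)
  invisible(path)
}

#' Gaussian blur of a 3D array (periodic, FFT-based)
#'
#' Isotropic Gaussian smoothing specified by its full width at half maximum
#' in millimetres, applied in the frequency domain with the closed-form
#' Gaussian transfer function. Boundary handling is periodic, adequate when
#' the structures of interest are away from the grid faces.
#'
#' @param x 3D numeric array.
#' @param fwhm_mm Full width at half maximum of the kernel, mm; `0` is a
#'   no-op.
#' @param spacing Voxel spacing, mm (length 3).
#' @return Blurred array of the same shape.
#' @export
gaussian_blur <- function(x, fwhm_mm, spacing) {
  stopifnot(is.array(x), length(dim(x)) == 3L, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(x)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(x)
  freq <- function(n, dd) {
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n
    k / (n * dd)
  }
  f2 <- lapply(1:3, function(a) freq(d[a], spacing[a])^2)
  h <- exp(-2 * pi^2 * sigma^2 *
             outer(outer(f2[[1]], f2[[2]], "+"), f2[[3]], "+"))
  Re(fft(fft(x) * h, inverse = TRUE)) / length(x)
}

# half-away-from-zero rounding used for reported integer percentages
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
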