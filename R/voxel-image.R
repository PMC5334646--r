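#' Isotropic voxel image
#'
#' The working representation of the pipeline: a 3D grayscale array with a
#' single physical pitch for all three axes and intensities in \[0, 1\].
#' Arrays are stored with `dim = c(ny, nx, nz)` so that `voxels[, , k]` is
#' image plane `k`; coordinate tables use 0-based `(x, y, z)` voxel
#' coordinates.
#'
#' @param voxels numeric 3D array with values in \[0, 1\].
#' @param pitch voxel pitch in micrometres (isotropic).
#' @param provenance one of `"raw"`, `"isotropic"`, `"downscaled"`,
#'   `"inverted"`.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(voxels, pitch,
                        provenance = c("raw", "isotropic", "downscaled",
                                       "inverted")) {
  provenance <- match.arg(provenance)
  stopifnot(length(dim(voxels)) == 3, pitch > 0)
  rng <- range(voxels)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("voxel intensities must lie in [0, 1]")
  }
  structure(list(voxels = voxels, pitch = pitch, provenance = provenance),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<voxel_image> %d x %d x %d (y,x,z), %.4g um/voxel, %s\n",
              d[1], d[2], d[3], x$pitch, x$provenance))
  invisible(x)
}

#' Labelled nuclei partition
#'
#' @param labels integer 3D array; 0 marks background and watershed lines,
#'   objects are labelled 1..n consecutively.
#' @param pitch voxel pitch in micrometres.
#' @return An object of class `label_image`.
#' @export
label_image <- function(labels, pitch) {
  stopifnot(length(dim(labels)) == 3, pitch > 0)
  n <- max(0L, max(labels))
  structure(list(labels = labels, n_objects = as.integer(n), pitch = pitch),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_image> %d x %d x %d (y,x,z), %d objects, %.4g um/voxel\n",
              d[1], d[2], d[3], x$n_objects, x$pitch))
  invisible(x)
}

#' Resample a raw stack to an isotropic, downscaled working image
#'
#' First rescales the plane (Z) axis by linear interpolation so voxels become
#' isotropic at the lateral pitch, then downscales all axes by
#' `image_scaling_factor` using local-mean (block-average) resampling, and
#' finally min-max normalizes intensities to \[0, 1\]. With the instrument
#' defaults (0.325 um lateral pitch, scaling 0.5) the result has isotropic
#' 0.65 um voxels.
#'
#' @param stack a [raw_stack()].
#' @param z_scaling_factor plane-axis upsampling ratio; defaults to
#'   `axial_pitch / lateral_pitch`.
#' @param image_scaling_factor overall downscaling factor in (0, 1\];
#'   `1 / image_scaling_factor` must be a whole number (block resampling).
#'
#' @return A [voxel_image()] with pitch `lateral_pitch / image_scaling_factor`.
#' @export
#' @examples
#' st <- raw_stack(array(runif(16 * 16 * 4, 0, 255), c(16, 16, 4)),
#'                 lateral_pitch = 0.325, axial_pitch = 1.29, bit_depth = 8)
#' img <- prepare_image(st)
#' img$pitch  # 0.65
prepare_image <- function(stack, z_scaling_factor = NULL,
                          image_scaling_factor = 0.5) {
  stopifnot(inherits(stack, "raw_stack"))
  if (is.null(z_scaling_factor)) {
    z_scaling_factor <- stack$axial_pitch / stack$lateral_pitch
  }
  if (z_scaling_factor <= 0) stop("z_scaling_factor must be positive")
  if (image_scaling_factor <= 0 || image_scaling_factor > 1) {
    stop("image_scaling_factor must be in (0, 1]")
  }
  arr <- stack$planes
  d <- dim(arr)
  if (abs(z_scaling_factor - 1) > 1e-12) {
    nz_out <- max(2L, as.integer(round((d[3] - 1) * z_scaling_factor)) + 1L)
    zpos <- seq(0, d[3] - 1, length.out = nz_out)
    arr <- interp_planes_cpp(as.numeric(arr), as.integer(d), zpos)
    d <- dim(arr)
  }
  if (abs(image_scaling_factor - 1) > 1e-12) {
    block <- 1 / image_scaling_factor
    if (abs(block - round(block)) > 1e-9) {
      stop("1 / image_scaling_factor must be a whole number")
    }
    arr <- block_mean_cpp(as.numeric(arr), as.integer(d), as.integer(round(block)))
  }
  rng <- range(arr)
  if (rng[2] > rng[1]) {
    arr <- (arr - rng[1]) / (rng[2] - rng[1])
  } else {
    arr <- array(0, dim(arr))
  }
  provenance <- if (image_scaling_factor != 1) "downscaled" else "isotropic"
  voxel_image(arr, pitch = stack$lateral_pitch / image_scaling_factor,
              provenance = provenance)
}

#' Invert a voxel image
#'
#' Maps every intensity v to 1 - v. Nuclei, bright in the prepared image,
#' become dark minima that the immersion watershed floods.
#'
#' @param image a [voxel_image()].
#' @return A [voxel_image()] with provenance `"inverted"`.
#' @export
invert <- function(image) {
  stopifnot(inherits(image, "voxel_image"))
  voxel_image(1 - image$voxels, pitch = image$pitch, provenance = "inverted")
}
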