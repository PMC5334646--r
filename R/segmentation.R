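# --- kernels ---------------------------------------------------------------

.gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# second derivative of a Gaussian, forced to zero sum so a constant image
# yields an exactly zero Laplacian response
.gaussian_d2_kernel <- function(sigma, radius = ceiling(3.5 * sigma)) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  k <- g * (x^2 - sigma^2) / sigma^4
  k - mean(k)
}

#' Otsu's global threshold
#'
#' Histogram-based maximization of between-class variance on 256 bins.
#' A constant image has no foreground/background split; by convention the
#' threshold is then `+Inf` (empty mask downstream) with a warning.
#'
#' @param values numeric vector or array of intensities in \[0, 1\].
#' @param n_bins histogram resolution.
#' @return Threshold on the intensity scale of `values`.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  v <- as.numeric(values)
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps) {
    warning("constant image: Otsu threshold undefined, returning +Inf")
    return(Inf)
  }
  h <- tabulate(pmin(n_bins, floor((v - lo) / (hi - lo) * n_bins) + 1L),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) / n_bins * (hi - lo)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_total <- mu0[n_bins]
  between <- (mu_total * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Binary foreground mask
#' @param voxels logical 3D array.
#' @param pitch voxel pitch in micrometres.
#' @export
binary_mask <- function(voxels, pitch) {
  stopifnot(is.logical(voxels), length(dim(voxels)) == 3, pitch > 0)
  structure(list(voxels = voxels, pitch = pitch), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %d x %d x %d, %d foreground voxels (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$voxels),
              100 * mean(x$voxels)))
  invisible(x)
}

.local_mean_planes <- function(arr, axis, window) {
  d <- dim(arr)
  box <- rep(1 / window, window)
  in_plane <- setdiff(1:3, axis)
  for (a in in_plane) {
    if (window > d[a]) {
      stop("local threshold window (", window,
           ") larger than image extent along axis ", a)
    }
  }
  k <- list(NULL, NULL, NULL)
  k[in_plane] <- list(box, box)
  separable_filter_cpp(as.numeric(arr), as.integer(d), k[[1]], k[[2]], k[[3]])
}

#' Initial nuclei segmentation by local adaptive thresholding
#'
#' Smooths the prepared image with a Gaussian, determines the global
#' background level by Otsu's method, then thresholds each sectional plane
#' along X, Y and Z with the local rule
#' `t_local = m_local + gamma * t_global` (local mean `m_local` over a
#' `NucleiThresholdRange` square window, mirror padding). The three binary
#' stacks are combined voxel-wise by AND, and enclosed background cavities
#' smaller than `hole_threshold` voxels are filled.
#'
#' @param image prepared (isotropic, downscaled) [voxel_image()].
#' @param config a [spheroid_config()].
#' @return A [binary_mask()].
#' @export
initial_segmentation <- function(image, config = spheroid_config()) {
  stopifnot(inherits(image, "voxel_image"))
  d <- dim(image$voxels)
  r <- config$NucleiFilterRange
  g <- .gaussian_kernel(r / 2, radius = r)
  smoothed <- separable_filter_cpp(as.numeric(image$voxels), as.integer(d),
                                   g, g, g)
  t_global <- otsu_threshold(smoothed)
  if (!is.finite(t_global)) {
    return(binary_mask(array(FALSE, d), image$pitch))
  }
  gamma <- config$NucleiBackgroundFactor
  w <- config$NucleiThresholdRange
  fg <- array(TRUE, d)
  for (axis in 3:1) {
    m_local <- .local_mean_planes(smoothed, axis, w)
    fg <- fg & (smoothed > m_local + gamma * t_global)
  }
  fg <- .fill_holes(fg, config$hole_threshold)
  binary_mask(fg, image$pitch)
}

# fill enclosed background cavities (6-connected complement components that
# do not touch the image border) smaller than `max_size` voxels
.fill_holes <- function(mask, max_size) {
  d <- dim(mask)
  comp <- label_components_cpp(as.vector(!mask), as.integer(d), 6L)
  n <- attr(comp, "n_objects")
  if (n == 0) return(mask)
  comp <- array(comp, d)
  sizes <- tabulate(comp[comp > 0], nbins = n)
  border <- unique(c(comp[c(1, d[1]), , ], comp[, c(1, d[2]), ],
                     comp[, , c(1, d[3])]))
  fill <- setdiff(which(sizes < max_size), border)
  if (length(fill) > 0) mask[comp %in% fill] <- TRUE
  mask
}

#' Multiscale scale-normalized Laplacian-of-Gaussian response
#'
#' Computes, for each voxel, the maximum over scales of the
#' sigma^3-normalized LoG response of the inverted image. Scales are spaced
#' uniformly in sigma over \[r_min/sqrt(2), r_max/sqrt(2)\]: for the
#' sigma^3-normalized LoG the centre response of a solid ball of radius R
#' peaks at sigma = R/sqrt(2). Bright nuclei (dark in the inverted image)
#' produce positive local maxima.
#'
#' @param inverted the inverted prepared image (see [invert()]).
#' @param config a [spheroid_config()].
#' @return Numeric array of the same shape with attribute `"sigmas"`.
#' @export
multiscale_log <- function(inverted, config = spheroid_config()) {
  stopifnot(inherits(inverted, "voxel_image"))
  r_min <- config$NucleiSeedDetectionMinRadius
  r_max <- config$NucleiSeedDetectionMaxRadius
  if (r_min > r_max) stop("NucleiSeedDetectionMinRadius > MaxRadius")
  sigmas <- seq(r_min, r_max, length.out = config$n_scales) / sqrt(2)
  d <- dim(inverted$voxels)
  f <- as.numeric(inverted$voxels)
  response <- NULL
  for (s in sigmas) {
    g <- .gaussian_kernel(s, radius = ceiling(3.5 * s))
    g2 <- .gaussian_d2_kernel(s, radius = ceiling(3.5 * s))
    log_s <- separable_filter_cpp(f, as.integer(d), g2, g, g) +
      separable_filter_cpp(f, as.integer(d), g, g2, g) +
      separable_filter_cpp(f, as.integer(d), g, g, g2)
    log_s <- s^3 * log_s
    response <- if (is.null(response)) log_s else
      pmax_inplace_cpp(response, log_s)
  }
  response <- array(response, d)
  attr(response, "sigmas") <- sigmas
  response
}

#' Marker image
#' @param voxels logical 3D array of marker voxels.
#' @param components integer array labelling the marker components.
#' @param n_components number of marker components.
#' @export
marker_image <- function(voxels, components, n_components) {
  structure(list(voxels = voxels, components = components,
                 component_count = as.integer(n_components)),
            class = "marker_image")
}

#' @export
print.marker_image <- function(x, ...) {
  cat(sprintf("<marker_image> %d marker components, %d voxels\n",
              x$component_count, sum(x$voxels)))
  invisible(x)
}

#' Detect watershed markers from the multiscale LoG response
#'
#' Extracts extended maxima of the response (regional maxima of the h-maxima
#' transform, h = `h_fraction` of the response dynamic range), discards
#' maxima outside the initial segmentation, merges near-adjacent maxima by
#' dilation with a digital ball of radius `NucleiSeedDilation`, and labels
#' the resulting connected components (26-connectivity) as markers.
#'
#' @param response array from [multiscale_log()].
#' @param mask a [binary_mask()] from [initial_segmentation()].
#' @param config a [spheroid_config()].
#' @return A [marker_image()].
#' @export
detect_markers <- function(response, mask, config = spheroid_config()) {
  stopifnot(inherits(mask, "binary_mask"),
            all(dim(response) == dim(mask$voxels)))
  d <- dim(response)
  rng <- range(response)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    return(marker_image(array(FALSE, d), array(0L, d), 0L))
  }
  h <- config$h_fraction * (rng[2] - rng[1])
  hmax <- reconstruct_dilation_cpp(as.numeric(response) - h,
                                   as.numeric(response), as.integer(d), 26L)
  emax <- array(regional_maxima_cpp(hmax, as.integer(d), 26L), d)
  emax <- emax & mask$voxels
  dil <- dilate_ball_cpp(as.vector(emax), as.integer(d),
                         config$NucleiSeedDilation)
  comp <- label_components_cpp(dil, as.integer(d), 26L)
  marker_image(array(dil, d), array(comp, d), attr(comp, "n_objects"))
}

#' Marker-controlled immersion watershed decomposition
#'
#' Floods the inverted image from the marker components in ascending
#' intensity (6-connected flooding); watershed lines arise where basins
#' meet. The resulting partition is restricted to the initial segmentation
#' mask (immersion does not stop at nucleus borders), objects outside the
#' \[`NucleiMinCount`, `NucleiMaxCount`\] volume gates are removed, and
#' labels are compacted to 1..n.
#'
#' @param inverted inverted prepared image ([invert()]).
#' @param markers a [marker_image()].
#' @param mask a [binary_mask()].
#' @param config a [spheroid_config()].
#' @return A [label_image()].
#' @export
watershed_decompose <- function(inverted, markers, mask,
                                config = spheroid_config()) {
  stopifnot(inherits(inverted, "voxel_image"), inherits(markers, "marker_image"),
            inherits(mask, "binary_mask"))
  d <- dim(inverted$voxels)
  if (markers$component_count == 0) {
    warning("no markers: returning empty label image")
    return(label_image(array(0L, d), inverted$pitch))
  }
  ws <- watershed_cpp(as.numeric(inverted$voxels),
                      as.integer(markers$components), as.integer(d), 6L)
  ws <- array(ws, d)
  ws[!mask$voxels] <- 0L
  .apply_volume_gates(ws, config$NucleiMinCount, config$NucleiMaxCount,
                      inverted$pitch)
}

.apply_volume_gates <- function(ws, min_count, max_count, pitch) {
  n <- max(0L, max(ws))
  if (n > 0) {
    vols <- tabulate(ws[ws > 0], nbins = n)
    keep <- which(vols >= min_count & vols <= max_count)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    pos <- ws > 0
    ws[pos] <- remap[ws[pos]]
  }
  label_image(ws, pitch)
}

#' Segment nuclei in a prepared spheroid image
#'
#' Orchestrates the full segmentation chain: initial local-threshold
#' segmentation, image inversion, multiscale LoG marker detection, and
#' marker-controlled watershed decomposition with volume gating.
#' Deterministic for a fixed input and configuration.
#'
#' @param image prepared [voxel_image()].
#' @param config a [spheroid_config()].
#' @return A [label_image()] with attributes `"n_markers"` (marker component
#'   count) and `"mask_voxels"` (foreground size of the initial
#'   segmentation).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(n_nuclei = 12, spheroid_radius = 18,
#'                                     seed = 1))
#' img <- prepare_image(ph$stack, z_scaling_factor = 1,
#'                      image_scaling_factor = 1)
#' seg <- segment(img)
#' seg$n_objects
segment <- function(image, config = spheroid_config()) {
  mask <- initial_segmentation(image, config)
  inv <- invert(image)
  response <- multiscale_log(inv, config)
  markers <- detect_markers(response, mask, config)
  labels <- watershed_decompose(inv, markers, mask, config)
  attr(labels, "n_markers") <- markers$component_count
  attr(labels, "mask_voxels") <- sum(mask$voxels)
  labels
}
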