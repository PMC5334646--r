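#' Per-nucleus morphological and intensity features
#'
#' Computes, for every labelled nucleus, its volume, centroid and
#' intensity-weighted centroid, distance-to-centroid statistics over all
#' object voxels, surface voxel count (6-neighbour definition), bounding
#' box, principal axes with peak-to-peak extents from a PCA of the voxel
#' coordinates, and intensity statistics. Coordinates are 0-based voxel
#' coordinates `(x, y, z)`; micrometre columns are derived via the pitch.
#' Intensity statistics refer to the \[0, 1\]-normalized stack.
#'
#' The `nds` column (normalized distance to the spheroid surface) is `NA`
#' until filled in by [depth_from_surface()].
#'
#' @param labels a [label_image()].
#' @param image the [voxel_image()] the labels were derived from.
#' @return A tibble with one row per nucleus.
#' @export
#' @examples
#' arr <- array(0L, c(8, 8, 8)); arr[3:5, 3:5, 3:5] <- 1L
#' img <- voxel_image(array(0.5, c(8, 8, 8)), pitch = 0.65)
#' extract_features(label_image(arr, 0.65), img)
extract_features <- function(labels, image) {
  stopifnot(inherits(labels, "label_image"), inherits(image, "voxel_image"),
            all(dim(labels$labels) == dim(image$voxels)))
  n <- labels$n_objects
  if (n == 0) return(.empty_feature_table())
  d <- dim(labels$labels)
  pitch <- labels$pitch
  st <- label_stats_cpp(as.integer(labels$labels), as.numeric(image$voxels),
                        as.integer(d), n)
  vol <- st$volume
  centroid <- cbind(x = st$sum_x / vol, y = st$sum_y / vol, z = st$sum_z / vol)
  wc <- cbind(x = st$wsum_x / st$wsum, y = st$wsum_y / st$wsum,
              z = st$wsum_z / st$wsum)
  mo <- label_moments_cpp(as.integer(labels$labels), as.integer(d), centroid)

  axes <- matrix(0, n, 9)
  extents <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    cov <- matrix(c(mo$cxx[k], mo$cxy[k], mo$cxz[k],
                    mo$cxy[k], mo$cyy[k], mo$cyz[k],
                    mo$cxz[k], mo$cyz[k], mo$czz[k]) / vol[k], 3, 3)
    eg <- eigen(cov, symmetric = TRUE)
    # eigen() returns descending eigenvalues; zero-variance axes keep the
    # completed orthonormal basis and get extent 0
    axes[k, ] <- as.vector(t(eg$vectors))
  }
  extents <- label_extents_cpp(as.integer(labels$labels), as.integer(d),
                               centroid, axes)
  int_mean <- st$int_sum / vol
  int_sd <- sqrt(pmax(0, st$int_sum2 / vol - int_mean^2))

  tibble::tibble(
    label = seq_len(n),
    volume = vol,
    volume_um3 = vol * pitch^3,
    x = as.numeric(centroid[, 1]), y = as.numeric(centroid[, 2]),
    z = as.numeric(centroid[, 3]),
    weighted_x = as.numeric(wc[, 1]), weighted_y = as.numeric(wc[, 2]),
    weighted_z = as.numeric(wc[, 3]),
    dist_to_centroid_mean = mo$dist_sum / vol,
    dist_to_centroid_min = ifelse(is.finite(mo$dist_min), mo$dist_min, 0),
    dist_to_centroid_max = mo$dist_max,
    surface_voxel_count = st$surface,
    bbox_x_min = st$x_min, bbox_x_max = st$x_max,
    bbox_y_min = st$y_min, bbox_y_max = st$y_max,
    bbox_z_min = st$z_min, bbox_z_max = st$z_max,
    axis1_x = axes[, 1], axis1_y = axes[, 2], axis1_z = axes[, 3],
    axis2_x = axes[, 4], axis2_y = axes[, 5], axis2_z = axes[, 6],
    axis3_x = axes[, 7], axis3_y = axes[, 8], axis3_z = axes[, 9],
    extent1 = extents[, 1], extent2 = extents[, 2], extent3 = extents[, 3],
    intensity_mean = int_mean,
    intensity_min = st$int_min,
    intensity_max = st$int_max,
    intensity_sd = int_sd,
    nds = NA_real_,
    pitch = pitch
  )
}

.empty_feature_table <- function() {
  cols <- c("label", "volume", "volume_um3", "x", "y", "z", "weighted_x",
            "weighted_y", "weighted_z", "dist_to_centroid_mean",
            "dist_to_centroid_min", "dist_to_centroid_max",
            "surface_voxel_count", "bbox_x_min", "bbox_x_max", "bbox_y_min",
            "bbox_y_max", "bbox_z_min", "bbox_z_max", "axis1_x", "axis1_y",
            "axis1_z", "axis2_x", "axis2_y", "axis2_z", "axis3_x", "axis3_y",
            "axis3_z", "extent1", "extent2", "extent3", "intensity_mean",
            "intensity_min", "intensity_max", "intensity_sd", "nds", "pitch")
  out <- tibble::as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
  out$label <- integer(0)
  out
}

#' Centroids of a label image
#'
#' @param labels a [label_image()].
#' @return A tibble with `label`, `x`, `y`, `z` (0-based voxel coordinates).
#' @export
label_centroids <- function(labels) {
  stopifnot(inherits(labels, "label_image"))
  n <- labels$n_objects
  if (n == 0) {
    return(tibble::tibble(label = integer(0), x = numeric(0), y = numeric(0),
                          z = numeric(0)))
  }
  st <- label_stats_cpp(as.integer(labels$labels),
                        as.numeric(labels$labels) * 0,
                        as.integer(dim(labels$labels)), n)
  tibble::tibble(label = seq_len(n), x = st$sum_x / st$volume,
                 y = st$sum_y / st$volume, z = st$sum_z / st$volume)
}
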