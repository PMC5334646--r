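#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a radial density profile
#'
#' Mean feature value per NDS bin with a shaded standard-error band, the
#' standard depth-profile display for spheroid density analyses.
#'
#' @param object a `spheroid_radial_profile`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot spheroid_radial_profile
#' @export
autoplot.spheroid_radial_profile <- function(object, ...) {
  df <- object[!is.na(object$mean), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nds_mid, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "normalized distance to surface (NDS)",
                  y = "mean feature value") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot the volume-cell-number relation
#'
#' @param object a `spheroid_volume_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot spheroid_volume_fit
#' @export
autoplot.spheroid_volume_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$cell_number, y = .data$volume)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "cell number", y = expression(volume ~ (mu * m^3)),
                  subtitle = sprintf("slope %.0f um^3/cell, r = %.2f",
                                     object$slope, object$pearson_r)) +
    ggplot2::theme_minimal()
}

#' Display one plane of a voxel or label image
#'
#' @param image a [voxel_image()] or [label_image()].
#' @param z plane index (1-based); defaults to the middle plane.
#' @return A ggplot object.
#' @export
plot_plane <- function(image, z = NULL) {
  arr <- if (inherits(image, "label_image")) image$labels else image$voxels
  if (is.null(z)) z <- ceiling(dim(arr)[3] / 2)
  m <- arr[, , z]
  df <- expand.grid(y = seq_len(nrow(m)) - 1, x = seq_len(ncol(m)) - 1)
  df$value <- as.vector(m)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("plane %d", z)) +
    ggplot2::theme_void()
  if (inherits(image, "label_image")) {
    p + ggplot2::scale_fill_gradientn(
      colours = c("black", grDevices::rainbow(32)), guide = "none")
  } else {
    p + ggplot2::scale_fill_gradient(low = "black", high = "white",
                                     guide = "none")
  }
}
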