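#' Run the complete spheroid analysis pipeline
#'
#' Executes the full chain on one stack: pre-processing to an isotropic
#' downscaled image, nuclei segmentation, per-nucleus features, alpha-shape
#' surface with NDS, proximity and Delaunay cell graphs, local density,
#' radial density profile and (optionally) the RCP null-model ensemble.
#' All stage parameters come from a single [spheroid_config()]; outputs and
#' a machine-readable run manifest are written to `out_dir`.
#'
#' @param stack a [raw_stack()] or path to a TIFF stack.
#' @param config a [spheroid_config()]; `NULL` applies the defaults (logged).
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output and only returns results.
#' @param rcp_reps RCP Monte Carlo replicates (0 skips the null model).
#' @param n_bins radial profile bins.
#' @param seed RNG seed for the stochastic stages (RCP model).
#' @param z_scaling_factor,image_scaling_factor passed to [prepare_image()];
#'   the defaults derive the Z factor from the stack pitches and downscale
#'   by the configured `ImageScalingFactor`.
#' @return (Invisibly) a list with the prepared image, label image, feature
#'   table, surface model, graphs, density table, profile, RCP profile and
#'   the manifest.
#' @export
run_pipeline <- function(stack, config = NULL, out_dir = NULL, rcp_reps = 10,
                         n_bins = 20, seed = 1, z_scaling_factor = NULL,
                         image_scaling_factor = NULL) {
  t_start <- Sys.time()
  if (is.character(stack)) stack <- read_stack(stack)
  stopifnot(inherits(stack, "raw_stack"))
  if (is.null(config)) {
    message("no configuration supplied: applying defaults")
    config <- spheroid_config()
  }
  if (is.null(image_scaling_factor)) {
    image_scaling_factor <- config$ImageScalingFactor
  }
  if (is.null(z_scaling_factor)) z_scaling_factor <- config$ImageZScalingFactor

  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  log_stage("prepare", "z factor %s, image factor %g",
            ifelse(is.null(z_scaling_factor), "auto", z_scaling_factor),
            image_scaling_factor)
  img <- prepare_image(stack, z_scaling_factor = z_scaling_factor,
                       image_scaling_factor = image_scaling_factor)

  log_stage("segment", "running segmentation")
  labels <- segment(img, config)
  log_stage("segment", "%d nuclei (from %d markers)", labels$n_objects,
            attr(labels, "n_markers"))

  features <- extract_features(labels, img)

  log_stage("surface", "outlier removal at %g voxels, alpha %g",
            config$OutlierDistanceThreshold, config$Alpha)
  pts <- remove_outliers(features[, c("x", "y", "z")],
                         threshold = config$OutlierDistanceThreshold)
  surface <- build_alpha_shape(pts, alpha = config$Alpha, pitch = img$pitch)
  features <- add_nds(features, surface)

  log_stage("graphs", "edge threshold %g voxels", config$EdgeDistanceThreshold)
  pcg <- build_pcg(features[, c("x", "y", "z")],
                   threshold = config$EdgeDistanceThreshold, pitch = img$pitch)
  dcg <- build_dcg(features[, c("x", "y", "z")],
                   threshold = config$EdgeDistanceThreshold, pitch = img$pitch,
                   jitter = 1e-9)
  density <- density_features(pcg)
  profile <- radial_profile(density$degree, features$nds, n_bins = n_bins)

  rcp <- NULL
  if (rcp_reps > 0 && labels$n_objects > 0) {
    # RCP sphere radius = median equivalent-sphere radius of the segmented
    # nuclei (the null model mirrors the dataset it is compared against)
    r_med <- stats::median((3 * features$volume / (4 * pi))^(1 / 3))
    log_stage("rcp", "%d Monte Carlo replicates, sphere radius %.1f, seed %d",
              rcp_reps, r_med, seed)
    set.seed(seed)
    rcp <- rcp_profile_ensemble(surface, n_cells = labels$n_objects,
                                sphere_radius = r_med, n_reps = rcp_reps,
                                threshold = config$EdgeDistanceThreshold,
                                n_bins = n_bins)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("spheroidr")),
    seed = seed,
    config = unclass(config)[!vapply(config, is.null, logical(1))],
    stack_dim = dim(stack$planes),
    image_dim = dim(img$voxels),
    pitch_um = img$pitch,
    n_markers = attr(labels, "n_markers"),
    n_nuclei = labels$n_objects,
    surface = surface_summary(surface),
    n_pcg_edges = nrow(pcg$edges),
    n_dcg_edges = nrow(dcg$edges),
    rcp_reps = rcp_reps,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_labels(labels, file.path(out_dir, "labels.tif"))
    write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    write_ply(surface, file.path(out_dir, "surface.ply"))
    jsonlite::write_json(surface_summary(surface),
                         file.path(out_dir, "surface.json"),
                         auto_unbox = TRUE, digits = NA)
    write_graphml(pcg, file.path(out_dir, "pcg.graphml"))
    write_graphml(dcg, file.path(out_dir, "dcg.graphml"))
    write.csv(density, file.path(out_dir, "density.csv"), row.names = FALSE)
    write.csv(profile, file.path(out_dir, "profile.csv"), row.names = FALSE)
    if (!is.null(rcp)) {
      write.csv(rcp, file.path(out_dir, "rcp_profile.csv"), row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  log_stage("done", "%d nuclei in %.1f s", labels$n_objects,
            manifest$elapsed_s)
  invisible(list(image = img, labels = labels, features = features,
                 surface = surface, pcg = pcg, dcg = dcg, density = density,
                 profile = profile, rcp_profile = rcp, manifest = manifest))
}
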