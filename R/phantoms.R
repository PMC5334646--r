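#' Specification of a synthetic phantom spheroid
#'
#' Describes a synthetic nuclei-stained spheroid stack with exact ground
#' truth. Defaults emulate the working (downscaled, isotropic) image space
#' of cleared light-sheet data: ~200 densely packed nuclei with a median
#' radius of 6 voxels (radii 4.5-7.5, matching a median nucleus volume of
#' ~900 voxels / ~250 um^3 at 0.65 um pitch), heterogeneous per-nucleus
#' intensity, a dim background and additive Gaussian noise. The resulting
#' cell density (~1e6 cells/mm^3) lies at the dense end of the range
#' observed in real spheroids.
#'
#' @param n_nuclei number of nuclei.
#' @param spheroid_radius radius of the spherical aggregate (voxels).
#' @param r_min,r_max nucleus radius range (voxels).
#' @param min_center_gap minimum centre separation of two nuclei as a
#'   fraction of the sum of their radii; 0.9 gives apparently touching,
#'   partly fused nuclei as in dense aggregates.
#' @param intensity_range per-nucleus peak intensity range (uniform draw).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param background background intensity level.
#' @param layering optional `list(boundary_nds =, density_ratio =)`:
#'   nuclei are placed with `density_ratio`-fold higher density in the
#'   outer shell (normalized depth below `boundary_nds`) than in the core.
#' @param anisotropy optional integer plane-subsampling factor emulating a
#'   coarser axial pitch (e.g. 4 for the 1.29 um / 0.325 um instrument
#'   ratio).
#' @param pitch lateral/isotropic pitch in micrometres.
#' @param seed RNG seed making the phantom reproducible.
#' @param margin empty margin around the aggregate (voxels).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_nuclei = 200, spheroid_radius = 56, r_min = 4.5,
                         r_max = 7.5, min_center_gap = 0.9,
                         intensity_range = c(0.6, 1), noise_sd = 0.05,
                         background = 0.1, layering = NULL, anisotropy = NULL,
                         pitch = 0.65, seed = 1, margin = 4) {
  stopifnot(r_min <= r_max, r_min > 0, noise_sd >= 0, n_nuclei >= 0,
            min_center_gap >= 0, spheroid_radius > r_max)
  # random-sequential packing feasibility (jamming near 38%); centres are
  # confined to a ball of radius (spheroid_radius - r), hence the shrunken
  # denominator
  if (n_nuclei > 0) {
    mean_r <- (r_min + r_max) / 2
    mean_r3 <- (r_max^4 - r_min^4) / (4 * (r_max - r_min) + 1e-12)
    frac <- n_nuclei * (min_center_gap)^3 * mean_r3 /
      max(1e-9, (spheroid_radius - mean_r)^3)
    if (frac > 0.38) {
      stop(sprintf("packing infeasible: requested fraction %.2f > 0.38", frac))
    }
  }
  structure(list(n_nuclei = n_nuclei, spheroid_radius = spheroid_radius,
                 r_min = r_min, r_max = r_max,
                 min_center_gap = min_center_gap,
                 intensity_range = intensity_range, noise_sd = noise_sd,
                 background = background, layering = layering,
                 anisotropy = anisotropy, pitch = pitch, seed = seed,
                 margin = margin),
            class = "phantom_spec")
}

#' Generate a synthetic spheroid stack with exact ground truth
#'
#' Nucleus centres are sampled uniformly (or with concentric layering)
#' inside a ball under a pairwise non-overlap constraint, each nucleus is
#' rendered as a solid sphere with a radial intensity falloff, the stack is
#' blurred with a 1-voxel Gaussian (PSF surrogate), background and Gaussian
#' noise are added, and the result is quantized to 16 bits. The ground
#' truth records the exact centres, radii and a reference label volume.
#'
#' @param spec a [phantom_spec()].
#' @param render render the image stack and reference label volume? With
#'   `FALSE` only the ground-truth point pattern is produced (`stack` and
#'   `labels` are `NULL`), which is sufficient for geometry/graph analyses.
#' @return A list: `stack` (a [raw_stack()]), `centroids` (tibble `label`,
#'   `x`, `y`, `z`, `radius`, 0-based voxel coordinates in the rendered
#'   isotropic grid), and `labels` (reference [label_image()]).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(n_nuclei = 10, spheroid_radius = 15,
#'                                     seed = 7))
#' dim(ph$stack$planes)
generate_phantom <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  R <- spec$spheroid_radius
  L <- 2 * ceiling(R + spec$r_max + spec$margin) + 1
  dims <- c(L, L, L)
  ctr <- (L - 1) / 2 # 0-based centre

  n <- spec$n_nuclei
  radii <- if (n > 0) runif(n, spec$r_min, spec$r_max) else numeric(0)
  centers <- matrix(0, n, 3)
  ratio <- if (!is.null(spec$layering)) spec$layering$density_ratio else 1
  boundary <- if (!is.null(spec$layering)) spec$layering$boundary_nds else 0
  wmax <- max(ratio, 1)
  placed <- 0
  while (placed < n) {
    attempts <- 0
    repeat {
      attempts <- attempts + 1
      if (attempts > 10000) {
        stop("phantom packing infeasible: placed ", placed, " of ", n,
             " nuclei")
      }
      rmax_c <- R - radii[placed + 1]
      u <- rnorm(3)
      p <- u / sqrt(sum(u^2)) * rmax_c * runif(1)^(1 / 3)
      if (ratio != 1) {
        depth_frac <- (R - sqrt(sum(p^2))) / R # 0 surface .. 1 centre
        w <- if (depth_frac < boundary) ratio else 1
        if (runif(1) > w / wmax) next
      }
      ok <- TRUE
      if (placed > 0) {
        d <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                           (ctr + p))^2))
        lim <- spec$min_center_gap * (radii[seq_len(placed)] + radii[placed + 1])
        if (any(d < lim)) ok <- FALSE
      }
      if (ok) break
    }
    placed <- placed + 1
    centers[placed, ] <- ctr + p
  }

  if (!render) {
    return(list(
      stack = NULL,
      centroids = tibble::tibble(label = seq_len(n),
                                 x = centers[, 1], y = centers[, 2],
                                 z = centers[, 3], radius = radii),
      labels = NULL
    ))
  }

  img <- if (n > 0) {
    peaks <- runif(n, spec$intensity_range[1], spec$intensity_range[2])
    base <- render_nuclei_cpp(as.integer(dims), centers, radii, peaks,
                              falloff = 0.3)
    g <- .gaussian_kernel(1, radius = 3)
    array(separable_filter_cpp(as.numeric(base), as.integer(dims), g, g, g),
          dims)
  } else {
    array(0, dims)
  }
  img <- spec$background + img
  if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
  img <- pmin(1, pmax(0, img))
  planes <- array(round(img * 65535), dims)

  labels <- if (n > 0) {
    array(render_labels_cpp(as.integer(dims), centers, radii), dims)
  } else {
    array(0L, dims)
  }

  axial_pitch <- spec$pitch
  if (!is.null(spec$anisotropy)) {
    a <- as.integer(spec$anisotropy)
    stopifnot(a >= 1)
    planes <- planes[, , seq(1, dims[3], by = a), drop = FALSE]
    axial_pitch <- spec$pitch * a
  }

  list(
    stack = raw_stack(planes, lateral_pitch = spec$pitch,
                      axial_pitch = axial_pitch, bit_depth = 16L),
    # centers matrix columns are (x, y, z): x = column axis, y = row axis
    centroids = tibble::tibble(label = seq_len(n),
                               x = centers[, 1], y = centers[, 2],
                               z = centers[, 3], radius = radii),
    labels = label_image(labels, spec$pitch)
  )
}

#' Small deterministic fixtures for unit tests
#'
#' * `"single_ball"`: one radius-6 ball in a 32-cube (volume ~905 voxels).
#' * `"dumbbell"`: two overlapping radius-6 balls whose centres are 10
#'   voxels apart — the canonical watershed-split case.
#' * `"grid"`: 3 x 3 x 3 nuclei on a 20-voxel grid in a 64-cube.
#' * `"two_layer"`: a layered phantom (outer shell twice as dense as the
#'   core, boundary at 0.5 normalized depth).
#'
#' @param name fixture name.
#' @return As [generate_phantom()].
#' @export
generate_toy_fixture <- function(name = c("single_ball", "dumbbell", "grid",
                                          "two_layer")) {
  name <- match.arg(name)
  switch(name,
    single_ball = .render_fixture(
      dims = c(32, 32, 32),
      centers = matrix(c(15.5, 15.5, 15.5), 1), radii = 6),
    dumbbell = .render_fixture(
      dims = c(32, 32, 32),
      centers = rbind(c(10.5, 15.5, 15.5), c(20.5, 15.5, 15.5)), # 10 apart in x
      radii = c(6, 6)),
    grid = .render_fixture(
      dims = c(64, 64, 64),
      centers = as.matrix(expand.grid(x = c(11.5, 31.5, 51.5),
                                      y = c(11.5, 31.5, 51.5),
                                      z = c(11.5, 31.5, 51.5))),
      radii = rep(3, 27)),
    two_layer = generate_phantom(phantom_spec(
      n_nuclei = 180, spheroid_radius = 26, r_min = 2.5, r_max = 3.5,
      min_center_gap = 0.85, noise_sd = 0.03,
      layering = list(boundary_nds = 0.5, density_ratio = 2), seed = 42))
  )
}

.render_fixture <- function(dims, centers, radii) {
  centers <- centers[, c(1, 2, 3), drop = FALSE] # columns (x, y, z)
  base <- render_nuclei_cpp(as.integer(dims), centers, radii,
                            rep(0.9, nrow(centers)), falloff = 0.3)
  g <- .gaussian_kernel(1, radius = 3)
  img <- array(separable_filter_cpp(as.numeric(base), as.integer(dims),
                                    g, g, g), dims)
  img <- pmin(1, pmax(0, 0.05 + img))
  planes <- array(round(img * 65535), dims)
  labels <- array(render_labels_cpp(as.integer(dims), centers, radii), dims)
  list(
    stack = raw_stack(planes, lateral_pitch = 0.65, axial_pitch = 0.65,
                      bit_depth = 16L),
    centroids = tibble::tibble(label = seq_len(nrow(centers)),
                               x = centers[, 1], y = centers[, 2],
                               z = centers[, 3], radius = radii),
    labels = label_image(labels, 0.65)
  )
}
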