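#' Radial profile of a per-nucleus feature over normalized depth
#'
#' Bins nuclei into equal-width NDS bins on \[0, 1\] and reports the
#' per-bin mean, standard error of the mean and count. Empty bins are kept
#' with `NA` mean/SE.
#'
#' @param values per-nucleus feature (e.g. PCG degree).
#' @param nds per-nucleus normalized distance to the surface, aligned with
#'   `values`.
#' @param n_bins number of equal-width bins (>= 2).
#' @return A tibble of class `spheroid_radial_profile` with `bin`, `nds_lo`,
#'   `nds_hi`, `nds_mid`, `mean`, `se`, `n`.
#' @export
#' @examples
#' radial_profile(rep(5, 100), runif(100), n_bins = 10)
radial_profile <- function(values, nds, n_bins = 20) {
  stopifnot(length(values) == length(nds), n_bins >= 2)
  stopifnot(all(nds >= -1e-9 & nds <= 1 + 1e-9))
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(n_bins, findInterval(nds, edges, rightmost.closed = TRUE))
  bin <- pmax(1L, bin)
  out <- tibble::tibble(bin = seq_len(n_bins),
                        nds_lo = edges[-(n_bins + 1)], nds_hi = edges[-1])
  out$nds_mid <- (out$nds_lo + out$nds_hi) / 2
  agg <- lapply(seq_len(n_bins), function(b) {
    v <- values[bin == b]
    if (length(v) == 0) return(c(NA_real_, NA_real_, 0))
    c(mean(v), if (length(v) > 1) sd(v) / sqrt(length(v)) else 0, length(v))
  })
  agg <- do.call(rbind, agg)
  out$mean <- agg[, 1]; out$se <- agg[, 2]; out$n <- as.integer(agg[, 3])
  class(out) <- c("spheroid_radial_profile", class(out))
  out
}

#' Surface / outer / core region summary
#'
#' Assigns each nucleus to one of three concentric regions by its NDS:
#' surface `[0, surface_cut)`, outer `[surface_cut, core_cut)`, core
#' `[core_cut, 1]`, and summarizes the local cell density per region. The
#' mean spheroid radius is the maximum depth (the NDS normalizer) in
#' micrometres, and the thickness of the outer region is the depth of the
#' outer/core boundary below the surface, `core_cut * mean_radius`. The
#' outer-region volume is reported under a concentric-shrinkage convention:
#' shape volume times `(1 - surface_cut)^3 - (1 - core_cut)^3`.
#'
#' @param depth tibble from [depth_from_surface()] (columns `distance`,
#'   `nds`).
#' @param density per-nucleus local cell density (cells/u.v.), aligned with
#'   `depth`.
#' @param surface optional `surface_model`, used for the outer-region
#'   volume.
#' @param surface_cut NDS boundary between surface and outer region.
#' @param core_cut NDS boundary between outer and core region (0.75 for
#'   medium, 0.5 for large spheroids).
#' @param pitch voxel pitch in micrometres.
#' @return A list of class `region_summary`: `assignment` (tibble with
#'   `nds`, `region`), `regions` (tibble with per-region `n` and
#'   `mean_density`), `mean_radius_um`, `outer_thickness_um`,
#'   `outer_volume_mm3` (or `NA`).
#' @export
#' @examples
#' dep <- tibble::tibble(distance = c(10, 100, 250), nds = c(0.04, 0.4, 1))
#' rs <- summarize_regions(dep, density = c(45, 62, 55), core_cut = 0.75,
#'                         pitch = 0.65)
#' rs$outer_thickness_um
summarize_regions <- function(depth, density, surface = NULL,
                              surface_cut = 0.1, core_cut = 0.75,
                              pitch = 0.65) {
  if (core_cut <= surface_cut) stop("core_cut must exceed surface_cut")
  nds <- depth$nds
  stopifnot(length(nds) == length(density))
  region <- cut(nds, breaks = c(-Inf, surface_cut, core_cut, Inf),
                labels = c("surface", "outer", "core"), right = FALSE)
  regions <- tibble::tibble(
    region = factor(c("surface", "outer", "core"),
                    levels = c("surface", "outer", "core")))
  regions$n <- as.integer(table(region)[as.character(regions$region)])
  regions$mean_density <- vapply(as.character(regions$region), function(r) {
    v <- density[region == r]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  mean_radius_um <- max(depth$distance) * pitch
  outer_thickness_um <- core_cut * mean_radius_um
  outer_volume_mm3 <- NA_real_
  if (!is.null(surface)) {
    shell <- (1 - surface_cut)^3 - (1 - core_cut)^3
    outer_volume_mm3 <- surface$volume * pitch^3 * shell / 1e9
  }
  structure(list(
    assignment = tibble::tibble(nds = nds, region = region),
    regions = regions,
    surface_cut = surface_cut, core_cut = core_cut,
    mean_radius_um = mean_radius_um,
    outer_thickness_um = outer_thickness_um,
    outer_volume_mm3 = outer_volume_mm3
  ), class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("<region_summary> cuts %g / %g NDS\n", x$surface_cut,
              x$core_cut))
  print(x$regions)
  cat(sprintf("  mean radius %.1f um, outer thickness %.1f um\n",
              round_half_away(x$mean_radius_um, 1),
              round_half_away(x$outer_thickness_um, 1)))
  invisible(x)
}

#' One replicate of the random cell position (RCP) null model
#'
#' Places `n_cells` points uniformly inside the alpha-shape solid as
#' non-overlapping spheres: a tetrahedron is drawn with probability
#' proportional to its volume, a point uniformly within it, and candidates
#' closer than `2 * sphere_radius` to an accepted point are rejected. The
#' sphere radius defaults to the median nucleus radius (~6 voxels). Uses
#' R's RNG; call `set.seed()` for reproducibility.
#'
#' @param surface a `surface_model`.
#' @param n_cells number of cells; the exact analogue of a real dataset uses
#'   its detected cell count.
#' @param sphere_radius nucleus sphere radius in voxels.
#' @param max_attempts consecutive rejections per point before the packing
#'   is declared infeasible.
#' @return A tibble of points (`x`, `y`, `z`).
#' @export
rcp_sample <- function(surface, n_cells, sphere_radius = 6,
                       max_attempts = 10000) {
  stopifnot(inherits(surface, "surface_model"), n_cells > 0,
            sphere_radius > 0)
  circ <- tet_circum_cpp(surface$points, surface$tetrahedra)
  vols <- pmax(circ$volume, 0)
  # crude feasibility guard: random sequential packing jams near 38%
  packing <- n_cells * 4 / 3 * pi * sphere_radius^3 / sum(vols)
  if (packing > 0.38) {
    stop(sprintf(
      "packing infeasible: %d spheres of radius %g fill %.0f%% of the shape",
      n_cells, sphere_radius, 100 * packing))
  }
  pts <- rcp_pack_cpp(surface$points, surface$tetrahedra, cumsum(vols),
                      as.integer(n_cells), 2 * sphere_radius,
                      as.integer(max_attempts))
  tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

#' RCP ensemble radial density profile
#'
#' Runs `n_reps` Monte Carlo replicates of the RCP model (default 10): each
#' replicate samples cell positions, builds the proximity cell graph,
#' derives per-cell density and NDS, and bins a radial profile. The pooled
#' profile reports the mean over replicate bin means and its standard error
#' across replicates.
#'
#' @inheritParams rcp_sample
#' @param n_reps number of Monte Carlo replicates.
#' @param threshold PCG edge distance threshold (voxels).
#' @param n_bins NDS bins.
#' @return A tibble of class `spheroid_radial_profile` (pooled), with the
#'   per-replicate profiles in attribute `"replicates"`.
#' @export
rcp_profile_ensemble <- function(surface, n_cells, sphere_radius = 6,
                                 n_reps = 10, threshold = 40, n_bins = 20,
                                 max_attempts = 10000) {
  reps <- lapply(seq_len(n_reps), function(r) {
    pts <- rcp_sample(surface, n_cells, sphere_radius, max_attempts)
    g <- build_pcg(pts, threshold = threshold, pitch = surface$pitch)
    dens <- density_features(g)$degree
    dep <- depth_from_surface(pts, surface)
    prof <- radial_profile(dens, dep$nds, n_bins = n_bins)
    prof$replicate <- r
    prof
  })
  means <- sapply(reps, function(p) p$mean)   # n_bins x n_reps
  pooled <- reps[[1]][, c("bin", "nds_lo", "nds_hi", "nds_mid")]
  pooled$mean <- rowMeans(means, na.rm = TRUE)
  pooled$se <- apply(means, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  })
  pooled$n <- as.integer(rowSums(sapply(reps, function(p) p$n)))
  class(pooled) <- c("spheroid_radial_profile", class(pooled))
  attr(pooled, "replicates") <- do.call(rbind, reps)
  attr(pooled, "n_reps") <- n_reps
  pooled
}

#' Cluster spheroid datasets by cell number and volume
#'
#' Partitioning around medoids (PAM) with squared Euclidean distance on
#' z-scored cell number and volume. For n <= 20 datasets the medoid set is
#' found by exhaustive search (deterministic global optimum); larger inputs
#' use [cluster::pam()] on the squared-distance matrix.
#'
#' @param summary data frame with columns `cell_number` and `volume` (one
#'   row per dataset).
#' @param k number of groups.
#' @return `summary` with a `group` column (1..k, relabelled in order of
#'   increasing medoid cell number) and attribute `"medoids"` (row indices).
#' @export
#' @examples
#' df <- data.frame(cell_number = c(1, 2, 50, 52, 200, 210),
#'                  volume = c(1, 2, 50, 52, 200, 210) * 1000)
#' cluster_datasets(df, k = 3)$group
cluster_datasets <- function(summary, k = 3) {
  stopifnot(all(c("cell_number", "volume") %in% names(summary)))
  n <- nrow(summary)
  if (k > n) stop("k exceeds the number of datasets")
  X <- scale(cbind(summary$cell_number, summary$volume))
  D2 <- as.matrix(dist(X))^2
  if (n <= 20) {
    combs <- utils::combn(n, k)
    best <- NULL; best_obj <- Inf
    for (j in seq_len(ncol(combs))) {
      med <- combs[, j]
      obj <- sum(apply(D2[, med, drop = FALSE], 1, min))
      if (obj < best_obj - 1e-12) { best_obj <- obj; best <- med }
    }
    medoids <- best
    assign <- apply(D2[, medoids, drop = FALSE], 1, which.min)
  } else {
    fit <- cluster::pam(stats::as.dist(D2), k = k, diss = TRUE)
    medoids <- fit$id.med
    assign <- fit$clustering
  }
  # stable group labels: order groups by medoid cell number
  ord <- order(summary$cell_number[medoids])
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  out <- summary
  out$group <- relabel[assign]
  attr(out, "medoids") <- medoids[ord]
  out
}

#' Linear volume-cell-number relation
#'
#' Ordinary least squares fit of spheroid volume (um^3) against detected
#' cell number; the slope is the volume increase per cell.
#'
#' @param cell_numbers detected cells per dataset.
#' @param volumes spheroid volumes (um^3) per dataset.
#' @return An object of class `spheroid_volume_fit` wrapping the `lm` fit,
#'   with `slope`, `intercept` and Pearson `r`.
#' @export
#' @examples
#' fit <- fit_volume_cell_line(1:10, 1118 * (1:10) + 50)
#' fit$slope
fit_volume_cell_line <- function(cell_numbers, volumes) {
  stopifnot(length(cell_numbers) == length(volumes),
            length(cell_numbers) >= 2)
  if (var(cell_numbers) == 0) stop("cell numbers have zero variance")
  fit <- lm(volumes ~ cell_numbers)
  structure(list(
    fit = fit,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    pearson_r = stats::cor(cell_numbers, volumes),
    data = tibble::tibble(cell_number = cell_numbers, volume = volumes)
  ), class = "spheroid_volume_fit")
}

#' @export
print.spheroid_volume_fit <- function(x, ...) {
  cat(sprintf(
    "<spheroid_volume_fit> slope %.4g um^3/cell, intercept %.4g, Pearson r %.3f\n",
    x$slope, x$intercept, x$pearson_r))
  invisible(x)
}

#' Suggest a region transition point from a radial profile
#'
#' Optional helper: locates the NDS with the largest second difference of
#' the lightly smoothed profile mean, a simple change-point heuristic. The
#' region cuts used in analyses remain a user decision.
#'
#' @param profile a `spheroid_radial_profile`.
#' @return NDS value of the candidate transition point.
#' @export
suggest_transition <- function(profile) {
  m <- profile$mean
  ok <- !is.na(m)
  sm <- stats::filter(m[ok], rep(1 / 3, 3), sides = 2)
  d2 <- abs(diff(sm, differences = 2))
  idx <- which(ok)[which.max(d2) + 1]
  profile$nds_mid[idx]
}

#' Step contrast between a real profile and its RCP ensemble
#'
#' Quantifies how strongly a dataset's radial density profile deviates from
#' its random-cell-position analogue at a candidate layer boundary. The
#' statistic is the step in the difference curve (real minus RCP) across the
#' boundary, averaged over interior bins on each side, in units of its
#' standard error. Working on the difference of means across the boundary
#' cancels the small global density offset between a finite point pattern
#' and the alpha shape it defines.
#'
#' @param real a `spheroid_radial_profile` of the dataset.
#' @param rcp the pooled RCP ensemble profile ([rcp_profile_ensemble()]),
#'   same binning.
#' @param boundary NDS of the candidate outer/core boundary.
#' @param interior NDS range free of graph edge effects (bins outside it are
#'   ignored); the lower limit should exceed `threshold / spheroid radius`.
#' @return A one-row tibble with `step`, `se`, `z` (= step/se).
#' @export
rcp_step_test <- function(real, rcp, boundary = 0.5,
                          interior = c(0.25, 0.9)) {
  stopifnot(nrow(real) == nrow(rcp))
  diffc <- real$mean - rcp$mean
  below <- real$nds_mid > interior[1] & real$nds_mid < boundary
  above <- real$nds_mid > boundary & real$nds_mid < interior[2]
  ok <- !is.na(diffc)
  below <- below & ok; above <- above & ok
  if (sum(below) == 0 || sum(above) == 0) {
    stop("no interior bins on one side of the boundary")
  }
  step <- abs(mean(diffc[above]) - mean(diffc[below]))
  se <- sqrt(mean(rcp$se[above]^2 + real$se[above]^2, na.rm = TRUE) /
               sum(above) +
             mean(rcp$se[below]^2 + real$se[below]^2, na.rm = TRUE) /
               sum(below))
  tibble::tibble(step = step, se = se, z = step / se)
}
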