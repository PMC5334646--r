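# points arguments accept a matrix or a data frame with x/y/z columns
.as_points <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    m <- cbind(points$x, points$y, points$z)
  } else {
    m <- as.matrix(points)
    stopifnot(ncol(m) == 3)
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y", "z")
  m
}

#' Remove spurious detections before surface reconstruction
#'
#' Connects all centroids within `threshold` voxels of each other and keeps
#' the largest connected component of the resulting proximity graph; smaller
#' components (isolated false-positive detections away from the aggregate)
#' are dropped and reported.
#'
#' @param centroids matrix or data frame of points (voxel coordinates).
#' @param threshold connection distance in voxels.
#' @return The retained points, same type of container as the input, with
#'   attribute `"removed"` holding the dropped row indices.
#' @export
#' @examples
#' pts <- rbind(matrix(runif(300, 0, 20), ncol = 3), c(100, 100, 100))
#' nrow(remove_outliers(pts))
remove_outliers <- function(centroids, threshold = 20) {
  m <- .as_points(centroids)
  if (nrow(m) == 0) stop("no points supplied")
  if (threshold <= 0) stop("threshold must be positive")
  if (nrow(m) == 1) return(centroids)
  e <- edges_within_cpp(m, threshold * (1 + 1e-12))
  g <- igraph::graph_from_edgelist(cbind(e[, 1], e[, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(m) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keep_comp <- which.max(comp$csize)
  keep <- which(comp$membership == keep_comp)
  removed <- setdiff(seq_len(nrow(m)), keep)
  if (length(removed) > 0) {
    message(length(removed), " point(s) outside the main aggregate removed")
  }
  out <- if (is.data.frame(centroids)) centroids[keep, , drop = FALSE]
         else centroids[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Alpha-shape model of the spheroid
#'
#' Builds the 3D Delaunay tetrahedralization of the centroids and keeps the
#' tetrahedra whose circumradius is below `alpha`; their union is the solid
#' alpha shape. As `alpha` grows beyond the largest circumradius the shape
#' converges to the convex hull. Boundary triangles are the faces that
#' belong to exactly one kept tetrahedron. If the kept tetrahedra fall into
#' several face-connected components, the largest-volume component is
#' retained with a warning.
#'
#' @param points matrix or data frame of >= 4 non-coplanar points (voxel
#'   coordinates).
#' @param alpha circumradius threshold in voxels.
#' @param pitch voxel pitch in micrometres, used for the micrometre
#'   conversions in the summary; `NULL` to skip.
#' @param jitter standard deviation of a deterministic (seed-controlled)
#'   jitter applied before triangulation to break degeneracies; 0 disables.
#'
#' @return A `surface_model`: points, kept tetrahedra, boundary triangle
#'   mesh, `alpha`, solid `volume` (voxels^3), `surface_area` (voxels^2),
#'   volume-weighted `centroid` and `n_points`.
#' @export
#' @examples
#' set.seed(1)
#' p <- matrix(rnorm(3000), ncol = 3)
#' p <- p / sqrt(rowSums(p^2)) * runif(1000)^(1/3) * 50
#' s <- build_alpha_shape(p, alpha = 90)
#' s$volume / (4 / 3 * pi * 50^3)
build_alpha_shape <- function(points, alpha = 90, pitch = NULL, jitter = 0) {
  m <- .as_points(points)
  if (nrow(m) < 4) stop("alpha shape needs at least 4 points")
  if (alpha <= 0) stop("alpha must be positive")
  mj <- m
  if (jitter > 0) {
    mj <- m + matrix(rnorm(length(m), 0, jitter), nrow(m), 3)
  }
  tets <- tryCatch(delaunay3d_cpp(mj), error = function(e) {
    stop("Delaunay triangulation failed (degenerate/coplanar input?); ",
         "consider jitter > 0. Underlying error: ", conditionMessage(e))
  })
  if (nrow(tets) == 0) {
    stop("degenerate point set: no tetrahedra (coplanar input?)")
  }
  circ <- tet_circum_cpp(m, tets)
  keep <- which(circ$radius < alpha & circ$volume > 0)
  if (length(keep) == 0) {
    stop("alpha = ", alpha, " keeps no tetrahedra; increase alpha")
  }
  tets <- tets[keep, , drop = FALSE]
  vols <- circ$volume[keep]

  comp <- .tet_components(tets)
  if (max(comp) > 1) {
    comp_vol <- tapply(vols, comp, sum)
    best <- as.integer(names(which.max(comp_vol)))
    warning("alpha shape has ", max(comp),
            " components; keeping the largest by volume")
    sel <- comp == best
    tets <- tets[sel, , drop = FALSE]
    vols <- vols[sel]
  }

  faces <- .boundary_faces(tets)
  areas <- .triangle_areas(m, faces)
  tet_centroids <- (m[tets[, 1], , drop = FALSE] + m[tets[, 2], , drop = FALSE] +
                    m[tets[, 3], , drop = FALSE] + m[tets[, 4], , drop = FALSE]) / 4
  centroid <- colSums(tet_centroids * vols) / sum(vols)

  structure(list(
    points = m, tetrahedra = tets, boundary_triangles = faces,
    alpha = alpha, volume = sum(vols), surface_area = sum(areas),
    centroid = centroid, n_points = nrow(m), pitch = pitch
  ), class = "surface_model")
}

# face-connectivity components of a tetra set (faces keyed numerically)
.tet_components <- function(tets) {
  n <- nrow(tets)
  keys <- .face_keys(tets)           # 4n keys, rows grouped per tet
  tet_of <- rep(seq_len(n), times = 4)
  ord <- order(keys)
  keys_s <- keys[ord]; tet_s <- tet_of[ord]
  dup <- which(keys_s[-1] == keys_s[-length(keys_s)])
  if (length(dup) == 0) return(seq_len(n))
  g <- igraph::graph_from_edgelist(cbind(tet_s[dup], tet_s[dup + 1]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::components(g)$membership
}

.face_keys <- function(tets) {
  combs <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  M <- max(tets) + 1
  keys <- lapply(combs, function(cb) {
    f <- tets[, cb, drop = FALSE]
    f <- t(apply(f, 1, sort))
    f[, 1] * M * M + f[, 2] * M + f[, 3]
  })
  unlist(keys)
}

.boundary_faces <- function(tets) {
  combs <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  all_faces <- do.call(rbind, lapply(combs, function(cb)
    tets[, cb, drop = FALSE]))
  keys <- .face_keys(tets)
  tab <- table(keys)
  boundary_keys <- as.numeric(names(tab)[tab == 1])
  all_faces[keys %in% boundary_keys, , drop = FALSE]
}

.triangle_areas <- function(points, faces) {
  a <- points[faces[, 1], , drop = FALSE]
  b <- points[faces[, 2], , drop = FALSE] - a
  c <- points[faces[, 3], , drop = FALSE] - a
  cx <- b[, 2] * c[, 3] - b[, 3] * c[, 2]
  cy <- b[, 3] * c[, 1] - b[, 1] * c[, 3]
  cz <- b[, 1] * c[, 2] - b[, 2] * c[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf(
    "<surface_model> alpha = %g: %d points, %d tetrahedra, %d boundary triangles\n",
    x$alpha, x$n_points, nrow(x$tetrahedra), nrow(x$boundary_triangles)))
  cat(sprintf("  volume %.4g voxel^3, surface area %.4g voxel^2\n",
              x$volume, x$surface_area))
  if (!is.null(x$pitch)) {
    cat(sprintf("  volume %.4g um^3 at %.3g um/voxel\n",
                x$volume * x$pitch^3, x$pitch))
  }
  invisible(x)
}

#' Depth below the spheroid surface and normalized distance (NDS)
#'
#' Computes each centroid's minimum Euclidean distance to the boundary
#' triangle mesh of the alpha shape, and the normalized distance to the
#' surface NDS = distance / max(distance): 0 at the surface, 1 at the
#' deepest point of the dataset.
#'
#' @param centroids matrix or data frame of points.
#' @param surface a `surface_model` from [build_alpha_shape()].
#' @return A tibble with `distance` (voxels), `distance_um` (if the surface
#'   carries a pitch) and `nds`.
#' @export
depth_from_surface <- function(centroids, surface) {
  stopifnot(inherits(surface, "surface_model"))
  if (nrow(surface$boundary_triangles) == 0) stop("surface mesh is empty")
  m <- .as_points(centroids)
  d <- point_mesh_dist_cpp(m, surface$points, surface$boundary_triangles)
  dmax <- max(d)
  out <- tibble::tibble(distance = d,
                        nds = if (dmax > 0) d / dmax else rep(0, length(d)))
  if (!is.null(surface$pitch)) out$distance_um <- d * surface$pitch
  out
}

#' Attach NDS to a feature table
#'
#' Convenience wrapper: computes [depth_from_surface()] for the feature
#' centroids and fills the `nds` column.
#'
#' @param features tibble from [extract_features()].
#' @param surface a `surface_model`.
#' @return `features` with `nds` (and `depth`, in voxels) filled in.
#' @export
add_nds <- function(features, surface) {
  dep <- depth_from_surface(features, surface)
  features$nds <- dep$nds
  features$depth <- dep$distance
  features
}

#' Export a surface mesh as ASCII PLY
#'
#' @param surface a `surface_model`.
#' @param path output file path.
#' @export
write_ply <- function(surface, path) {
  stopifnot(inherits(surface, "surface_model"))
  used <- sort(unique(as.vector(surface$boundary_triangles)))
  remap <- integer(max(used)); remap[used] <- seq_along(used) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", length(used)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(surface$boundary_triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  v <- surface$points[used, , drop = FALSE]
  writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
  f <- matrix(remap[surface$boundary_triangles],
              nrow(surface$boundary_triangles))
  writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' Summary of an alpha-shape model as a plain list (JSON-ready)
#' @param surface a `surface_model`.
#' @export
surface_summary <- function(surface) {
  stopifnot(inherits(surface, "surface_model"))
  out <- list(alpha = surface$alpha, n_points = surface$n_points,
              volume_voxels3 = surface$volume,
              surface_area_voxels2 = surface$surface_area,
              centroid = as.numeric(surface$centroid))
  if (!is.null(surface$pitch)) {
    out$pitch_um <- surface$pitch
    out$volume_um3 <- surface$volume * surface$pitch^3
    out$surface_area_um2 <- surface$surface_area * surface$pitch^2
  }
  out
}
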