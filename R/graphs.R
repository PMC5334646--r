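#' Proximity and Delaunay cell graphs
#'
#' `build_pcg()` connects every pair of nuclei centroids whose Euclidean
#' distance is strictly less than the edge threshold (default 40 voxels);
#' the vertex degree of this proximity cell graph (PCG) measures local cell
#' density. `build_dcg()` additionally requires the pair to be joined by an
#' edge of the 3D Delaunay triangulation, approximating physical cell
#' contact; its edge set is a subset of the PCG's at equal threshold. Edge
#' weights are Euclidean distances in voxels.
#'
#' @param centroids matrix or data frame of points (voxel coordinates).
#' @param threshold edge distance threshold in voxels (strict `<`).
#' @param pitch voxel pitch in micrometres for derived micrometre columns
#'   (`NULL` to skip).
#' @param jitter passed to the triangulation to break degeneracies
#'   (`build_dcg` only); coplanar inputs otherwise error with guidance.
#'
#' @return A `cell_graph`: list with `kind` ("PCG" or "DCG"), `vertices`
#'   (tibble `id`, `x`, `y`, `z`), `edges` (tibble `from`, `to`, `weight`),
#'   `threshold` and `pitch`.
#' @export
#' @examples
#' pts <- expand.grid(x = c(0, 20, 40), y = c(0, 20, 40), z = 0:1 * 20)
#' g <- build_pcg(pts, threshold = 25)
#' nrow(g$edges)
build_pcg <- function(centroids, threshold = 40, pitch = NULL) {
  m <- .as_points(centroids)
  if (nrow(m) == 0) stop("no points supplied")
  if (threshold <= 0) stop("threshold must be positive")
  e <- edges_within_cpp(m, threshold)
  .cell_graph("PCG", m, e, threshold, pitch)
}

#' @rdname build_pcg
#' @export
build_dcg <- function(centroids, threshold = 40, pitch = NULL, jitter = 0) {
  m <- .as_points(centroids)
  if (nrow(m) < 4) stop("Delaunay cell graph needs at least 4 points")
  if (threshold <= 0) stop("threshold must be positive")
  mj <- if (jitter > 0) m + matrix(rnorm(length(m), 0, jitter), nrow(m), 3)
        else m
  tets <- tryCatch(delaunay3d_cpp(mj), error = function(e) {
    stop("Delaunay triangulation failed (degenerate/coplanar input?); ",
         "jitter the points (jitter = 1e-6). Underlying error: ",
         conditionMessage(e))
  })
  if (nrow(tets) == 0) {
    stop("degenerate (coplanar?) input: no tetrahedra; jitter the points")
  }
  pairs <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
                 tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs <- unique(pairs)
  w <- sqrt(rowSums((m[pairs[, 1], , drop = FALSE] -
                     m[pairs[, 2], , drop = FALSE])^2))
  sel <- w < threshold
  e <- cbind(from = pairs[sel, 1], to = pairs[sel, 2], weight = w[sel])
  .cell_graph("DCG", m, e, threshold, pitch)
}

.cell_graph <- function(kind, m, e, threshold, pitch) {
  edges <- tibble::tibble(from = as.integer(e[, 1]), to = as.integer(e[, 2]),
                          weight = as.numeric(e[, 3]))
  edges <- edges[order(edges$from, edges$to), ]
  structure(list(
    kind = kind,
    vertices = tibble::tibble(id = seq_len(nrow(m)), x = m[, 1], y = m[, 2],
                              z = m[, 3]),
    edges = edges, threshold = threshold, pitch = pitch
  ), class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %s: %d vertices, %d edges (threshold %g voxels)\n",
              x$kind, nrow(x$vertices), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Per-vertex local density features of a cell graph
#'
#' The vertex degree (number of neighbours) is the local cell density in
#' cells per unit volume; the incident edge weights give the neighbour
#' distance statistics. Vertices with degree 0 have `NA` distance
#' statistics.
#'
#' @param graph a `cell_graph`.
#' @param unit_volume the neighbourhood volume (um^3) a degree of 1
#'   corresponds to; used for the `density_cells_mm3` column.
#' @return A tibble, one row per vertex: `id`, `degree`,
#'   `neighbor_dist_min/max/mean/sd` (voxels), micrometre columns if the
#'   graph has a pitch, and `density_cells_mm3`.
#' @export
density_features <- function(graph, unit_volume = 65450) {
  stopifnot(inherits(graph, "cell_graph"))
  n <- nrow(graph$vertices)
  inc <- c(graph$edges$from, graph$edges$to)
  w <- c(graph$edges$weight, graph$edges$weight)
  deg <- tabulate(inc, nbins = n)
  stats <- vapply(split(w, factor(inc, levels = seq_len(n))), function(v) {
    if (length(v) == 0) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(min(v), max(v), mean(v), if (length(v) > 1) sd(v) else 0)
  }, numeric(4))
  out <- tibble::tibble(
    id = graph$vertices$id,
    degree = deg,
    neighbor_dist_min = unname(stats[1, ]),
    neighbor_dist_max = unname(stats[2, ]),
    neighbor_dist_mean = unname(stats[3, ]),
    neighbor_dist_sd = unname(stats[4, ]),
    density_cells_mm3 = to_cells_per_mm3(deg, unit_volume)
  )
  if (!is.null(graph$pitch)) {
    out$neighbor_dist_mean_um <- out$neighbor_dist_mean * graph$pitch
    out$neighbor_dist_min_um <- out$neighbor_dist_min * graph$pitch
    out$neighbor_dist_max_um <- out$neighbor_dist_max * graph$pitch
  }
  out
}

#' Convert a PCG degree to cells per cubic millimetre
#'
#' A vertex degree counts the neighbours within one unit volume
#' (65,450 um^3 by convention); dividing by the unit volume and scaling by
#' 1e9 um^3/mm^3 converts to cells/mm^3.
#'
#' @param degree vertex degree(s), cells per unit volume.
#' @param unit_volume unit volume in um^3.
#' @return Density in cells/mm^3.
#' @export
#' @examples
#' to_cells_per_mm3(c(35, 70)) # ~5e5 and ~1e6
to_cells_per_mm3 <- function(degree, unit_volume = 65450) {
  if (unit_volume <= 0) stop("unit_volume must be positive")
  stopifnot(all(degree >= 0))
  degree / unit_volume * 1e9
}

#' Convert a cell graph to an igraph object
#'
#' Vertex attributes: coordinates, degree and density features; edge
#' attribute: `weight` (Euclidean distance in voxels).
#'
#' @param graph a `cell_graph`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  df <- density_features(graph)
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = cbind(graph$vertices, df[, setdiff(names(df), "id")]))
  g
}

#' Export a cell graph as GraphML
#' @param graph a `cell_graph`.
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}
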