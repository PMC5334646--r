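# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (plain-R brute force or closed forms).

# voxel count of a rasterized ball (same lattice convention as the renderer:
# voxel centre at integer coordinates, strict interior d2 <= r^2)
oracle_ball_voxels <- function(radius, center = c(0, 0, 0)) {
  r <- ceiling(radius)
  g <- expand.grid(x = (-r:r) + round(center[1]),
                   y = (-r:r) + round(center[2]),
                   z = (-r:r) + round(center[3]))
  sum((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2 <=
        radius^2)
}

# all-pairs proximity edges, strict < threshold; returns sorted (i, j) matrix
oracle_pairs_within <- function(pts, threshold) {
  n <- nrow(pts)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n - 1)) {
    d <- sqrt(colSums((t(pts[(i + 1):n, , drop = FALSE]) - pts[i, ])^2))
    j <- which(d < threshold) + i
    if (length(j) > 0) out <- rbind(out, cbind(i, j))
  }
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  unname(out)
}

# approximate point-to-mesh distance by dense barycentric sampling of every
# triangle (resolution controls the error bound ~ triangle_edge * res)
oracle_mesh_dist <- function(p, verts, faces, res = 0.05) {
  uv <- expand.grid(u = seq(0, 1, by = res), v = seq(0, 1, by = res))
  uv <- uv[uv$u + uv$v <= 1, ]
  best <- Inf
  for (f in seq_len(nrow(faces))) {
    a <- verts[faces[f, 1], ]; b <- verts[faces[f, 2], ]
    c <- verts[faces[f, 3], ]
    pts <- outer(1 - uv$u - uv$v, a) + outer(uv$u, b) + outer(uv$v, c)
    best <- min(best, sqrt(min(colSums((t(pts) - p)^2))))
  }
  best
}

# Meyer-style seeded immersion flood in plain R (small arrays only):
# repeatedly assigns the lowest-intensity unlabelled voxel adjacent to
# exactly one basin; voxels adjacent to >= 2 basins become lines (0).
oracle_priority_flood <- function(f, seeds, mask) {
  d <- dim(f)
  labels <- seeds
  state <- ifelse(seeds > 0, 1L, 0L) # 0 unset, 1 labelled, 2 line
  nbr <- function(i) {
    co <- arrayInd(i, d)
    out <- integer(0)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      cc <- co; cc[ax] <- cc[ax] + s
      if (cc[ax] >= 1 && cc[ax] <= d[ax]) {
        out <- c(out, cc[1] + d[1] * (cc[2] - 1 + d[2] * (cc[3] - 1)))
      }
    }
    out
  }
  # frontier: unlabelled voxels adjacent to a labelled one
  in_frontier <- rep(FALSE, length(f))
  for (i in which(state == 1L)) in_frontier[nbr(i)] <- TRUE
  in_frontier[state != 0L] <- FALSE
  order_key <- order(f, seq_along(f)) # intensity, then index (determinism)
  repeat {
    cand <- which(in_frontier)
    if (length(cand) == 0) break
    i <- cand[which.min(match(cand, order_key))]
    nb <- nbr(i)
    labs <- unique(labels[nb][state[nb] == 1L])
    if (length(labs) == 1L) {
      labels[i] <- labs
      state[i] <- 1L
      fresh <- nb[state[nb] == 0L]
      in_frontier[fresh] <- TRUE
    } else {
      labels[i] <- 0L
      state[i] <- 2L
    }
    in_frontier[i] <- FALSE
  }
  labels[!mask] <- 0L
  labels
}

# scipy-based Delaunay edge oracle (pre-installed python); returns a sorted
# two-column matrix of 1-based vertex pairs
oracle_scipy_delaunay_edges <- function(pts) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(unname(as.matrix(pts)), fin, digits = NA)
  script <- paste(
    "import json, sys, itertools",
    "from scipy.spatial import Delaunay",
    sprintf("pts = json.load(open('%s'))", fin),
    "tri = Delaunay(pts)",
    "edges = set()",
    "for s in tri.simplices:",
    "    for a, b in itertools.combinations(sorted(int(v) for v in s), 2):",
    "        edges.add((a + 1, b + 1))",
    sprintf("json.dump(sorted(edges), open('%s', 'w'))", fout),
    sep = "\n")
  status <- system2("python", c("-c", shQuote(script)))
  stopifnot(status == 0)
  m <- jsonlite::read_json(fout, simplifyVector = TRUE)
  if (is.list(m)) m <- do.call(rbind, m)
  m <- matrix(as.numeric(m), ncol = 2)
  unname(m[order(m[, 1], m[, 2]), , drop = FALSE])
}

# sorted edge matrix of a cell_graph for comparison
graph_edge_matrix <- function(g) {
  e <- cbind(as.numeric(g$edges$from), as.numeric(g$edges$to))
  unname(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

# small uniform-ball point cloud (rejection-free radial sampling)
ball_cloud <- function(n, radius, seed) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u / sqrt(rowSums(u^2)) * radius * runif(n)^(1 / 3)
}
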