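test_that("outlier removal keeps the largest proximity component", {
  set.seed(1)
  cluster <- matrix(runif(300, 0, 20), ncol = 3)
  # one tight cluster is untouched
  expect_identical(nrow(remove_outliers(cluster)), 100L)
  # a lone point 50 voxels away is removed (brute-force component oracle:
  # its nearest cluster point is farther than the threshold)
  lone <- c(70, 70, 70)
  d_lone <- min(sqrt(colSums((t(cluster) - lone)^2)))
  expect_gt(d_lone, 20)
  suppressMessages(kept <- remove_outliers(rbind(cluster, lone)))
  expect_identical(nrow(kept), 100L)
  expect_identical(attr(kept, "removed"), 101L)
  # two components of size 100 and 3: the triplet goes
  triplet <- matrix(rep(c(90, 90, 90), 3), ncol = 3, byrow = TRUE) +
    matrix(runif(9, 0, 2), ncol = 3)
  suppressMessages(kept2 <- remove_outliers(rbind(cluster, triplet)))
  expect_identical(nrow(kept2), 100L)
  expect_error(remove_outliers(cluster[0, ]), "no points")
})

test_that("alpha-shape limits match the closed-form oracles", {
  # alpha above every circumradius -> convex hull; cube + interior points
  # tile the unit cube exactly (hull volume 1 by construction)
  set.seed(2)
  pts <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)),
               matrix(runif(150), ncol = 3))
  shape <- build_alpha_shape(pts, alpha = 1e6, jitter = 1e-9)
  expect_equal(shape$volume, 1, tolerance = 1e-6)
  # unit regular tetrahedron: volume 1/(6*sqrt(2))
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  s_tet <- build_alpha_shape(tet, alpha = 10)
  expect_equal(s_tet$volume, 1 / (6 * sqrt(2)), tolerance = 1e-9)
  expect_identical(nrow(s_tet$boundary_triangles), 4L)
  # 5,000 uniform points in a radius-50 ball at the canonical alpha = 90:
  # volume within 10% of (4/3) pi 50^3
  pb <- ball_cloud(5000, 50, seed = 3)
  s_ball <- build_alpha_shape(pb, alpha = 90)
  expect_lt(abs(s_ball$volume - 4 / 3 * pi * 50^3) / (4 / 3 * pi * 50^3),
            0.1)
  # degenerate inputs error
  expect_error(build_alpha_shape(tet[1:3, ], alpha = 10), "at least 4")
})

test_that("alpha-shape volume is monotone in alpha and bounded by the hull", {
  pb <- ball_cloud(600, 30, seed = 4)
  alphas <- c(5, 10, 20, 40, 1e5)
  vols <- sapply(alphas, function(a)
    tryCatch(build_alpha_shape(pb, alpha = a)$volume, error = function(e) 0))
  expect_true(all(diff(vols) >= -1e-9))
  expect_lte(max(vols), vols[length(vols)] + 1e-9)
})

test_that("boundary faces belong to exactly one kept tetrahedron", {
  pb <- ball_cloud(300, 25, seed = 5)
  shape <- build_alpha_shape(pb, alpha = 90)
  keys <- spheroidr:::.face_keys(shape$tetrahedra)
  counts <- table(keys)
  # parity: every face of the complex is shared by at most 2 tetrahedra
  expect_lte(max(counts), 2)
  expect_identical(nrow(shape$boundary_triangles),
                   as.integer(sum(counts == 1)))
})

test_that("depth_from_surface matches exhaustive point-to-triangle search", {
  pb <- ball_cloud(120, 25, seed = 6)
  shape <- build_alpha_shape(pb, alpha = 90)
  # a boundary vertex has distance exactly 0
  v0 <- shape$points[shape$boundary_triangles[1, 1], , drop = FALSE]
  expect_equal(depth_from_surface(v0, shape)$distance, 0, tolerance = 1e-9)
  expect_equal(depth_from_surface(v0, shape)$nds, 0)
  # dense-sampling oracle on a handful of interior query points
  set.seed(7)
  queries <- ball_cloud(5, 15, seed = 7)
  got <- depth_from_surface(queries, shape)$distance
  for (i in seq_len(nrow(queries))) {
    ref <- oracle_mesh_dist(queries[i, ], shape$points,
                            shape$boundary_triangles, res = 0.05)
    expect_equal(got[i], ref, tolerance = 0.3)
    expect_lte(got[i], ref + 1e-9) # sampling oracle overestimates
  }
})

test_that("NDS is anchored at 0 on the surface and 1 at the deepest point", {
  pb <- rbind(ball_cloud(800, 50, seed = 8), c(0, 0, 0)) # centre included
  shape <- build_alpha_shape(pb, alpha = 90)
  dep <- depth_from_surface(pb, shape)
  expect_true(all(dep$nds >= 0 & dep$nds <= 1))
  expect_equal(max(dep$nds), 1)
  # the centre of the ball is the deepest point, ~50 voxels from the surface
  centre_idx <- nrow(pb)
  expect_equal(dep$distance[centre_idx], 50, tolerance = 2.5)
  expect_equal(dep$nds[centre_idx], 1)
  # a point midway to the surface sits near NDS 0.5
  mid <- matrix(c(25, 0, 0), 1)
  expect_equal(depth_from_surface(mid, shape)$distance, 25, tolerance = 2.5)
})

test_that("surface export and summary are consistent", {
  pb <- ball_cloud(200, 20, seed = 9)
  shape <- build_alpha_shape(pb, alpha = 90, pitch = 0.65)
  tf <- tempfile(fileext = ".ply")
  write_ply(shape, tf)
  lines <- readLines(tf)
  expect_identical(lines[1], "ply")
  nv <- as.integer(sub("element vertex ", "",
                       grep("element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("element face", lines, value = TRUE)))
  expect_identical(nf, nrow(shape$boundary_triangles))
  expect_identical(length(lines), 9L + nv + nf)
  smry <- surface_summary(shape)
  expect_equal(smry$volume_um3, shape$volume * 0.65^3)
  unlink(tf)
})
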