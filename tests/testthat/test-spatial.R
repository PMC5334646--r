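test_that("radial profile bins are exact for a constant feature", {
  set.seed(20)
  nds <- runif(200)
  prof <- radial_profile(rep(7, 200), nds, n_bins = 10)
  expect_identical(nrow(prof), 10L)
  expect_true(all(prof$mean[prof$n > 0] == 7))
  expect_true(all(prof$se[prof$n > 0] == 0))
  expect_identical(sum(prof$n), 200L)
  # empty bins reported as missing
  prof2 <- radial_profile(c(1, 2), c(0.05, 0.95), n_bins = 10)
  expect_true(is.na(prof2$mean[5]))
  expect_identical(prof2$n[5], 0L)
})

test_that("region summary reproduces the printed thickness arithmetic", {
  # medium spheroids: radius 191.3 um, outer/core boundary at 0.75 NDS
  dep_m <- tibble::tibble(distance = c(0.1, 150, 294.3), nds = c(0, 0.5, 1))
  rs_m <- summarize_regions(dep_m, density = c(45, 61, 56), core_cut = 0.75,
                            pitch = 0.65)
  expect_equal(rs_m$mean_radius_um, 294.3 * 0.65) # 191.295
  expect_equal(round_half_away(rs_m$outer_thickness_um, 1), 143.5)
  # large spheroids: radius 213.7 um, boundary at 0.5 NDS
  dep_l <- tibble::tibble(distance = c(0.1, 150, 328.769), nds = c(0, 0.5, 1))
  rs_l <- summarize_regions(dep_l, density = c(45, 65, 53), core_cut = 0.5,
                            pitch = 0.65)
  expect_equal(rs_l$mean_radius_um, 213.7, tolerance = 1e-3)
  # 0.5 x 213.7 = 106.85 um sits exactly on the rounding boundary; the
  # reported value agrees with the printed 106.8 within the 0.1 um
  # rounding ambiguity
  expect_lt(abs(rs_l$outer_thickness_um - 106.85), 0.01)
  expect_lt(abs(round_half_away(rs_l$outer_thickness_um, 1) - 106.8), 0.11)
})

test_that("region labels partition nuclei by the NDS cuts", {
  dep <- tibble::tibble(distance = c(5, 30, 70), nds = c(0.05, 0.3, 0.7))
  rs <- summarize_regions(dep, density = c(1, 2, 3), surface_cut = 0.1,
                          core_cut = 0.5)
  expect_identical(as.character(rs$assignment$region),
                   c("surface", "outer", "core"))
  expect_identical(sum(rs$regions$n), 3L)
  expect_error(summarize_regions(dep, 1:3, surface_cut = 0.5, core_cut = 0.3),
               "exceed")
})

test_that("outer thickness is linear in radius at fixed cut", {
  t1 <- summarize_regions(tibble::tibble(distance = c(0, 100), nds = c(0, 1)),
                          c(1, 1), core_cut = 0.75, pitch = 1)
  t2 <- summarize_regions(tibble::tibble(distance = c(0, 200), nds = c(0, 1)),
                          c(1, 1), core_cut = 0.75, pitch = 1)
  expect_equal(t2$outer_thickness_um / t1$outer_thickness_um, 2)
})

test_that("RCP samples are uniform, contained and non-overlapping", {
  pb <- ball_cloud(800, 50, seed = 21)
  shape <- build_alpha_shape(pb, alpha = 90)
  set.seed(1)
  one <- rcp_sample(shape, n_cells = 1, sphere_radius = 6)
  expect_identical(nrow(one), 1L)
  expect_lt(sqrt(sum(one^2)), 50.5) # inside the ball-shaped alpha shape
  # 150 spheres of radius 6 in the radius-50 ball: a feasible analogue of
  # the dense-packing case (500 such spheres would exceed the random-
  # sequential jamming limit)
  set.seed(2)
  pts <- as.matrix(rcp_sample(shape, n_cells = 150, sphere_radius = 6))
  expect_gte(min(dist(pts)), 12)
  expect_true(all(sqrt(rowSums(pts^2)) < 50.5))
  expect_true(all(depth_from_surface(pts, shape)$distance >= 0))
  # octant counts consistent with uniformity (chi-square, fixed seed)
  set.seed(3)
  u <- as.matrix(rcp_sample(shape, n_cells = 2000, sphere_radius = 1))
  octant <- 1 + (u[, 1] > 0) + 2 * (u[, 2] > 0) + 4 * (u[, 3] > 0)
  p <- stats::chisq.test(tabulate(octant, 8))$p.value
  expect_gt(p, 0.01)
  # infeasible packings error out with the achieved count context
  expect_error(rcp_sample(shape, n_cells = 5000, sphere_radius = 6),
               "infeasible")
})

test_that("RCP ensembles honour the replicate count and a fixed seed", {
  pb <- ball_cloud(500, 40, seed = 22)
  shape <- build_alpha_shape(pb, alpha = 90)
  set.seed(9)
  ens <- rcp_profile_ensemble(shape, n_cells = 80, sphere_radius = 6,
                              n_reps = 10, threshold = 20, n_bins = 5)
  expect_identical(attr(ens, "n_reps"), 10)
  expect_identical(max(attr(ens, "replicates")$replicate), 10L)
  set.seed(9)
  ens2 <- rcp_profile_ensemble(shape, n_cells = 80, sphere_radius = 6,
                               n_reps = 10, threshold = 20, n_bins = 5)
  expect_equal(ens$mean, ens2$mean)
  expect_equal(ens$se, ens2$se)
})

test_that("PAM recovers well-separated groups and the printed group sizes", {
  # three tight synthetic triplets -> exact recovery
  df <- data.frame(
    cell_number = c(10, 11, 12, 100, 101, 102, 500, 501, 502),
    volume = c(10, 11, 12, 100, 101, 102, 500, 501, 502) * 1000)
  cl <- cluster_datasets(df, k = 3)
  expect_identical(cl$group, rep(1:3, each = 3))
  # sixteen datasets drawn at the printed group means/SDs (cells and um^3)
  set.seed(42)
  cells <- c(rnorm(9, 4977, 2766), rnorm(3, 25582, 454), rnorm(4, 34742, 2941))
  vols <- c(rnorm(9, 6.0e6, 3.1e6), rnorm(3, 2.7e7, 0.04e7),
            rnorm(4, 4.0e7, 0.2e7))
  cl16 <- cluster_datasets(data.frame(cell_number = cells, volume = vols),
                           k = 3)
  expect_identical(as.integer(table(cl16$group)), c(9L, 3L, 4L))
  expect_identical(cl16$group[1:9], rep(1L, 9))
  expect_error(cluster_datasets(df, k = 10), "exceeds")
})

test_that("exhaustive PAM equals the cluster::pam objective for n <= 10", {
  set.seed(23)
  df <- data.frame(cell_number = runif(10, 0, 100), volume = runif(10, 0, 1e5))
  ours <- cluster_datasets(df, k = 3)
  X <- scale(cbind(df$cell_number, df$volume))
  D2 <- as.matrix(dist(X))^2
  ref <- cluster::pam(stats::as.dist(D2), k = 3, diss = TRUE)
  obj <- function(med) sum(apply(D2[, med, drop = FALSE], 1, min))
  expect_equal(obj(attr(ours, "medoids")), obj(ref$id.med), tolerance = 1e-9)
})

test_that("volume-cell-number fit matches the normal-equation oracle", {
  # exact line through the origin
  fit0 <- fit_volume_cell_line(1:10, 1000 * (1:10))
  expect_equal(fit0$slope, 1000)
  expect_equal(fit0$intercept, 0, tolerance = 1e-9)
  expect_equal(fit0$pearson_r, 1)
  # OLS equals the closed-form normal equations on random data
  set.seed(24)
  x <- runif(20, 1000, 40000)
  y <- 1118 * x + rnorm(20, 0, 1e6)
  fit <- fit_volume_cell_line(x, y)
  slope_ref <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  expect_equal(fit$slope, slope_ref, tolerance = 1e-12)
  expect_error(fit_volume_cell_line(rep(5, 4), 1:4), "variance")
  # broom-style accessors
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "cell_number"))
  gl <- glance(fit)
  expect_equal(gl$slope, fit$slope)
  expect_identical(gl$nobs, 20L)
})

test_that("slope recovery at the literature value lies within its SE band", {
  set.seed(25)
  cells <- runif(16, 1000, 40000)
  vols <- 1118 * cells * (1 + rnorm(16, 0, 0.1)) # 10% multiplicative noise
  fit <- fit_volume_cell_line(cells, vols)
  se <- tidy(fit)$std.error[2]
  expect_lt(abs(fit$slope - 1118), 2 * se)
})

test_that("transition-point helper finds a programmed profile step", {
  nds <- seq(0.025, 0.975, by = 0.05)
  vals <- ifelse(nds < 0.5, 60, 40)
  prof <- radial_profile(rep(vals, each = 20), rep(nds, each = 20),
                         n_bins = 20)
  expect_lt(abs(suggest_transition(prof) - 0.5), 0.1)
})
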