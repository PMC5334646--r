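test_that("constant images give an empty mask via the degenerate Otsu rule", {
  img <- voxel_image(array(0.4, c(30, 30, 30)), 0.65)
  expect_warning(mask <- initial_segmentation(img), "constant image")
  expect_false(any(mask$voxels))
  set.seed(99)
  small <- voxel_image(array(runif(1000), c(10, 10, 10)), 0.65)
  expect_error(initial_segmentation(small), "window")
})

test_that("initial segmentation covers every ground-truth nucleus centre", {
  ph <- generate_phantom(phantom_spec(n_nuclei = 40, spheroid_radius = 28,
                                      r_min = 3, r_max = 5, seed = 2))
  img <- prepare_image(ph$stack, z_scaling_factor = 1,
                       image_scaling_factor = 1)
  mask <- initial_segmentation(img)
  idx <- cbind(round(ph$centroids$y) + 1, round(ph$centroids$x) + 1,
               round(ph$centroids$z) + 1)
  expect_true(all(mask$voxels[idx]))
})

test_that("enclosed cavities below the hole threshold are filled", {
  # bright ball with a 100-voxel dark interior cavity
  d <- c(28, 28, 28)
  arr <- array(0, d)
  for (z in 1:28) for (x in 1:28) for (y in 1:28) {
    r2 <- (x - 14.5)^2 + (y - 14.5)^2 + (z - 14.5)^2
    if (r2 < 10^2) arr[y, x, z] <- 0.9
  }
  cav <- which(arr > 0, arr.ind = TRUE)
  ctr <- cav[(cav[, 1] - 14.5)^2 + (cav[, 2] - 14.5)^2 +
               (cav[, 3] - 14.5)^2 < 3.2^2, ]
  expect_lt(nrow(ctr), 250)      # cavity smaller than the hole threshold
  expect_gt(nrow(ctr), 50)
  arr[ctr] <- 0                  # carve the cavity
  img <- voxel_image(arr, 0.65)
  mask <- initial_segmentation(img)
  expect_true(all(mask$voxels[ctr]))   # refilled
  # oracle: the cavity is a connected component of the complement
  comp <- array(spheroidr:::label_components_cpp(
    as.vector(arr == 0), as.integer(d), 6L), d)
  sizes <- table(comp[comp > 0])
  expect_true(any(sizes == nrow(ctr)))
})

test_that("multiscale LoG response behaves like a calibrated blob detector", {
  cfg <- spheroid_config()
  # constant image -> exactly zero response
  flat <- voxel_image(array(0.5, c(20, 20, 20)), 0.65, "inverted")
  expect_equal(max(abs(multiscale_log(flat, cfg))), 0)
  expect_error(
    multiscale_log(flat, spheroid_config(NucleiSeedDetectionMinRadius = 7)),
    "MinRadius")
  # the sigma maximizing the centre response of a radius-4.5 ball sits at
  # r/sqrt(2) for the sigma^3-normalized LoG (dense numerical sweep oracle)
  d <- c(36L, 36L, 36L)
  ball <- array(0, d)
  for (z in 1:36) for (x in 1:36) for (y in 1:36) {
    if ((x - 18.5)^2 + (y - 18.5)^2 + (z - 18.5)^2 < 4.5^2) ball[y, x, z] <- 1
  }
  inv <- as.numeric(1 - ball)
  sigmas <- seq(1.6, 4.4, by = 0.2)
  centre <- sapply(sigmas, function(s) {
    g <- spheroidr:::.gaussian_kernel(s, ceiling(3.5 * s))
    g2 <- spheroidr:::.gaussian_d2_kernel(s, ceiling(3.5 * s))
    L <- spheroidr:::separable_filter_cpp(inv, d, g2, g, g) +
      spheroidr:::separable_filter_cpp(inv, d, g, g2, g) +
      spheroidr:::separable_filter_cpp(inv, d, g, g, g2)
    s^3 * array(L, d)[18, 18, 18]
  })
  scale_step <- diff(attr(multiscale_log(
    voxel_image(1 - ball, 1, "inverted"), cfg), "sigmas"))[1]
  expect_lt(abs(sigmas[which.max(centre)] - 4.5 / sqrt(2)), scale_step)
  # sigma^3 normalization weights larger blobs proportionally to radius:
  # equal-contrast balls of radius 3 and 6 respond ~ in ratio 1:2
  d2 <- c(48L, 48L, 24L)
  two <- array(0, d2)
  for (z in 1:24) for (x in 1:48) for (y in 1:48) {
    if ((x - 12.5)^2 + (y - 24.5)^2 + (z - 12.5)^2 < 3^2) two[y, x, z] <- 1
    if ((x - 36.5)^2 + (y - 24.5)^2 + (z - 12.5)^2 < 6^2) two[y, x, z] <- 1
  }
  r <- multiscale_log(voxel_image(1 - two, 1, "inverted"), cfg)
  ratio <- max(r[, 1:24, ]) / max(r[, 25:48, ])
  expect_gt(ratio, 0.5 * 0.8)
  expect_lt(ratio, 0.5 * 1.25)
})

test_that("marker detection finds one marker inside each separated nucleus", {
  # zero response -> zero markers
  mask <- binary_mask(array(TRUE, c(8, 8, 8)), 0.65)
  mk0 <- detect_markers(array(0, c(8, 8, 8)), mask)
  expect_identical(mk0$component_count, 0L)
  # well-separated balls -> one marker per ball, inside it
  ph <- generate_phantom(phantom_spec(n_nuclei = 50, spheroid_radius = 40,
                                      r_min = 3, r_max = 4,
                                      min_center_gap = 1.8, noise_sd = 0.02,
                                      seed = 3))
  img <- prepare_image(ph$stack, z_scaling_factor = 1,
                       image_scaling_factor = 1)
  cfg <- spheroid_config()
  m <- initial_segmentation(img, cfg)
  mk <- detect_markers(multiscale_log(invert(img), cfg), m, cfg)
  expect_identical(mk$component_count, 50L)
  # every marker component contains exactly one GT nucleus (markers live
  # inside nuclei: each GT centre's nearest marker component is unique)
  comp_at <- mk$components[cbind(round(ph$centroids$y) + 1,
                                 round(ph$centroids$x) + 1,
                                 round(ph$centroids$z) + 1)]
  expect_setequal(comp_at[comp_at > 0], seq_len(50))
})

test_that("dilation merges extended maxima closer than twice the radius", {
  d <- c(11L, 11L, 5L)
  resp <- array(0, d)
  resp[6, 4, 3] <- 1
  resp[6, 7, 3] <- 1 # 3 voxels apart in x
  mask <- binary_mask(array(TRUE, d), 1)
  mk <- detect_markers(resp, mask, spheroid_config())
  expect_identical(mk$component_count, 1L)
  # brute-force dilation oracle: the union of two digital radius-2 balls
  # whose centres are 3 apart is smaller than twice one ball (they overlap,
  # hence form a single 26-connected component)
  ball_offsets <- subset(expand.grid(dy = -2:2, dx = -2:2, dz = -2:2),
                         dy^2 + dx^2 + dz^2 <= 4)
  b1 <- sprintf("%d_%d_%d", 6 + ball_offsets$dy, 4 + ball_offsets$dx,
                3 + ball_offsets$dz)
  b2 <- sprintf("%d_%d_%d", 6 + ball_offsets$dy, 7 + ball_offsets$dx,
                3 + ball_offsets$dz)
  expect_lt(length(union(b1, b2)), 2 * length(b1))
  dil <- array(spheroidr:::dilate_ball_cpp(as.vector(resp > 0), d, 2), d)
  expect_identical(sum(dil), length(union(b1, b2)))
})

test_that("watershed splits the dumbbell into two marker-consistent basins", {
  fx <- generate_toy_fixture("dumbbell")
  img <- prepare_image(fx$stack, z_scaling_factor = 1,
                       image_scaling_factor = 1)
  cfg <- spheroid_config(NucleiMinCount = 50)
  seg <- segment(img, cfg)
  expect_identical(seg$n_objects, 2L)
  cen <- label_centroids(seg)
  m <- match_centroids(fx$centroids, cen, radius = 3)
  expect_identical(m$tp, 2L)
  # split near the neck plane x = 15.5: label changes across it
  lab_left <- seg$labels[16, 8, 16]
  lab_right <- seg$labels[16, 25, 16]
  expect_true(lab_left != lab_right && lab_left > 0 && lab_right > 0)
})

test_that("watershed agrees with a plain-R priority-flood oracle", {
  fx <- generate_toy_fixture("dumbbell")
  img <- prepare_image(fx$stack, z_scaling_factor = 1,
                       image_scaling_factor = 1)
  # restrict to a small crop around the dumbbell for the O(n^2) oracle
  crop <- list(9:24, 3:30, 9:24)
  f <- img$voxels[crop[[1]], crop[[2]], crop[[3]]]
  inv <- 1 - f
  mask <- f > 0.3
  seeds <- array(0L, dim(f))
  seeds[8, 9, 8] <- 1L   # centre of left ball in crop coordinates
  seeds[8, 19, 8] <- 2L  # centre of right ball
  ours <- spheroidr:::watershed_cpp(as.numeric(inv), as.integer(seeds),
                                    as.integer(dim(f)), 6L)
  ours <- array(ours, dim(f)); ours[!mask] <- 0L
  ref <- array(oracle_priority_flood(inv, seeds, mask), dim(f))
  labelled <- ours > 0 & ref > 0
  agree <- mean(ours[labelled] == ref[labelled])
  expect_gt(agree, 0.99)
  expect_identical(sort(unique(as.vector(ours[mask]))),
                   sort(unique(as.vector(ref[mask]))))
})

test_that("volume gates drop objects outside [min, max] count", {
  d <- c(24, 24, 12)
  arr <- array(0, d)
  arr[2:11, 2:11, 2:6] <- 0.9   # 500-voxel block
  arr[15:18, 15:19, 2:6] <- 0.9 # 100-voxel block (< 250)
  img <- voxel_image(arr, 0.65)
  cfg <- spheroid_config(NucleiThresholdRange = 11)
  seg <- segment(img, cfg)
  vols <- tabulate(seg$labels[seg$labels > 0], nbins = max(1, seg$n_objects))
  expect_true(all(vols >= 250 & vols <= 42500))
  expect_identical(seg$n_objects, 1L)
})

test_that("segmentation structure invariants hold on a packed phantom", {
  ph <- generate_phantom(phantom_spec(n_nuclei = 60, spheroid_radius = 38,
                                      seed = 4))
  img <- prepare_image(ph$stack, z_scaling_factor = 1,
                       image_scaling_factor = 1)
  cfg <- spheroid_config()
  mask <- initial_segmentation(img, cfg)
  inv <- invert(img)
  mk <- detect_markers(multiscale_log(inv, cfg), mask, cfg)
  seg <- watershed_decompose(inv, mk, mask, cfg)
  # objects cannot outnumber markers
  expect_lte(seg$n_objects, mk$component_count)
  # labelled foreground is a subset of the initial mask
  expect_true(all(mask$voxels[seg$labels > 0]))
  # every object contains voxels of exactly one marker component
  for (lab in seq_len(seg$n_objects)) {
    comps <- unique(mk$components[seg$labels == lab & mk$components > 0])
    expect_lte(length(comps), 1)
  }
  # all volumes within gates
  vols <- tabulate(seg$labels[seg$labels > 0], nbins = seg$n_objects)
  expect_true(all(vols >= cfg$NucleiMinCount & vols <= cfg$NucleiMaxCount))
})

test_that("segmentation is deterministic and intensity-scale invariant", {
  ph <- generate_phantom(phantom_spec(n_nuclei = 25, spheroid_radius = 26,
                                      r_min = 3, r_max = 5, seed = 6))
  img <- prepare_image(ph$stack, z_scaling_factor = 1,
                       image_scaling_factor = 1)
  s1 <- segment(img)
  s2 <- segment(img)
  expect_identical(s1$labels, s2$labels)
  # global affine rescale: halving raw intensities is erased by the
  # min-max normalization in prepare_image
  half <- ph$stack
  half$planes <- half$planes * 0.5
  s3 <- segment(prepare_image(half, z_scaling_factor = 1,
                              image_scaling_factor = 1))
  expect_identical(s1$n_objects, s3$n_objects)
})

test_that("empty images segment to zero nuclei", {
  ph <- generate_phantom(phantom_spec(n_nuclei = 0, spheroid_radius = 12,
                                      noise_sd = 0.02, seed = 8))
  img <- prepare_image(ph$stack, z_scaling_factor = 1,
                       image_scaling_factor = 1)
  seg <- suppressWarnings(segment(img))
  expect_identical(seg$n_objects, 0L)
  expect_identical(extract_features(seg, img), spheroidr:::.empty_feature_table())
})
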