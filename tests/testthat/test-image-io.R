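test_that("TIFF round-trip is lossless for 8- and 16-bit stacks", {
  for (bits in c(8L, 16L)) {
    set.seed(bits)
    maxv <- 2^bits - 1
    planes <- array(sample(0:maxv, 10 * 64 * 64, replace = TRUE),
                    c(64, 64, 10))
    st <- raw_stack(planes, lateral_pitch = 0.325, axial_pitch = 1.29,
                    bit_depth = bits)
    tf <- tempfile(fileext = ".tif")
    write_stack(st, tf)
    back <- read_stack(tf)
    expect_identical(dim(back$planes), c(64L, 64L, 10L))
    expect_equal(back$planes, planes)
    expect_identical(back$bit_depth, bits)
    # pitches restored from the sidecar
    expect_equal(back$lateral_pitch, 0.325)
    expect_equal(back$axial_pitch, 1.29)
    unlink(c(tf, paste0(tf, ".yaml")))
  }
})

test_that("phantom stack survives a write/read cycle byte-identically", {
  ph <- generate_phantom(phantom_spec(n_nuclei = 8, spheroid_radius = 12,
                                      r_min = 2, r_max = 3, seed = 5))
  tf <- tempfile(fileext = ".tif")
  write_stack(ph$stack, tf)
  back <- read_stack(tf)
  expect_equal(back$planes, ph$stack$planes)
  unlink(c(tf, paste0(tf, ".yaml")))
})

test_that("unreadable and malformed files raise I/O errors", {
  expect_error(read_stack(tempfile()), "no such file")
  # truncated file: valid header, then cut off
  good <- tempfile(fileext = ".tif")
  st <- raw_stack(array(1, c(16, 16, 2)), 0.325, 1.29, bit_depth = 8)
  write_stack(st, good, sidecar = FALSE)
  bad <- tempfile(fileext = ".tif")
  bytes <- readBin(good, "raw", file.size(good))
  writeBin(bytes[1:200], bad)
  expect_error(read_stack(bad), "truncated")
  # not a TIFF at all
  txt <- tempfile(fileext = ".tif")
  writeLines("not an image", txt)
  expect_error(read_stack(txt), "not a TIFF")
  # multi-channel (RGB) data is rejected: patch SamplesPerPixel to 3
  rgb <- tempfile(fileext = ".tif")
  bytes <- readBin(good, "raw", file.size(good))
  # tag 277 (0x0115) little-endian: 15 01; value short at offset +8
  idx <- which(bytes == as.raw(0x15))
  for (i in idx) {
    if (i < length(bytes) && bytes[i + 1] == as.raw(0x01)) {
      bytes[i + 8] <- as.raw(0x03)
    }
  }
  writeBin(bytes, rgb)
  expect_error(read_stack(rgb), "multi-channel")
  unlink(c(good, bad, txt, rgb))
})

test_that("prepare_image produces the documented isotropic pitches", {
  # instrument defaults: 6.5 um camera pixels / 20x -> 0.325 um, axial 1.29
  expect_equal(6.5 / 20, 0.325)
  set.seed(1)
  st <- raw_stack(array(runif(40 * 40 * 6, 0, 255), c(40, 40, 6)),
                  lateral_pitch = 0.325, axial_pitch = 1.29, bit_depth = 8)
  iso <- prepare_image(st, image_scaling_factor = 1)
  expect_equal(iso$pitch, 0.325)
  # z axis upsampled by ~1.29/0.325 = 3.97
  expect_equal(dim(iso$voxels)[3],
               round((6 - 1) * 1.29 / 0.325) + 1)
  down <- prepare_image(st, image_scaling_factor = 0.5)
  expect_equal(down$pitch, 0.65)
  expect_equal(dim(down$voxels)[1:2], c(20L, 20L))
  expect_true(all(down$voxels >= 0 & down$voxels <= 1))
})

test_that("prepare_image with unit factors is the identity on [0,1] data", {
  arr <- array(seq(0, 255, length.out = 8 * 8 * 4), c(8, 8, 4))
  st <- raw_stack(arr, lateral_pitch = 1, axial_pitch = 1, bit_depth = 8)
  img <- prepare_image(st, z_scaling_factor = 1, image_scaling_factor = 1)
  expect_equal(img$voxels, arr / 255, tolerance = 1e-12)
  expect_error(prepare_image(st, z_scaling_factor = -1), "positive")
})

test_that("monotone interpolation preserves intensity ordering at sample points", {
  # a stack increasing in z stays increasing after z interpolation
  arr <- array(rep(1:5, each = 36), c(6, 6, 5))
  st <- raw_stack(arr, lateral_pitch = 1, axial_pitch = 2, bit_depth = 8)
  img <- prepare_image(st, image_scaling_factor = 1)
  prof <- img$voxels[3, 3, ]
  expect_true(all(diff(prof) >= 0))
})

test_that("invert is an involution that swaps extremes", {
  expect_equal(invert(voxel_image(array(0, c(3, 3, 3)), 1))$voxels,
               array(1, c(3, 3, 3)))
  set.seed(2)
  img <- voxel_image(array(runif(4^3), c(4, 4, 4)), 0.65)
  expect_equal(invert(invert(img))$voxels, img$voxels)
  expect_equal(max(invert(img)$voxels), 1 - min(img$voxels))
  expect_identical(invert(img)$provenance, "inverted")
})

test_that("configuration carries the canonical defaults and round-trips YAML", {
  cfg <- spheroid_config()
  expect_equal(cfg$ImageScalingFactor, 0.5)
  expect_equal(cfg$NucleiFilterRange, 3)
  expect_equal(cfg$NucleiThresholdRange, 25)
  expect_equal(cfg$NucleiBackgroundFactor, 0.25)
  expect_equal(cfg$NucleiSeedDetectionMinRadius, 3)
  expect_equal(cfg$NucleiSeedDetectionMaxRadius, 6)
  expect_equal(cfg$NucleiSeedDilation, 2)
  expect_equal(cfg$NucleiMinCount, 250)
  expect_equal(cfg$NucleiMaxCount, 42500)
  expect_equal(cfg$OutlierDistanceThreshold, 20)
  expect_equal(cfg$Alpha, 90)
  expect_equal(cfg$EdgeDistanceThreshold, 40)
  tf <- tempfile(fileext = ".yaml")
  write_config(spheroid_config(Alpha = 120), tf)
  expect_equal(read_config(tf)$Alpha, 120)
  expect_error(spheroid_config(NoSuchKey = 1), "unknown configuration")
  unlink(tf)
})
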