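test_that("resample output shape follows round(n * s / t)", {
  vol <- ct_volume(array(0, c(96, 96, 96)), spacing = rep(1.2, 3))
  r <- resample_isotropic(vol, 1.6)
  expect_equal(dim(r$data), rep(72L, 3))          # 96 * 1.2 / 1.6 = 72
  expect_equal(r$spacing, rep(1.6, 3))
  vol2 <- ct_volume(array(0, c(10, 10, 3)), spacing = c(1, 1, 5))
  expect_equal(dim(resample_isotropic(vol2, 2)$data), c(5L, 5L, 8L))
})

test_that("resampling a constant volume returns the same constant", {
  for (mode in c("trilinear", "nearest")) {
    vol <- ct_volume(array(37.5, c(20, 18, 16)), spacing = c(2, 2, 2.5))
    r <- resample_isotropic(vol, 1.6, mode)
    expect_true(all(abs(r$data - 37.5) < 1e-12))
  }
})

test_that("nearest-mode resampling keeps masks binary and conserves volume", {
  # physical volume before vs after, 20 random blobs
  set.seed(21)
  errs <- replicate(20, {
    m <- array(0, c(32, 32, 32))
    cen <- runif(3, 12, 20); rad <- runif(1, 6, 10)
    g <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
    m[sqrt((g$x - cen[1])^2 + (g$y - cen[2])^2 + (g$z - cen[3])^2) <= rad] <- 1
    mk <- seg_mask(m, spacing = rep(2.0, 3))
    r <- resample_isotropic(mk, 1.6, "nearest")
    expect_true(all(r$data %in% c(0, 1)))
    v0 <- sum(mk$data) * 2.0^3
    v1 <- sum(r$data) * 1.6^3
    abs(v1 - v0) / v0
  })
  expect_lt(max(errs), 0.15)
})

test_that("non-positive target spacing is a parameter error", {
  vol <- ct_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
  expect_error(resample_isotropic(vol, 0), "parameter error")
  expect_error(resample_isotropic(vol, -1), "parameter error")
})

test_that("pad_crop_center: identity, pure pad, pure crop", {
  mkvol <- function(n) {
    set.seed(n)
    ct_volume(array(rnorm(n^3), rep(n, 3)), c(1, 1, 1))
  }
  # identity
  r <- pad_crop_center(mkvol(16), 16)
  expect_equal(r$volume$data, mkvol(16)$data)
  expect_true(all(c(r$transform$pad_low, r$transform$pad_high,
                    r$transform$crop_low, r$transform$crop_high) == 0))
  # 100 -> 128-style pad, scaled down: 10 -> 16 pads (3,3)
  v <- mkvol(10)
  r <- pad_crop_center(v, 16, pad_value = -800)
  expect_equal(r$transform$pad_low, rep(3L, 3))
  expect_equal(r$transform$pad_high, rep(3L, 3))
  expect_equal(r$volume$data[4, 4, 4], v$data[1, 1, 1])  # voxel 0 -> pad_low
  expect_equal(r$volume$data[1, 1, 1], -800)
  # 150-style crop, scaled: 22 -> 16 crops (3,3); centre preserved bit-exact
  v <- mkvol(22)
  r <- pad_crop_center(v, 16)
  expect_equal(r$transform$crop_low, rep(3L, 3))
  expect_equal(r$volume$data, v$data[4:19, 4:19, 4:19])  # slicing oracle
  # asymmetric split differs by at most one
  v <- ct_volume(array(0, c(9, 16, 23)), c(1, 1, 1))
  tr <- pad_crop_center(v, 16)$transform
  expect_true(all(abs(tr$pad_low - tr$pad_high) <= 1))
  expect_true(all(abs(tr$crop_low - tr$crop_high) <= 1))
  # per axis, at most one of pad/crop is active
  expect_true(all(tr$pad_low * tr$crop_low == 0))
})

test_that("clip_normalize maps the clip window onto [0, 1]", {
  vol <- ct_volume(array(c(-800, 1200, 200, -2000, 5000, 0),
                         c(6, 1, 1)), c(1, 1, 1))
  out <- clip_normalize(vol)$data
  expect_equal(out[1, 1, 1], 0)
  expect_equal(out[2, 1, 1], 1)
  expect_equal(out[3, 1, 1], 0.5)     # (200 + 800) / 2000
  expect_equal(out[4, 1, 1], 0)       # clamped below floor
  expect_equal(out[5, 1, 1], 1)
  expect_error(clip_normalize(vol, 10, 10), "parameter error")
})

test_that("clip_normalize is monotone in HU", {
  set.seed(5)
  x <- sort(runif(100, -2000, 3000))
  vol <- ct_volume(array(x, c(100, 1, 1)), c(1, 1, 1))
  out <- as.vector(clip_normalize(vol)$data)
  expect_true(all(diff(out) >= 0))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("redundant class matches a brute-force voxel loop", {
  set.seed(31)
  shape <- c(7, 6, 10)
  vol <- ct_volume(array(runif(prod(shape), -400, 100), shape), c(2, 2, 2))
  peri <- seg_mask(array(rbinom(prod(shape), 1, 0.3), shape), c(2, 2, 2))
  cfg <- preprocess_config()
  lab <- make_redundant_class(vol, peri, cfg)$data
  # brute force oracle
  zmax <- ceiling(0.2 * shape[3])            # = 2 for 10 slices
  expect_equal(zmax, 2)
  ref <- array(0, shape)
  for (z in seq_len(shape[3]))
    for (y in seq_len(shape[2]))
      for (x in seq_len(shape[1])) {
        if (peri$data[x, y, z] == 1) ref[x, y, z] <- 1
        else if (z <= zmax && vol$data[x, y, z] >= -198 &&
                 vol$data[x, y, z] <= -80) ref[x, y, z] <- 2
      }
  expect_identical(lab, ref)
  # per-slice counts agree with the oracle too
  expect_equal(apply(lab == 2, 3, sum), apply(ref == 2, 3, sum))
  # no redundant label above the inferior boundary
  expect_true(all(lab[, , (zmax + 1):shape[3]] != 2))
  # exactly one label per voxel and 1/2 disjoint by construction
  expect_true(all(lab %in% 0:2))
  expect_true(all(lab[peri$data == 1] == 1))
})

test_that("redundant-class precedence and slice-window examples hold", {
  shape <- c(2, 2, 10)
  hu <- array(0, shape); hu[1, 1, ] <- -100    # fat-density column
  vol <- ct_volume(hu, c(1, 1, 1))
  peri <- array(0, shape); peri[1, 1, 6] <- 1; peri[1, 1, 1] <- 1
  lab <- make_redundant_class(vol, seg_mask(peri, c(1, 1, 1)))$data
  expect_equal(lab[1, 1, 1], 1)   # inside pericardium wins over HU window
  expect_equal(lab[1, 1, 2], 2)   # slice 2 of 10 is in the inferior 20%
  expect_equal(lab[1, 1, 3], 0)   # slice 3 is not
  expect_equal(lab[1, 1, 6], 1)
})

test_that("full pipeline on an already-conforming cube is clip_normalize", {
  set.seed(41)
  n <- 32
  cfg <- preprocess_config(target_spacing_mm = 1.6, cube_size = n)
  vol <- ct_volume(array(runif(n^3, -800, 1200), rep(n, 3)), rep(1.6, 3))
  pp <- apply_pipeline(vol, NULL, cfg)
  expect_identical(pp$image, clip_normalize(vol)$data)
  tr <- pp$transform
  expect_true(all(c(tr$pad_low, tr$pad_high, tr$crop_low, tr$crop_high) == 0))
  expect_equal(tr$resampled_shape, rep(n, 3))
})

test_that("pipeline resamples a finer grid onto the cube without padding", {
  cfg <- preprocess_config(target_spacing_mm = 1.6, cube_size = 32)
  vol <- ct_volume(array(0, rep(64, 3)), rep(0.8, 3))
  pp <- apply_pipeline(vol, NULL, cfg)
  expect_equal(pp$transform$resampled_shape, rep(32L, 3))
  expect_true(all(pp$transform$pad_low == 0 & pp$transform$crop_low == 0))
})

test_that("invert_to_native of an all-ones cube covers the native grid", {
  # native extents below the cube extent, so the transform only pads
  cfg <- preprocess_config(target_spacing_mm = 2, cube_size = 16)
  vol <- ct_volume(array(0, c(18, 24, 30)), c(1.7, 1.3, 0.9))
  pp <- apply_pipeline(vol, NULL, cfg)
  expect_true(all(pp$transform$crop_low == 0))
  ones <- array(1, rep(16, 3))
  back <- invert_to_native(ones, pp$transform, vol)
  expect_equal(dim(back$data), c(18L, 24L, 30L))
  expect_true(all(back$data == 1))
  # all-zero cube stays empty
  expect_true(all(invert_to_native(array(0, rep(16, 3)), pp$transform,
                                   vol)$data == 0))
})

test_that("forward + inverse round-trip keeps blob masks (Dice >= 0.9)", {
  set.seed(55)
  cfg <- e2e_pre_cfg()
  dices <- replicate(10, {
    shape <- c(64, 64, 64); spacing <- c(2.2, 2.2, 2.8)
    m <- sphere_mask(shape, spacing, runif(3, 24, 40), runif(1, 10, 16))
    vol <- ct_volume(array(0, shape), spacing)
    pp <- apply_pipeline(vol, m, cfg)
    back <- invert_to_native((pp$labels == 1) * 1, pp$transform, vol)
    dice(back, m)
  })
  expect_gte(min(dices), 0.9)
})

test_that("grid mismatches and invalid configs raise informative errors", {
  vol <- ct_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
  peri <- seg_mask(array(0, c(4, 4, 5)), c(1, 1, 1))
  expect_error(make_redundant_class(vol, peri), "alignment error")
  expect_error(preprocess_config(inferior_fraction = 0), "parameter error")
  expect_error(preprocess_config(clip_lo_hu = 10, clip_hi_hu = 0),
               "parameter error")
  cfg <- preprocess_config(target_spacing_mm = 2, cube_size = 8)
  pp <- apply_pipeline(vol, NULL, cfg)
  expect_error(invert_to_native(array(0, c(4, 4, 4)), pp$transform, vol),
               "alignment error")
})
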