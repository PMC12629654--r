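test_that("phantom generation is deterministic for a fixed spec", {
  sp <- phantom_spec(shape = c(32, 32, 32), spacing = c(4, 4, 4),
                     heart_axes = c(40, 38, 42), supersample = 1L, seed = 5)
  a <- generate_phantom(sp); b <- generate_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$pericardium_mask$data,
                   b$truth$pericardium_mask$data)
})

test_that("rendered fat volume converges to the analytic value", {
  errs <- sapply(c(2.0, 1.0, 0.5), function(sp) {
    n <- as.integer(round(96 / sp))
    spec <- phantom_spec(shape = rep(n, 3), spacing = rep(sp, 3),
                         heart_axes = c(32, 30, 33), noise_sd = 0,
                         supersample = 2L, calcium_radius = 0)
    ph <- generate_phantom(spec)
    v <- sum(ph$truth$eat_mask$data) * sp^3 / 1000
    abs(v - ph$truth$eat_volume_cm3) / ph$truth$eat_volume_cm3
  })
  expect_true(errs[3] < errs[1])
  expect_lt(errs[3], 0.03)
})

test_that("phantom truth respects its structural invariants", {
  ph <- small_phantom()
  expect_true(all(ph$truth$eat_mask$data <=
                    ph$truth$pericardium_mask$data))
  # the fat HU mean lies in both the adipose and the redundant windows
  fat_hu <- ph$spec$hu_means["fat"]
  expect_true(fat_hu > -190 && fat_hu < -30)
  expect_true(fat_hu > -198 && fat_hu < -80)
})

test_that("paracardial fat defeats naive global thresholding", {
  sp <- phantom_spec(shape = c(48, 48, 48), spacing = c(3, 3, 3),
                     heart_axes = c(45, 40, 46), supersample = 1L,
                     noise_sd = 0, paracardial_fat = TRUE)
  ph <- generate_phantom(sp)
  win <- eat_window()
  global <- sum(ph$volume$data >= win$lo & ph$volume$data <= win$hi) *
    prod(sp$spacing) / 1000
  constrained <- extract_eat(ph$volume,
                             ph$truth$pericardium_mask)$volume_cm3
  expect_gte(global, 1.2 * constrained)
  # without paracardial fat the two nearly coincide
  sp2 <- phantom_spec(shape = c(48, 48, 48), spacing = c(3, 3, 3),
                      heart_axes = c(45, 40, 46), supersample = 1L,
                      noise_sd = 0, paracardial_fat = FALSE)
  ph2 <- generate_phantom(sp2)
  global2 <- sum(ph2$volume$data >= win$lo & ph2$volume$data <= win$hi) *
    prod(sp2$spacing) / 1000
  constrained2 <- extract_eat(ph2$volume,
                              ph2$truth$pericardium_mask)$volume_cm3
  expect_lt(global2, 1.2 * constrained2)
})

test_that("datasets are reproducible and respect degenerate jitter", {
  base <- phantom_spec(shape = c(32, 32, 32), spacing = c(4.4, 4.4, 5.6),
                       supersample = 1L)
  a <- generate_dataset(4, base, seed = 3)
  b <- generate_dataset(4, base, seed = 3)
  expect_identical(lapply(a, function(x) x$volume$data),
                   lapply(b, function(x) x$volume$data))
  # four distinct cases
  expect_equal(length(unique(sapply(a, function(x)
    x$truth$eat_volume_cm3))), 4)
  # zero-width jitter pins every drawn parameter to its base value
  j0 <- phantom_jitter(axes_scale = c(1, 1), center_shift_mm = c(0, 0),
                       fat_fraction_equator = c(0.4, 0.4),
                       fat_fraction_apex = c(0.95, 0.95),
                       core_scale = c(0.72, 0.72), noise_sd = c(0, 0),
                       wedge_angle = c(0, 0))
  d <- generate_dataset(2, base, j0, seed = 1)
  expect_equal(d[[1]]$truth$eat_volume_cm3, d[[2]]$truth$eat_volume_cm3)
  expect_equal(d[[1]]$spec$heart_axes, base$heart_axes)
  expect_error(phantom_jitter(axes_scale = c(2, 1)), "spec error")
})

test_that("default jitter spans the configured clinical volume range", {
  base <- e2e_base_spec()
  base$supersample <- 1L
  cases <- generate_dataset(50, base, seed = 11)
  vols <- sapply(cases, function(x) x$truth$eat_volume_cm3)
  rng <- phantom_jitter()$volume_range
  expect_true(all(vols >= rng[1] & vols <= rng[2]))
  midpoint <- mean(rng)
  expect_lt(abs(mean(vols) - midpoint) / midpoint, 0.2)
})

test_that("spec validation rejects impossible geometry", {
  expect_error(phantom_spec(shape = c(16, 16, 16), spacing = c(2, 2, 2),
                            heart_axes = c(40, 40, 40)), "spec error")
  expect_error(phantom_spec(hu_means = c(air = -1000, soft = 40,
                                         lung = -800, fat = -50,
                                         line = 30, core = 45,
                                         calcium = 300)), "spec error")
  expect_error(phantom_spec(fat_fraction_equator = 0.9,
                            fat_fraction_apex = 0.5), "spec error")
  expect_error(phantom_spec(core_scale = 0.99), "spec error")
})

test_that("sparse annotations derived from truth keep the extremes", {
  ph <- small_phantom()
  ann <- sparse_annotation_from_truth(ph$truth, step = 5)
  nonempty <- which(apply(ph$truth$pericardium_mask$data, 3, sum) > 0)
  expect_true(min(nonempty) %in% ann$idx)
  expect_true(max(nonempty) %in% ann$idx)
  dense <- sparse_annotation_from_truth(ph$truth, step = 1)
  expect_equal(interpolate_dense(dense)$data[, , ann$bounds[1]:ann$bounds[2]],
               ph$truth$pericardium_mask$data[, , ann$bounds[1]:ann$bounds[2]])
})
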