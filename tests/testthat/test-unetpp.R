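tiny_cfg <- function() unetpp_config(levels = 2L, channels = c(2, 3),
                                     final_up_channels = 2L, cube_size = 8L)

test_that("forward pass preserves shape, stays in (0,1) and finite", {
  cfg <- unetpp_config(levels = 3L, channels = c(2, 3, 4),
                       final_up_channels = 2L, cube_size = 16L)
  m <- build_unetpp(cfg, seed = 2)
  p <- predict_probs(m, array(0, c(16, 16, 16)))
  expect_equal(dim(p), c(16, 16, 16, 3))
  expect_true(all(is.finite(p)))
  expect_true(all(p > 0 & p < 1))
  # non-cubic but divisible input also works
  p2 <- predict_probs(m, array(0.5, c(16, 8, 16)))
  expect_equal(dim(p2)[1:3], c(16, 8, 16))
})

test_that("parameter count matches hand-enumerated layer arithmetic", {
  cfg <- unetpp_config(levels = 2L, channels = c(4, 8),
                       final_up_channels = 4L, cube_size = 8L)
  m <- build_unetpp(cfg)
  # independent enumeration: conv w = 27*cin*cout + cout, IN = 2*cout,
  # upconv = 8*cin*cout + cout, head = cin*classes + classes
  conv_block <- function(cin, cout) (27 * cin * cout + cout) + 2 * cout +
    (27 * cout * cout + cout) + 2 * cout
  expected <- conv_block(1, 4) +          # X(0,0)
    conv_block(4, 8) +                    # X(1,0)
    conv_block(4 + 4, 4) +                # X(0,1): skip + upsample
    (8 * 8 * 4 + 4) +                     # transposed conv 8 -> 4
    (4 * 3 + 3)                           # head
  expect_equal(n_parameters(m), expected)
})

test_that("initialization is seed-deterministic", {
  a <- build_unetpp(tiny_cfg(), seed = 5)
  b <- build_unetpp(tiny_cfg(), seed = 5)
  c <- build_unetpp(tiny_cfg(), seed = 6)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})

test_that("config invariants are enforced", {
  expect_error(unetpp_config(levels = 3, channels = c(2, 3)), "config error")
  expect_error(unetpp_config(levels = 4, channels = c(2, 3, 4, 5),
                             cube_size = 20), "config error")
  m <- build_unetpp(tiny_cfg())
  expect_error(eatct:::forward_unetpp(m, array(0, c(9, 8, 8))),
               "config error")
})

test_that("backpropagation matches numeric differentiation", {
  m <- build_unetpp(tiny_cfg(), seed = 7)
  set.seed(3)
  x <- array(runif(8^3), c(8, 8, 8))
  tgt <- eatct:::labels_to_target(array(sample(0:2, 8^3, TRUE), c(8, 8, 8)), 3)
  lossval <- function(params) {
    mm <- m; mm$params <- params
    tp <- eatct:::tape_new()
    f <- eatct:::forward_unetpp(mm, x, tp)
    z <- f$logits$value
    sum(pmax(z, 0) - z * tgt + log1p(exp(-abs(z)))) / nrow(z)
  }
  tp <- eatct:::tape_new()
  f <- eatct:::forward_unetpp(m, x, tp)
  loss <- eatct:::op_bce_logits(tp, f$logits, tgt)
  eatct:::tp_backward(tp, loss)
  set.seed(11)
  h <- 5e-4   # larger step: the forward pass carries float32 noise
  for (nm in c("x0_0.conv1.w", "x0_0.in1.g", "x1_0.conv2.w", "up0_1.w",
               "x0_1.conv1.w", "head.w", "head.b")) {
    g <- tp$pgrads[[nm]]
    ks <- order(-abs(g))[seq_len(min(3, length(g)))]  # largest entries
    for (k in ks) {
      pp <- m$params
      pp[[nm]][k] <- pp[[nm]][k] + h; up <- lossval(pp)
      pp[[nm]][k] <- pp[[nm]][k] - 2 * h; dn <- lossval(pp)
      num <- (up - dn) / (2 * h)
      expect_lt(abs(num - g[k]) / max(1e-3, abs(num)), 0.05,
                label = sprintf("gradient of %s[%d]", nm, k))
    }
  }
})

test_that("float32 conv kernels agree with the naive double reference", {
  set.seed(19)
  dims <- c(9, 7, 6); N <- prod(dims)
  x <- matrix(rnorm(N * 3), N, 3)
  w <- array(rnorm(27 * 3 * 4, sd = 0.2), c(3, 3, 3, 3, 4))
  b <- rnorm(4)
  fast <- eatct:::cpp_conv3d_fwd(x, dims, w, b)
  ref <- eatct:::cpp_conv3d_fwd_ref(x, dims, w, b)
  expect_lt(max(abs(fast - ref)), 1e-4)
  # analytic conv gradients vs numeric differentiation of the reference
  g <- matrix(rnorm(N * 4), N, 4)
  bw <- eatct:::cpp_conv3d_bwd(x, dims, w, g)
  h <- 1e-6
  set.seed(20)
  for (k in sample(length(w), 8)) {
    wp <- w; wp[k] <- wp[k] + h
    wm <- w; wm[k] <- wm[k] - h
    num <- sum(g * (eatct:::cpp_conv3d_fwd_ref(x, dims, wp, b) -
                      eatct:::cpp_conv3d_fwd_ref(x, dims, wm, b))) / (2 * h)
    expect_lt(abs(num - bw$gw[k]), 1e-3 * max(1, abs(num)))
  }
  for (k in sample(length(x), 8)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    num <- sum(g * (eatct:::cpp_conv3d_fwd_ref(xp, dims, w, b) -
                      eatct:::cpp_conv3d_fwd_ref(xm, dims, w, b))) / (2 * h)
    expect_lt(abs(num - bw$gx[k]), 1e-3 * max(1, abs(num)))
  }
})

test_that("training reduces the loss when overfitting one sample", {
  ph <- generate_phantom(phantom_spec(shape = c(16, 16, 16),
                                      spacing = c(8, 8, 8),
                                      heart_axes = c(40, 38, 42),
                                      supersample = 2L, noise_sd = 5,
                                      calcium_radius = 0, seed = 3))
  pre <- preprocess_config(target_spacing_mm = 8, cube_size = 16)
  pp <- apply_pipeline(ph$volume, ph$truth$pericardium_mask, pre)
  cfg <- unetpp_config(levels = 2L, channels = c(4, 8),
                       final_up_channels = 4L, cube_size = 16L)
  m <- build_unetpp(cfg, seed = 1)
  fit <- train_unetpp(m, list(list(image = pp$image, labels = pp$labels)),
                      train_config(learning_rate = 1e-3, epochs = 30,
                                   seed = 1))
  expect_lt(fit$trace[30], fit$trace[1])
  expect_true(all(is.finite(fit$trace)))
})

test_that("a zero learning rate leaves the loss trace constant", {
  ph <- generate_phantom(phantom_spec(shape = c(16, 16, 16),
                                      spacing = c(8, 8, 8),
                                      heart_axes = c(40, 38, 42),
                                      supersample = 1L, seed = 3))
  pre <- preprocess_config(target_spacing_mm = 8, cube_size = 16)
  pp <- apply_pipeline(ph$volume, ph$truth$pericardium_mask, pre)
  m <- build_unetpp(unetpp_config(levels = 2L, channels = c(2, 3),
                                  final_up_channels = 2L, cube_size = 16L))
  fit <- train_unetpp(m, list(list(image = pp$image, labels = pp$labels)),
                      train_config(learning_rate = 0, epochs = 4, seed = 1))
  expect_lt(diff(range(fit$trace)), 1e-12)
})

test_that("training is reproducible for a fixed seed", {
  ph <- generate_phantom(phantom_spec(shape = c(16, 16, 16),
                                      spacing = c(8, 8, 8),
                                      heart_axes = c(40, 38, 42),
                                      supersample = 1L, seed = 3))
  pre <- preprocess_config(target_spacing_mm = 8, cube_size = 16)
  pp <- apply_pipeline(ph$volume, ph$truth$pericardium_mask, pre)
  s <- list(list(image = pp$image, labels = pp$labels))
  m <- build_unetpp(unetpp_config(levels = 2L, channels = c(2, 3),
                                  final_up_channels = 2L, cube_size = 16L))
  f1 <- train_unetpp(m, s, train_config(epochs = 3, seed = 9))
  f2 <- train_unetpp(m, s, train_config(epochs = 3, seed = 9))
  expect_identical(f1$trace, f2$trace)
})

test_that("degenerate heads give full or empty native masks", {
  cfg <- unetpp_config(levels = 2L, channels = c(2, 3),
                       final_up_channels = 2L, cube_size = 16L)
  m <- build_unetpp(cfg, seed = 1)
  m$params[["head.w"]][] <- 0
  vol <- ct_volume(array(-100, c(20, 20, 20)), c(2, 2, 2))
  pre <- preprocess_config(target_spacing_mm = 2.5, cube_size = 16)
  m$params[["head.b"]] <- c(-10, 10, -10)   # pericardium channel saturated on
  full <- predict_pericardium(m, vol, pre)
  expect_true(all(full$data == 1))
  m$params[["head.b"]] <- c(10, -10, 10)
  empty <- predict_pericardium(m, vol, pre)
  expect_true(all(empty$data == 0))
})

test_that("model checkpoints round-trip", {
  dir <- withr::local_tempdir()
  m <- build_unetpp(tiny_cfg(), seed = 4)
  p <- file.path(dir, "model.rds")
  save_model(m, p)
  back <- load_model(p)
  expect_identical(back$params, m$params)
  expect_identical(back$cfg, m$cfg)
})
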