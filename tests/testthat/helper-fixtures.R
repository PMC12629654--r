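# Shared fixtures, built once per test run.

# small, fast phantom used by several files
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(phantom_spec(shape = c(48, 48, 48),
                                              spacing = c(3, 3, 3),
                                              heart_axes = c(45, 40, 46),
                                              supersample = 1L,
                                              noise_sd = 5, seed = 7L))
    cache
  }
})

# native-grid training phantom conditions used by the end-to-end checks
e2e_base_spec <- function() {
  phantom_spec(shape = c(64, 64, 64), spacing = c(2.2, 2.2, 2.8))
}

e2e_pre_cfg <- function() {
  preprocess_config(target_spacing_mm = 2.5, cube_size = 64L)
}

toy_unetpp_cfg <- function() {
  unetpp_config(levels = 4L, channels = c(4, 8, 16, 32),
                final_up_channels = 4L, cube_size = 64L)
}

# a random blob (sphere) mask on a native grid
sphere_mask <- function(shape, spacing, center_vox, radius_vox) {
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  d <- sqrt((g$x - center_vox[1])^2 + (g$y - center_vox[2])^2 +
              (g$z - center_vox[3])^2)
  seg_mask(array(as.double(d <= radius_vox), shape), spacing)
}

rand_hu_volume <- function(shape = c(12, 10, 8), spacing = c(1.5, 1.5, 3),
                           seed = 1) {
  set.seed(seed)
  ct_volume(array(as.double(sample(-1000:2000, prod(shape), TRUE)), shape),
            spacing)
}
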