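#' 3D UNet++ configuration
#'
#' Nested encoder-decoder with dense skip pathways.  Node X(i,0) is the
#' encoder column (stride-2 max-pool downsampling between levels); each
#' nested node X(i,j), j >= 1, receives the concatenation of X(i,0..j-1)
#' with a transposed-convolution upsampling of X(i+1,j-1).  Every
#' convolutional block is two (3x3x3 conv -> instance norm -> LeakyReLU)
#' stages; the head is a 1x1x1 convolution with a per-class sigmoid on
#' X(0, levels-1).  Deep supervision is not used.
#'
#' @param levels number of resolution levels (default 5).
#' @param channels encoder feature channels per level
#'   (default `c(32, 32, 64, 128, 256)`).
#' @param final_up_channels channels produced by upsampling into the top
#'   level (default 32).
#' @param negative_slope LeakyReLU negative slope (default 0.1).
#' @param out_classes output class channels: background, pericardium,
#'   redundant (default 3).
#' @param cube_size expected input edge length; must be divisible by
#'   `2^(levels-1)`.
#' @param in_channels input image channels (default 1).
#' @return A `unetpp_config` list.
#' @export
unetpp_config <- function(levels = 5L, channels = c(32, 32, 64, 128, 256),
                          final_up_channels = 32L, negative_slope = 0.1,
                          out_classes = 3L, cube_size = 128L,
                          in_channels = 1L) {
  levels <- as.integer(levels)
  if (length(channels) != levels)
    stop("config error: length(channels) must equal levels")
  if (any(channels < 1)) stop("config error: channels must be >= 1")
  if (cube_size %% 2^(levels - 1) != 0)
    stop("config error: cube_size must be divisible by 2^(levels-1)")
  structure(list(levels = levels, channels = as.integer(channels),
                 final_up_channels = as.integer(final_up_channels),
                 negative_slope = negative_slope,
                 out_classes = as.integer(out_classes),
                 cube_size = as.integer(cube_size),
                 in_channels = as.integer(in_channels)),
            class = "unetpp_config")
}

# channels flowing out of the upsampling branch into level i
up_out_channels <- function(cfg, i) {
  if (i == 0L) cfg$final_up_channels else cfg$channels[i + 1L]
}

# input channels of the conv block at node (i, j)  [0-based i, j]
block_in_channels <- function(cfg, i, j) {
  if (j == 0L) {
    if (i == 0L) cfg$in_channels else cfg$channels[i]     # from pool(X(i-1,0))
  } else {
    j * cfg$channels[i + 1L] + up_out_channels(cfg, i)
  }
}

he_init <- function(dims, fan_in, slope) {
  gain <- sqrt(2 / (1 + slope^2))
  array(stats::rnorm(prod(dims), sd = gain / sqrt(fan_in)), dims)
}

#' Build a randomly initialized 3D UNet++ model
#'
#' He-style random weight initialization; identical seeds give bitwise
#' identical parameters.
#'
#' @param cfg a [unetpp_config()].
#' @param seed integer RNG seed for the initialization.
#' @return A `unetpp_model` list with elements `cfg`, `params`, `seed`.
#' @export
build_unetpp <- function(cfg = unetpp_config(), seed = 1L) {
  stopifnot(inherits(cfg, "unetpp_config"))
  params <- list()
  with_seed(seed, {
    L <- cfg$levels
    for (i in 0:(L - 1L)) {
      for (j in 0:(L - 1L - i)) {
        cin <- block_in_channels(cfg, i, j)
        cout <- cfg$channels[i + 1L]
        nm <- sprintf("x%d_%d", i, j)
        params[[paste0(nm, ".conv1.w")]] <-
          he_init(c(3, 3, 3, cin, cout), 27 * cin, cfg$negative_slope)
        params[[paste0(nm, ".conv1.b")]] <- numeric(cout)
        params[[paste0(nm, ".in1.g")]] <- rep(1, cout)
        params[[paste0(nm, ".in1.b")]] <- numeric(cout)
        params[[paste0(nm, ".conv2.w")]] <-
          he_init(c(3, 3, 3, cout, cout), 27 * cout, cfg$negative_slope)
        params[[paste0(nm, ".conv2.b")]] <- numeric(cout)
        params[[paste0(nm, ".in2.g")]] <- rep(1, cout)
        params[[paste0(nm, ".in2.b")]] <- numeric(cout)
        if (j >= 1L) {
          cin_up <- cfg$channels[i + 2L]
          cout_up <- up_out_channels(cfg, i)
          nmu <- sprintf("up%d_%d", i, j)
          params[[paste0(nmu, ".w")]] <-
            he_init(c(2, 2, 2, cin_up, cout_up), cin_up, cfg$negative_slope)
          params[[paste0(nmu, ".b")]] <- numeric(cout_up)
        }
      }
    }
    c0 <- cfg$channels[1L]
    params[["head.w"]] <- array(stats::rnorm(c0 * cfg$out_classes,
                                              sd = 1 / sqrt(c0)),
                                 c(c0, cfg$out_classes))
    params[["head.b"]] <- numeric(cfg$out_classes)
  })
  structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
            class = "unetpp_model")
}

#' Number of trainable parameters
#' @param model a `unetpp_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# one conv block: (conv -> IN -> LeakyReLU) x 2, with the IN/activation
# stages fused into a single kernel
block_forward <- function(tape, model, x, name) {
  s <- model$cfg$negative_slope
  h <- op_conv3(tape, model, x, paste0(name, ".conv1"))
  h <- op_in_lrelu(tape, model, h, paste0(name, ".in1"), s)
  h <- op_conv3(tape, model, h, paste0(name, ".conv2"))
  op_in_lrelu(tape, model, h, paste0(name, ".in2"), s)
}

# forward pass; x is an array (nx, ny, nz) or (nx, ny, nz, C) in [0, 1]
forward_unetpp <- function(model, x, tape = tape_new()) {
  cfg <- model$cfg
  dims <- dim(x)[1:3]
  if (any(dims %% 2^(cfg$levels - 1L) != 0))
    stop("config error: input shape ", paste(dims, collapse = "x"),
         " is not divisible by 2^(levels-1)")
  cin <- if (length(dim(x)) == 4L) dim(x)[4] else 1L
  if (cin != cfg$in_channels)
    stop("config error: input has ", cin, " channels, model expects ",
         cfg$in_channels)
  xin <- op_input(tape, feat(matrix(as.double(x), prod(dims), cin), dims))
  L <- cfg$levels
  X <- vector("list", L)
  for (i in 0:(L - 1L)) X[[i + 1L]] <- vector("list", L - i)
  # encoder column
  for (i in 0:(L - 1L)) {
    src <- if (i == 0L) xin else op_maxpool2(tape, X[[i]][[1L]])
    X[[i + 1L]][[1L]] <- block_forward(tape, model, src, sprintf("x%d_0", i))
  }
  # nested decoder nodes
  for (j in 1:(L - 1L)) {
    for (i in 0:(L - 1L - j)) {
      up <- op_upconv2(tape, model, X[[i + 2L]][[j]], sprintf("up%d_%d", i, j))
      skips <- X[[i + 1L]][seq_len(j)]
      h <- op_concat(tape, c(skips, list(up)))
      X[[i + 1L]][[j + 1L]] <- block_forward(tape, model, h,
                                             sprintf("x%d_%d", i, j))
    }
  }
  logits <- op_head(tape, model, X[[1L]][[L]], "head")
  list(logits = logits, tape = tape)
}

#' Run the network on an image cube and return per-class probabilities
#'
#' @param model a trained `unetpp_model`.
#' @param x input array of shape `cube^3` (values in `[0, 1]`).
#' @return Array `(nx, ny, nz, out_classes)` of sigmoid probabilities.
#' @export
predict_probs <- function(model, x) {
  f <- forward_unetpp(model, x)
  z <- f$logits$value
  dims <- sdim(z)
  array(stats::plogis(z), c(dims, ncol(z)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding the config, seed and all
#' parameters.
#'
#' @param model a `unetpp_model`.
#' @param path file path.
#' @return `path` (save) or the restored `unetpp_model` (load).
#' @export
save_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  structure(m, class = "unetpp_model")
}
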