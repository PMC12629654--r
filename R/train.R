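#' Training configuration
#'
#' The training recipe: RMSProp at a fixed learning rate (no scheduler),
#' mini-batch size 1, per-voxel binary cross-entropy summed over the class
#' channels.  RMSProp smoothing constants follow the common framework
#' defaults and are recorded in the returned object.
#'
#' @param learning_rate fixed learning rate (default 1e-4).
#' @param batch_size mini-batch size; only 1 is supported.
#' @param epochs number of passes over the training set (>= 1).
#' @param seed RNG seed controlling sample order shuffling.
#' @param rmsprop_alpha squared-gradient smoothing constant (default 0.99).
#' @param rmsprop_eps denominator stabilizer (default 1e-8).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 1L,
                         epochs = 10L, seed = 1L,
                         rmsprop_alpha = 0.99, rmsprop_eps = 1e-8) {
  if (learning_rate < 0) stop("config error: learning_rate must be >= 0")
  if (batch_size != 1L)
    stop("config error: only mini-batch size 1 is supported")
  if (epochs < 1) stop("config error: epochs must be >= 1")
  structure(list(learning_rate = learning_rate, batch_size = 1L,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 rmsprop_alpha = rmsprop_alpha, rmsprop_eps = rmsprop_eps),
            class = "train_config")
}

# expand a {0,1,2} label cube to per-class binary target channels (N x K)
labels_to_target <- function(labels, out_classes) {
  n <- length(labels)
  tg <- matrix(0, n, out_classes)
  lv <- as.integer(labels)
  for (k in seq_len(out_classes)) tg[lv == (k - 1L), k] <- 1
  tg
}

#' Train a UNet++ model on image/label cube pairs
#'
#' One RMSProp step per sample (mini-batch 1); samples are reshuffled each
#' epoch.  With a fixed seed the loss trace is reproducible on one machine
#' (BLAS-level determinism is machine-local).  Training aborts with a
#' divergence error naming the epoch if the loss turns non-finite.
#'
#' @param model a `unetpp_model` from [build_unetpp()].
#' @param samples list of `list(image = cube array in [0,1], labels = cube
#'   array over {0,1,2})`.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch mean loss?
#' @return `list(model = trained model, trace = per-epoch mean loss)`.
#' @export
train_unetpp <- function(model, samples, cfg = train_config(),
                         verbose = FALSE) {
  stopifnot(inherits(model, "unetpp_model"), length(samples) >= 1)
  params <- model$params
  sq <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  targets <- lapply(samples, function(s)
    labels_to_target(s$labels, model$cfg$out_classes))
  trace <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(samples))
      losses <- numeric(length(ord))
      for (si in seq_along(ord)) {
        s <- samples[[ord[si]]]
        tp <- tape_new()
        f <- forward_unetpp(structure(list(cfg = model$cfg, params = params),
                                      class = "unetpp_model"),
                            s$image, tp)
        loss <- op_bce_logits(tp, f$logits, targets[[ord[si]]])
        if (!is.finite(loss$value))
          stop("divergence error: non-finite loss at epoch ", ep)
        losses[si] <- loss$value
        if (cfg$learning_rate > 0) {
          tp_backward(tp, loss)
          for (nm in names(params)) {
            g <- tp$pgrads[[nm]]
            if (is.null(g)) next
            sq[[nm]] <- cfg$rmsprop_alpha * sq[[nm]] +
              (1 - cfg$rmsprop_alpha) * g * g
            params[[nm]] <- params[[nm]] -
              cfg$learning_rate * g / (sqrt(sq[[nm]]) + cfg$rmsprop_eps)
          }
        }
        rm(tp, f, loss)
      }
      trace[ep] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %d/%d  mean loss %.5f", ep, cfg$epochs,
                        trace[ep]))
    }
  })
  out <- model
  out$params <- params
  list(model = out, trace = trace)
}

#' Export a loss trace as CSV
#' @param trace numeric per-epoch losses from [train_unetpp()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_loss_trace <- function(trace, path) {
  utils::write.csv(data.frame(epoch = seq_along(trace), loss = trace),
                   path, row.names = FALSE)
  invisible(path)
}

#' Predict the pericardium mask of a native-grid volume
#'
#' Preprocesses the volume (image-only pipeline), runs the network, takes
#' the pericardium channel probability at 0.5, optionally keeps only the
#' largest 26-connected component, and maps the cube mask back to the
#' native grid.  The redundant channel is a training aid only and is
#' discarded here.
#'
#' @param model a trained `unetpp_model`.
#' @param vol native-grid HU [ct_volume()].
#' @param pre_cfg a [preprocess_config()]; its `cube_size` must match the
#'   model's.
#' @param postprocess `"none"` or `"largest_component"`.
#' @param threshold probability cut for binarization (default 0.5).
#' @return A [seg_mask()] on the native grid.
#' @export
predict_pericardium <- function(model, vol,
                                pre_cfg = preprocess_config(),
                                postprocess = c("none", "largest_component"),
                                threshold = 0.5) {
  postprocess <- match.arg(postprocess)
  if (pre_cfg$cube_size != model$cfg$cube_size)
    stop("config error: preprocess cube_size (", pre_cfg$cube_size,
         ") does not match model cube_size (", model$cfg$cube_size, ")")
  vol <- canonicalize(vol)
  pp <- apply_pipeline(vol, NULL, pre_cfg)
  probs <- predict_probs(model, pp$image)
  peri <- (probs[, , , 2L] >= threshold) * 1   # channel 2 = pericardium
  if (postprocess == "largest_component" && sum(peri) > 0) {
    lab <- cpp_largest_component(as.integer(peri), dim(peri))
    peri <- array(as.double(lab), dim(peri))
  }
  invert_to_native(peri, pp$transform, vol)
}
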