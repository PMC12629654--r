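# Differentiable layer ops used by the UNet++ graph.  Each op returns a new
# tape node; parameter-bearing ops read weights from model$params and write
# gradients into tape$pgrads under the parameter names.

op_input <- function(tape, x) tp_node(tape, x)

op_conv3 <- function(tape, model, x, name) {
  w <- model$params[[paste0(name, ".w")]]
  b <- model$params[[paste0(name, ".b")]]
  dims <- sdim(x$value)
  val <- feat(cpp_conv3d_fwd(x$value, dims, w, b), dims)
  tp_node(tape, val, backfn = function(g) {
    r <- cpp_conv3d_bwd(x$value, dims, w, g)
    tp_accum(x, feat(r$gx, dims))
    tp_pgrad_add(tape, paste0(name, ".w"), array(r$gw, dim(w)))
    tp_pgrad_add(tape, paste0(name, ".b"), r$gb)
  })
}

# fused instance norm -> LeakyReLU (each block stage's tail)
op_in_lrelu <- function(tape, model, x, name, slope, eps = 1e-5) {
  gm <- model$params[[paste0(name, ".g")]]
  bt <- model$params[[paste0(name, ".b")]]
  r <- cpp_inlrelu_fwd(x$value, gm, bt, eps, slope)
  dims <- sdim(x$value)
  yv <- r$y
  tp_node(tape, feat(yv, dims), backfn = function(g) {
    b <- cpp_inlrelu_bwd(x$value, yv, g, gm, r$mu, r$istd, slope)
    tp_accum(x, feat(b$gx, dims))
    tp_pgrad_add(tape, paste0(name, ".g"), b$gg)
    tp_pgrad_add(tape, paste0(name, ".b"), b$gb)
  })
}

op_maxpool2 <- function(tape, x) {
  dims <- sdim(x$value)
  r <- cpp_maxpool2_fwd(x$value, dims)
  odims <- dims %/% 2L
  val <- feat(r$out, odims)
  nin <- prod(dims)
  tp_node(tape, val, backfn = function(g) {
    tp_accum(x, feat(cpp_maxpool2_bwd(r$argmax, g, nin), dims))
  })
}

op_upconv2 <- function(tape, model, x, name) {
  w <- model$params[[paste0(name, ".w")]]
  b <- model$params[[paste0(name, ".b")]]
  dims <- sdim(x$value)
  odims <- dims * 2L
  val <- feat(cpp_upconv2_fwd(x$value, dims, w, b), odims)
  tp_node(tape, val, backfn = function(g) {
    r <- cpp_upconv2_bwd(x$value, dims, w, g)
    tp_accum(x, feat(r$gx, dims))
    tp_pgrad_add(tape, paste0(name, ".w"), array(r$gw, dim(w)))
    tp_pgrad_add(tape, paste0(name, ".b"), r$gb)
  })
}

op_concat <- function(tape, xs) {
  dims <- sdim(xs[[1]]$value)
  cols <- vapply(xs, function(x) ncol(x$value), integer(1))
  val <- feat(do.call(cbind, lapply(xs, function(x) x$value)), dims)
  tp_node(tape, val, backfn = function(g) {
    at <- 0L
    for (i in seq_along(xs)) {
      tp_accum(xs[[i]], feat(g[, at + seq_len(cols[i]), drop = FALSE], dims))
      at <- at + cols[i]
    }
  })
}

# 1x1x1 convolution head (a plain per-voxel linear map)
op_head <- function(tape, model, x, name) {
  w <- model$params[[paste0(name, ".w")]]   # Cin x Cout
  b <- model$params[[paste0(name, ".b")]]
  v <- x$value
  val <- feat(v %*% w + rep(b, each = nrow(v)), sdim(v))
  tp_node(tape, val, backfn = function(g) {
    tp_accum(x, feat(g %*% t(w), sdim(v)))
    tp_pgrad_add(tape, paste0(name, ".w"), crossprod(v, g))
    tp_pgrad_add(tape, paste0(name, ".b"), colSums(g))
  })
}

# numerically stable per-voxel binary cross-entropy on logits, summed over
# class channels and averaged over voxels
op_bce_logits <- function(tape, x, target) {
  z <- x$value
  n <- nrow(z)
  le <- pmax(z, 0) - z * target + log1p(exp(-abs(z)))
  val <- sum(le) / n
  tp_node(tape, val, backfn = function(g) {
    p <- stats::plogis(z)
    tp_accum(x, feat((p - target) * (g / n), sdim(z)))
  })
}
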