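# Minimal reverse-mode tape for the segmentation network.
#
# Feature maps are N x C matrices (one column per channel) with the spatial
# shape kept in attr "sdim"; N = prod(sdim).  Each node records its value and
# a backward closure that routes the incoming gradient to its parents and
# accumulates parameter gradients in tape$pgrads.  The network is a static
# DAG built fresh per forward pass, so plain reverse creation order is a
# valid topological order for backpropagation.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$pgrads <- new.env(parent = emptyenv())
  tp
}

tp_node <- function(tape, value, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backfn <- backfn
  tape$nodes[[length(tape$nodes) + 1L]] <- nd
  nd
}

tp_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

tp_pgrad_add <- function(tape, name, g) {
  cur <- tape$pgrads[[name]]
  tape$pgrads[[name]] <- if (is.null(cur)) g else cur + g
}

# run reverse-mode accumulation from a scalar loss node
tp_backward <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (i in rev(seq_along(tape$nodes))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
    # release memory as soon as a node has been consumed
    nd$value <- NULL
    nd$grad <- NULL
  }
  invisible(NULL)
}

sdim <- function(x) attr(x, "sdim")

feat <- function(mat, dims) {
  attr(mat, "sdim") <- as.integer(dims)
  mat
}
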