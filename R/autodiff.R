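#' @useDynLib aopmeter, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# A compact reverse-mode autodiff tape.
#
# Values are dense arrays, typically (H, W, C, N); scalars are length-1
# numerics. Each node stores its value, its parent node ids, and a backward
# closure mapping the incoming gradient to a list of parent gradients.
# Trainable parameters live in an environment (name -> list(value, grad,
# m, v, trainable)) shared across tapes so the optimizer can step them.
# ---------------------------------------------------------------------------

tape_new <- function(params, train = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp$params <- params
  tp$train <- train
  tp
}

tp_push <- function(tp, value, parents = integer(), backfn = NULL, param = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- list(value = value, parents = parents, backfn = backfn, param = param)
  tp$n <- n
  n
}

# NB: force(id) first - `id` is often a promise whose evaluation pushes the
# very node being read, and `tp$nodes` must be fetched after that happens.
tp_value <- function(tp, id) {
  force(id)
  tp$nodes[[id]]$value
}

op_input <- function(tp, value) tp_push(tp, value)

op_param <- function(tp, name) {
  stopifnot(!is.null(tp$params[[name]]))
  tp_push(tp, tp$params[[name]]$value, param = name)
}

#' Run the backward pass of a tape
#'
#' Seeds the gradient of `loss_id` with 1, propagates gradients to every
#' reachable node in reverse topological (creation) order, and accumulates
#' gradients of parameter leaves into the shared parameter environment.
#'
#' @param tp tape environment from `tape_new()`.
#' @param loss_id node id of the scalar loss.
#' @keywords internal
tape_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- 1
  for (id in seq(tp$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tp$nodes[[id]]
    if (!is.null(nd$param)) {
      p <- tp$params[[nd$param]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
      tp$params[[nd$param]] <- p
    }
    if (!is.null(nd$backfn)) {
      pg <- nd$backfn(g)
      for (j in seq_along(nd$parents)) {
        if (is.null(pg[[j]])) next
        pid <- nd$parents[j]
        grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]] else grads[[pid]] + pg[[j]]
      }
    }
    grads[id] <- list(NULL)  # free memory as we go
  }
  invisible(NULL)
}

# --- basic tensor ops -------------------------------------------------------

op_conv2d <- function(tp, x, wname, bname) {
  wid <- op_param(tp, wname); bid <- op_param(tp, bname)
  xv <- tp_value(tp, x); wv <- tp_value(tp, wid); bv <- tp_value(tp, bid)
  xd <- dim(xv); wd <- dim(wv)
  y <- cpp_conv2d_forward(xv, wv, bv, xd, wd)
  tp_push(tp, y, parents = c(x, wid, bid), backfn = function(dy) {
    gr <- cpp_conv2d_backward(xv, wv, dy, xd, wd)
    list(gr$dx, gr$dw, gr$db)
  })
}

op_relu <- function(tp, x) {
  xv <- tp_value(tp, x)
  y <- pmax(xv, 0)
  dim(y) <- dim(xv)
  tp_push(tp, y, parents = x, backfn = function(dy) list(dy * (xv > 0)))
}

op_sigmoid <- function(tp, x) {
  xv <- tp_value(tp, x)
  y <- 1 / (1 + exp(-xv))
  tp_push(tp, y, parents = x, backfn = function(dy) list(dy * y * (1 - y)))
}

op_maxpool2 <- function(tp, x) {
  xv <- tp_value(tp, x)
  fw <- cpp_maxpool2_forward(xv, dim(xv))
  xd <- dim(xv)
  tp_push(tp, fw$y, parents = x,
          backfn = function(dy) list(cpp_maxpool2_backward(dy, fw$idx, xd)))
}

op_upsample2 <- function(tp, x) {
  xv <- tp_value(tp, x)
  xd <- dim(xv)
  tp_push(tp, cpp_upsample2_forward(xv, xd), parents = x,
          backfn = function(dy) list(cpp_upsample2_backward(dy, xd)))
}

op_concat <- function(tp, ids) {
  vals <- lapply(ids, function(i) tp_value(tp, i))
  dims <- lapply(vals, dim)
  cs <- vapply(dims, function(d) d[3], 0)
  d0 <- dims[[1]]
  y <- array(0, c(d0[1], d0[2], sum(cs), d0[4]))
  at <- 0L
  for (v in vals) {
    y[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  tp_push(tp, y, parents = as.integer(ids), backfn = function(dy) {
    out <- vector("list", length(ids)); at <- 0L
    for (j in seq_along(ids)) {
      ck <- dy[, , at + seq_len(cs[j]), , drop = FALSE]
      dim(ck) <- dims[[j]]
      out[[j]] <- ck
      at <- at + cs[j]
    }
    out
  })
}

op_add <- function(tp, a, b) {
  y <- tp_value(tp, a) + tp_value(tp, b)
  tp_push(tp, y, parents = c(a, b), backfn = function(dy) list(dy, dy))
}

op_mul <- function(tp, a, b) {
  av <- tp_value(tp, a); bv <- tp_value(tp, b)
  tp_push(tp, av * bv, parents = c(a, b),
          backfn = function(dy) list(dy * bv, dy * av))
}

# Broadcast a per-channel vector over an (H, W, C, N) array.
bcast_ch <- function(v, d) array(rep(v, each = d[1] * d[2]), d)

# Per-channel reduction of an (H, W, C, N) array (sum over H, W, N);
# .colSums avoids duplicating the array to reshape it.
reduce_ch <- function(x, d) {
  m <- .colSums(x, d[1] * d[2], d[3] * d[4])
  rowSums(matrix(m, d[3], d[4]))
}

# Batch normalization over (H, W, N) per channel. Running statistics are kept
# in non-trainable parameter slots "<name>.rm" / "<name>.rv".
op_bn <- function(tp, x, name, eps = 1e-5, momentum = 0.1) {
  gid <- op_param(tp, paste0(name, ".g"))
  bid <- op_param(tp, paste0(name, ".b"))
  xv <- tp_value(tp, x)
  d <- dim(xv); C <- d[3]; M <- d[1] * d[2] * d[4]
  g <- tp_value(tp, gid); b <- tp_value(tp, bid)
  if (tp$train) {
    mu <- reduce_ch(xv, d) / M
    va <- reduce_ch(xv * xv, d) / M - mu^2
    rm_ <- tp$params[[paste0(name, ".rm")]]
    rv_ <- tp$params[[paste0(name, ".rv")]]
    rm_$value <- (1 - momentum) * rm_$value + momentum * mu
    rv_$value <- (1 - momentum) * rv_$value + momentum * va
    tp$params[[paste0(name, ".rm")]] <- rm_
    tp$params[[paste0(name, ".rv")]] <- rv_
  } else {
    mu <- tp$params[[paste0(name, ".rm")]]$value
    va <- tp$params[[paste0(name, ".rv")]]$value
  }
  sd_ <- sqrt(va + eps)
  xhat <- cpp_chan_affine(xv, 1 / sd_, -mu / sd_, d)
  y <- cpp_chan_affine(xhat, g, b, d)
  train <- tp$train
  tp_push(tp, y, parents = c(x, gid, bid), backfn = function(dy) {
    dg <- reduce_ch(dy * xhat, d)
    db <- reduce_ch(dy, d)
    if (train) {
      dx <- cpp_bn_dx(dy, xhat, db, dg, g / (M * sd_), M, d)
    } else {
      dx <- cpp_chan_affine(dy, g / sd_, numeric(length(g)), d)
    }
    list(dx, dg, db)
  })
}

# Global average pool (H,W,C,N) -> (C,N).
op_gap <- function(tp, x) {
  xv <- tp_value(tp, x)
  d <- dim(xv)
  xm <- xv; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  y <- colMeans(xm)
  dim(y) <- c(d[3], d[4])
  tp_push(tp, y, parents = x, backfn = function(dy) {
    dx <- array(rep(dy / (d[1] * d[2]), each = d[1] * d[2]), d)
    list(dx)
  })
}

# Multiply each channel of x (H,W,C,N) by scale s (C,N).
op_scale_channels <- function(tp, x, s) {
  xv <- tp_value(tp, x); sv <- tp_value(tp, s)
  d <- dim(xv)
  sb <- array(rep(sv, each = d[1] * d[2]), d)
  tp_push(tp, xv * sb, parents = c(x, s), backfn = function(dy) {
    ds <- dy * xv; dim(ds) <- c(d[1] * d[2], d[3] * d[4])
    ds <- colSums(ds)
    dim(ds) <- dim(sv)
    list(dy * sb, ds)
  })
}

# Shared 1-D convolution over the channel axis (zero padded), x: (C,N).
op_conv1d_channels <- function(tp, x, kname) {
  kid <- op_param(tp, kname)
  xv <- tp_value(tp, x); kv <- tp_value(tp, kid)
  y <- cpp_conv1d_channels(xv, kv)
  tp_push(tp, y, parents = c(x, kid), backfn = function(dy) {
    gr <- cpp_conv1d_channels_backward(xv, kv, dy)
    list(gr$dx, as.numeric(gr$dk))
  })
}

# Fully connected: x (C,N), weight (K,C), bias (K) -> (K,N).
op_fc <- function(tp, x, wname, bname) {
  wid <- op_param(tp, wname); bid <- op_param(tp, bname)
  xv <- tp_value(tp, x); wv <- tp_value(tp, wid); bv <- tp_value(tp, bid)
  y <- wv %*% xv + bv
  tp_push(tp, y, parents = c(x, wid, bid), backfn = function(dy) {
    list(t(wv) %*% dy, dy %*% t(xv), rowSums(dy))
  })
}

# Softmax over the channel axis of (H,W,C,N).
op_softmax_channels <- function(tp, x) {
  xv <- tp_value(tp, x)
  d <- dim(xv)
  # per-pixel reductions over the (small) channel axis, via (H*W, C, N) views
  ch_cols <- function(a) {
    dim(a) <- c(d[1] * d[2], d[3], d[4])
    a
  }
  bchan <- function(v) {
    # v: (H*W, N) -> (H,W,C,N)
    out <- array(0, c(d[1] * d[2], d[3], d[4]))
    for (cc in seq_len(d[3])) out[, cc, ] <- v
    dim(out) <- d
    out
  }
  xm <- ch_cols(xv)
  m <- xm[, 1, ]
  for (cc in seq_len(d[3])[-1]) m <- pmax(m, xm[, cc, ])
  e <- exp(xv - bchan(m))
  em <- ch_cols(e)
  s <- em[, 1, ]
  for (cc in seq_len(d[3])[-1]) s <- s + em[, cc, ]
  y <- e / bchan(s)
  tp_push(tp, y, parents = x, backfn = function(dy) {
    dm <- ch_cols(dy * y)
    dot <- dm[, 1, ]
    for (cc in seq_len(d[3])[-1]) dot <- dot + dm[, cc, ]
    dx <- y * (dy - bchan(dot))
    list(dx)
  })
}

# Softmax over rows of a (K,N) matrix (class logits).
op_softmax_cols <- function(tp, x) {
  xv <- tp_value(tp, x)
  m <- apply(xv, 2, max)
  e <- exp(sweep(xv, 2, m, "-"))
  y <- sweep(e, 2, colSums(e), "/")
  tp_push(tp, y, parents = x, backfn = function(dy) {
    dot <- colSums(dy * y)
    list(y * sweep(dy, 2, dot, "-"))
  })
}
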