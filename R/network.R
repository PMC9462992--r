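# The multitask encoder-decoder network: one shared encoder whose
# downsampling stages carry efficient-channel-attention units, a
# classification head (two residual blocks), a segmentation decoder with
# U-Net skip connections and per-pixel softmax, and a landmark-heatmap
# decoder whose levels receive attention-fusion (AFM) injections from the
# segmentation stream.

#' Network configuration
#'
#' @param in_channels input image channels (1 for grayscale).
#' @param base_channels channels of the first encoder block; doubled at each
#'   of the five blocks (64 clinically, reducible to 8 for desk-scale runs).
#' @param n_classes_seg segmentation classes incl. background (3).
#' @param n_heatmaps landmark heatmaps (3).
#' @param eca_gamma,eca_b coefficients of the adaptive attention kernel-size
#'   rule (2 and 1).
#' @param input_size network input (H', W'); both divisible by 16 because
#'   blocks 1-4 downsample and the decoders restore full resolution.
#' @export
mtunet_config <- function(in_channels = 1, base_channels = 64,
                          n_classes_seg = 3, n_heatmaps = 3,
                          eca_gamma = 2, eca_b = 1,
                          input_size = c(384, 416)) {
  if (any(input_size %% 16 != 0)) stop("input size must be divisible by 16")
  if (base_channels < 2) stop("base_channels must be >= 2")
  structure(list(in_channels = in_channels, base_channels = base_channels,
                 depth = 5, n_classes_seg = n_classes_seg,
                 n_heatmaps = n_heatmaps, eca_gamma = eca_gamma,
                 eca_b = eca_b, input_size = input_size),
            class = "mtunet_config")
}

#' Adaptive attention kernel size
#'
#' \eqn{k = |(\log_2 C + b)/\gamma|_{odd}}: the value is truncated to an
#' integer and incremented if even, yielding the nearest odd size, never
#' below 1.
#'
#' @param C channel count (>= 1).
#' @param gamma,b rule coefficients.
#' @return odd positive integer.
#' @examples
#' eca_kernel_size(64)   # 3
#' eca_kernel_size(256)  # 5
#' @export
eca_kernel_size <- function(C, gamma = 2, b = 1) {
  if (C < 1) stop("C must be >= 1")
  t <- (log2(C) + b) / gamma
  k <- trunc(t)
  if (k %% 2 == 0) k <- k + 1
  max(1L, as.integer(k))
}

# --- parameter store --------------------------------------------------------

params_new <- function() new.env(parent = emptyenv())

param_add <- function(env, name, value, trainable = TRUE) {
  env[[name]] <- list(value = value, grad = NULL, m = NULL, v = NULL,
                      trainable = trainable)
  invisible(env)
}

kaiming_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

add_conv <- function(env, name, kh, kw, cin, cout) {
  param_add(env, paste0(name, ".w"), kaiming_conv(kh, kw, cin, cout))
  param_add(env, paste0(name, ".b"), numeric(cout))
}

add_bn <- function(env, name, C) {
  param_add(env, paste0(name, ".g"), rep(1, C))
  param_add(env, paste0(name, ".b"), numeric(C))
  param_add(env, paste0(name, ".rm"), numeric(C), trainable = FALSE)
  param_add(env, paste0(name, ".rv"), rep(1, C), trainable = FALSE)
}

mtu_channels <- function(cfg) cfg$base_channels * c(1, 2, 4, 8, 16)

#' Build a multitask network with Kaiming-initialized weights
#'
#' @param config an [mtunet_config()].
#' @param seed RNG seed for the initialization.
#' @return an object of class `mtunet` (parameter environment + config).
#' @export
mtunet <- function(config = mtunet_config(), seed = 1L) {
  ch <- mtu_channels(config)
  env <- params_new()
  with_seed_(seed, {
    cin <- config$in_channels
    for (i in 1:5) {
      add_conv(env, sprintf("enc%d.c1", i), 3, 3, cin, ch[i])
      add_bn(env, sprintf("enc%d.bn1", i), ch[i])
      add_conv(env, sprintf("enc%d.c2", i), 3, 3, ch[i], ch[i])
      add_bn(env, sprintf("enc%d.bn2", i), ch[i])
      cin <- ch[i]
      if (i < 5) {
        k <- eca_kernel_size(ch[i], config$eca_gamma, config$eca_b)
        param_add(env, sprintf("eca%d.k", i),
                  stats::rnorm(k, sd = sqrt(2 / k)))
      }
    }
    # Task1: two residual blocks on the bottleneck + GAP + FC + softmax
    for (r in 1:2) {
      add_conv(env, sprintf("t1.res%d.c1", r), 3, 3, ch[5], ch[5])
      add_bn(env, sprintf("t1.res%d.bn1", r), ch[5])
      add_conv(env, sprintf("t1.res%d.c2", r), 3, 3, ch[5], ch[5])
      add_bn(env, sprintf("t1.res%d.bn2", r), ch[5])
    }
    param_add(env, "t1.fc.w", matrix(stats::rnorm(2 * ch[5], sd = sqrt(2 / ch[5])), 2, ch[5]))
    param_add(env, "t1.fc.b", numeric(2))
    # Task2/Task3 upsampling blocks; level j works at encoder level 5-j
    for (j in 1:4) {
      cl <- ch[5 - j]        # output channels at this level
      cu <- ch[6 - j]        # channels arriving from the coarser level
      add_conv(env, sprintf("t2.up%d.c1", j), 3, 3, cu + cl, cl)
      add_bn(env, sprintf("t2.up%d.bn1", j), cl)
      add_conv(env, sprintf("t2.up%d.c2", j), 3, 3, cl, cl)
      add_bn(env, sprintf("t2.up%d.bn2", j), cl)
      # AFM at this level: S_prev (t2, coarser), L_prev (t3, coarser)
      cs <- if (j == 1) ch[5] else ch[6 - j]
      add_conv(env, sprintf("afm%d.c1", j), 1, 1, cs + cu, cu)
      add_conv(env, sprintf("afm%d.c2", j), 1, 1, cu, 1)
      add_bn(env, sprintf("afm%d.bn", j), 1)
      add_conv(env, sprintf("t3.up%d.c1", j), 3, 3, cu + cl + cl, cl)
      add_bn(env, sprintf("t3.up%d.bn1", j), cl)
      add_conv(env, sprintf("t3.up%d.c2", j), 3, 3, cl, cl)
      add_bn(env, sprintf("t3.up%d.bn2", j), cl)
    }
    add_conv(env, "t2.out", 1, 1, ch[1], config$n_classes_seg)
    add_conv(env, "t3.out", 1, 1, ch[1], config$n_heatmaps)
    # prior-aware head init: heatmap targets are overwhelmingly background,
    # so the sigmoid head starts near sigmoid(-2) ~ 0.12 instead of 0.5,
    # which removes a long background-suppression transient
    b3 <- env[["t3.out.b"]]; b3$value[] <- -2; env[["t3.out.b"]] <- b3
    param_add(env, "loss.s1", 0)
    param_add(env, "loss.s2", 0)
  })
  structure(list(params = env, config = config), class = "mtunet")
}

#' @export
print.mtunet <- function(x, ...) {
  cat(sprintf("<mtunet> base_channels=%d  input=%dx%d  parameters=%s\n",
              x$config$base_channels, x$config$input_size[1],
              x$config$input_size[2],
              format(mtunet_n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#' @param model an `mtunet`.
#' @export
mtunet_n_parameters <- function(model) {
  nm <- ls(model$params)
  sum(vapply(nm, function(n) {
    p <- model$params[[n]]
    if (p$trainable) length(p$value) else 0L
  }, 0))
}

# --- forward passes ---------------------------------------------------------

conv_bn_relu <- function(tp, x, cname, bname) {
  op_relu(tp, op_bn(tp, op_conv2d(tp, x, paste0(cname, ".w"),
                                  paste0(cname, ".b")), bname))
}

op_eca_unit <- function(tp, x, kname) {
  pooled <- op_gap(tp, x)
  wts <- op_sigmoid(tp, op_conv1d_channels(tp, pooled, kname))
  op_scale_channels(tp, x, wts)
}

# Broadcast-multiply a 1-channel mask (H,W,1,N) over x (H,W,C,N).
op_mul_mask <- function(tp, x, m) {
  xv <- tp_value(tp, x); mv <- tp_value(tp, m)
  d <- dim(xv)
  m3 <- mv[, , 1, , drop = FALSE]; dim(m3) <- c(d[1], d[2], d[4])
  mb <- array(0, c(d[1] * d[2], d[3], d[4]))
  for (cc in seq_len(d[3])) mb[, cc, ] <- m3
  dim(mb) <- d
  tp_push(tp, xv * mb, parents = c(x, m), backfn = function(dy) {
    p <- dy * xv; dim(p) <- c(d[1] * d[2], d[3], d[4])
    dm <- p[, 1, ]
    for (cc in seq_len(d[3])[-1]) dm <- dm + p[, cc, ]
    dim(dm) <- dim(mv)
    list(dy * mb, dm)
  })
}

# Shared encoder: returns the bottleneck node and the pre-pool skip nodes.
mtu_encode <- function(tp, x, cfg) {
  skips <- vector("list", 4)
  h <- x
  for (i in 1:5) {
    h <- conv_bn_relu(tp, h, sprintf("enc%d.c1", i), sprintf("enc%d.bn1", i))
    h <- conv_bn_relu(tp, h, sprintf("enc%d.c2", i), sprintf("enc%d.bn2", i))
    if (i < 5) {
      skips[[i]] <- h
      h <- op_maxpool2(tp, h)
      h <- op_eca_unit(tp, h, sprintf("eca%d.k", i))
    }
  }
  list(bottleneck = h, skips = skips)
}

mtu_task1 <- function(tp, bott) {
  h <- bott
  for (r in 1:2) {
    sc <- h
    h <- conv_bn_relu(tp, h, sprintf("t1.res%d.c1", r), sprintf("t1.res%d.bn1", r))
    h <- op_bn(tp, op_conv2d(tp, h, sprintf("t1.res%d.c2.w", r),
                             sprintf("t1.res%d.c2.b", r)),
               sprintf("t1.res%d.bn2", r))
    h <- op_relu(tp, op_add(tp, h, sc))
  }
  op_softmax_cols(tp, op_fc(tp, op_gap(tp, h), "t1.fc.w", "t1.fc.b"))
}

mtu_task23 <- function(tp, enc) {
  s_prev <- enc$bottleneck
  l_prev <- enc$bottleneck
  h2 <- enc$bottleneck
  seg <- NULL; hm <- NULL
  for (j in 1:4) {
    skip <- enc$skips[[5 - j]]
    # Task2 level
    h2u <- op_upsample2(tp, h2)
    h2 <- op_concat(tp, c(h2u, skip))
    h2 <- conv_bn_relu(tp, h2, sprintf("t2.up%d.c1", j), sprintf("t2.up%d.bn1", j))
    h2 <- conv_bn_relu(tp, h2, sprintf("t2.up%d.c2", j), sprintf("t2.up%d.bn2", j))
    s_cur <- h2
    # AFM: gate the current shared features with a mask learned from the
    # coarser-level shared and task-specific features
    fm <- op_conv2d(tp, op_concat(tp, c(s_prev, l_prev)),
                    sprintf("afm%d.c1.w", j), sprintf("afm%d.c1.b", j))
    m <- op_sigmoid(tp, op_bn(tp, op_conv2d(tp, fm, sprintf("afm%d.c2.w", j),
                                            sprintf("afm%d.c2.b", j)),
                              sprintf("afm%d.bn", j)))
    mu <- op_upsample2(tp, m)
    lu <- op_upsample2(tp, l_prev)
    wmap <- op_concat(tp, c(lu, op_mul_mask(tp, s_cur, mu)))
    # Task3 level
    h3 <- op_concat(tp, c(wmap, skip))
    h3 <- conv_bn_relu(tp, h3, sprintf("t3.up%d.c1", j), sprintf("t3.up%d.bn1", j))
    h3 <- conv_bn_relu(tp, h3, sprintf("t3.up%d.c2", j), sprintf("t3.up%d.bn2", j))
    s_prev <- s_cur
    l_prev <- h3
  }
  seg <- op_softmax_channels(tp, op_conv2d(tp, h2, "t2.out.w", "t2.out.b"))
  hm <- op_sigmoid(tp, op_conv2d(tp, l_prev, "t3.out.w", "t3.out.b"))
  list(seg_probs = seg, heatmaps = hm)
}

#' Forward pass of the multitask network
#'
#' @param model an `mtunet`.
#' @param x input batch array (H, W, C, N) in [-1, 1]; a single (H, W)
#'   matrix is promoted.
#' @param train run batch-norm in training mode (batch statistics).
#' @param tasks subset of `c("task1", "task2", "task3")`.
#' @return list with `class_probs` (2 x N), `seg_probs` (H, W, 3, N),
#'   `heatmaps` (H, W, 3, N) - NULL for tasks not requested - plus the tape
#'   and node ids (`ids`) for training.
#' @export
mtunet_forward <- function(model, x, train = FALSE,
                           tasks = c("task1", "task2", "task3")) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1, 1))
  stopifnot(length(dim(x)) == 4)
  if (any(dim(x)[1:2] %% 16 != 0)) stop("input size must be divisible by 16")
  tp <- tape_new(model$params, train)
  xin <- op_input(tp, x)
  enc <- mtu_encode(tp, xin, model$config)
  ids <- list(bottleneck = enc$bottleneck)
  out <- list(class_probs = NULL, seg_probs = NULL, heatmaps = NULL)
  if ("task1" %in% tasks) {
    ids$class_probs <- mtu_task1(tp, enc$bottleneck)
    out$class_probs <- tp_value(tp, ids$class_probs)
  }
  if (any(c("task2", "task3") %in% tasks)) {
    t23 <- mtu_task23(tp, enc)
    ids$seg_probs <- t23$seg_probs
    ids$heatmaps <- t23$heatmaps
    out$seg_probs <- tp_value(tp, t23$seg_probs)
    out$heatmaps <- tp_value(tp, t23$heatmaps)
  }
  out$tape <- tp
  out$ids <- ids
  out
}

# Classification head alone, starting from a precomputed bottleneck value
# (used when the encoder is frozen in stage 2).
mtunet_forward_task1 <- function(model, bottleneck, train = FALSE) {
  tp <- tape_new(model$params, train)
  bid <- op_input(tp, bottleneck)
  cid <- mtu_task1(tp, bid)
  list(class_probs = tp_value(tp, cid), tape = tp, ids = list(class_probs = cid))
}

# --- checkpoints ------------------------------------------------------------

#' Save a model checkpoint
#'
#' Stores weights, optimizer state, configuration and the RNG state so a
#' run can be resumed reproducibly.
#'
#' @param model an `mtunet`; @param path destination file.
#' @export
mtunet_save <- function(model, path) {
  rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(config = model$config,
               params = as.list(model$params),
               rng_state = rng), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [mtunet_save()].
#' @param restore_rng restore the saved RNG state.
#' @export
mtunet_load <- function(path, restore_rng = FALSE) {
  ck <- readRDS(path)
  env <- params_new()
  for (n in names(ck$params)) env[[n]] <- ck$params[[n]]
  if (restore_rng && !is.null(ck$rng_state))
    assign(".Random.seed", ck$rng_state, envir = globalenv())
  structure(list(params = env, config = ck$config), class = "mtunet")
}

# Deep-copy a model (parameter environments are mutable).
mtunet_clone <- function(model) {
  env <- params_new()
  for (n in ls(model$params)) env[[n]] <- model$params[[n]]
  structure(list(params = env, config = model$config), class = "mtunet")
}
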