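# The multitask network: attention kernel rule, unit behaviour of the
# channel-attention and fusion gates, output contracts, gradient flow and
# checkpointing.

test_that("adaptive attention kernel size follows the truncate-then-odd rule", {
  expect_equal(eca_kernel_size(2), 1L)
  expect_equal(eca_kernel_size(64), 3L)
  expect_equal(eca_kernel_size(256), 5L)
  expect_equal(eca_kernel_size(8), 3L)    # t = 2, even -> 3
  expect_equal(eca_kernel_size(1), 1L)    # floor at 1
  expect_error(eca_kernel_size(0), ">= 1")
})

test_that("channel attention with a zeroed kernel halves every channel", {
  model <- mtunet(tiny_config(), seed = 1)
  p <- model$params[["eca1.k"]]; p$value[] <- 0; model$params[["eca1.k"]] <- p
  tp <- aopmeter:::tape_new(model$params, FALSE)
  x <- withr::with_seed(2, array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2)))
  xid <- aopmeter:::op_input(tp, x)
  out <- aopmeter:::tp_value(tp, aopmeter:::op_eca_unit(tp, xid, "eca1.k"))
  expect_equal(out, 0.5 * x, tolerance = 1e-12)
})

test_that("channel attention preserves shape and never zeroes a channel", {
  model <- mtunet(tiny_config(), seed = 3)
  tp <- aopmeter:::tape_new(model$params, FALSE)
  x <- withr::with_seed(4, array(rnorm(8 * 8 * 2), c(8, 8, 2, 1)))
  xid <- aopmeter:::op_input(tp, x)
  wid <- aopmeter:::op_sigmoid(
    tp, aopmeter:::op_conv1d_channels(tp, aopmeter:::op_gap(tp, xid), "eca1.k"))
  w <- aopmeter:::tp_value(tp, wid)
  expect_true(all(w > 0 & w < 1))
  out <- aopmeter:::tp_value(tp, aopmeter:::op_scale_channels(tp, xid, wid))
  expect_equal(dim(out), dim(x))
})

test_that("the fusion mask gates the shared features as documented", {
  model <- mtunet(tiny_config(), seed = 1)
  tp <- aopmeter:::tape_new(model$params, FALSE)
  x <- withr::with_seed(5, array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)))
  xid <- aopmeter:::op_input(tp, x)
  ones <- aopmeter:::op_input(tp, array(1, c(8, 8, 1, 1)))
  zeros <- aopmeter:::op_input(tp, array(0, c(8, 8, 1, 1)))
  expect_equal(aopmeter:::tp_value(tp, aopmeter:::op_mul_mask(tp, xid, ones)),
               x, tolerance = 1e-12)
  expect_true(all(aopmeter:::tp_value(
    tp, aopmeter:::op_mul_mask(tp, xid, zeros)) == 0))
})

test_that("forward pass honours the output contracts", {
  model <- mtunet(tiny_config(c(32, 48), base = 2), seed = 6)
  x <- withr::with_seed(7, array(runif(32 * 48, -1, 1), c(32, 48, 1, 1)))
  out <- mtunet_forward(model, x)
  expect_equal(dim(out$seg_probs), c(32, 48, 3, 1))
  expect_equal(dim(out$heatmaps), c(32, 48, 3, 1))
  expect_length(out$class_probs, 2)
  expect_equal(sum(out$class_probs), 1, tolerance = 1e-9)
  sums <- apply(out$seg_probs[, , , 1], c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(out$heatmaps >= 0 & out$heatmaps <= 1))
  # eval-mode forward is deterministic
  out2 <- mtunet_forward(model, x)
  expect_identical(out$seg_probs, out2$seg_probs)
  expect_identical(out$class_probs, out2$class_probs)
  expect_error(mtunet_forward(model, array(0, c(30, 48, 1, 1))), "divisible")
})

test_that("parameter count is stable for a fixed configuration", {
  m <- mtunet(tiny_config(), seed = 1)
  expect_equal(mtunet_n_parameters(m), 86880)
  # scales roughly quadratically with width: base 4 has ~4x the parameters
  m4 <- mtunet(mtunet_config(base_channels = 4, input_size = c(16, 16)), seed = 1)
  expect_gt(mtunet_n_parameters(m4) / mtunet_n_parameters(m), 3.5)
})

test_that("gradient flows to every trainable parameter under the joint loss", {
  model <- mtunet(tiny_config(), seed = 9)
  x <- withr::with_seed(10, array(runif(16 * 16 * 2, -1, 1), c(16, 16, 1, 2)))
  mask <- array(0L, c(16, 16, 2))
  mask[4:9, 4:9, ] <- 2L; mask[11:13, 2:6, ] <- 1L
  y1h <- array(0, c(16, 16, 3, 2)); for (k in 0:2) y1h[, , k + 1, ] <- (mask == k)
  hm <- array(0, c(16, 16, 3, 2))
  hm[, , , 1] <- make_heatmaps(c(2, 12), c(6, 12), c(16, 16), 2)
  hm[, , , 2] <- hm[, , , 1]
  fw <- mtunet_forward(model, x, train = TRUE)
  tp <- fw$tape
  ld <- aopmeter:::op_dice_loss(tp, fw$ids$seg_probs, y1h)
  lsc <- withr::with_seed(11, aopmeter:::op_slf(tp, fw$ids$seg_probs, mask, 2, 3, 64L))
  lmse <- aopmeter:::op_mse_heatmap(tp, fw$ids$heatmaps, hm)
  lce <- aopmeter:::op_ce(tp, fw$ids$class_probs, c(1L, 0L))
  ltot <- aopmeter:::op_total_loss(tp, ld, lsc, lmse)
  lall <- aopmeter:::tp_push(tp, aopmeter:::tp_value(tp, ltot) +
                               aopmeter:::tp_value(tp, lce),
                             parents = c(ltot, lce),
                             backfn = function(dy) list(dy, dy))
  aopmeter:::tape_backward(tp, lall)
  for (nm in ls(model$params)) {
    p <- model$params[[nm]]
    if (!p$trainable) next
    expect_false(is.null(p$grad), label = paste("gradient reaches", nm))
    # conv biases immediately followed by batch-norm legitimately receive a
    # (numerically) zero gradient; require nonzero only for weights/scales
    if (grepl("\\.(w|g|k)$", nm) || nm %in% c("loss.s1", "loss.s2"))
      expect_true(any(p$grad != 0), label = paste("nonzero gradient at", nm))
  }
})

test_that("analytic gradients match finite differences on smooth parameters", {
  model <- mtunet(tiny_config(), seed = 12)
  x <- withr::with_seed(13, array(runif(16 * 16, -1, 1), c(16, 16, 1, 1)))
  hm <- array(0, c(16, 16, 3, 1))
  hm[, , , 1] <- make_heatmaps(c(3, 4), c(11, 12), c(16, 16), 2)
  loss_of <- function() {
    fw <- mtunet_forward(model, x, train = TRUE, tasks = c("task2", "task3"))
    list(tp = fw$tape,
         id = aopmeter:::op_mse_heatmap(fw$tape, fw$ids$heatmaps, hm))
  }
  snap <- as.list(model$params)
  res <- loss_of()
  aopmeter:::tape_backward(res$tp, res$id)
  sel <- c("t3.up1.c1.w", "t2.up2.c2.w", "afm2.c1.w", "t3.out.b")
  grads <- lapply(sel, function(nm) model$params[[nm]]$grad)
  names(grads) <- sel
  eps <- 1e-6
  for (nm in sel) {
    g <- grads[[nm]]
    idx <- which(abs(g) == max(abs(g)))[1]
    for (nmr in names(snap)) model$params[[nmr]] <- snap[[nmr]]
    p <- model$params[[nm]]; p$value[idx] <- p$value[idx] + eps
    model$params[[nm]] <- p
    lp <- aopmeter:::tp_value(loss_of()$tp, res$id)
    for (nmr in names(snap)) model$params[[nmr]] <- snap[[nmr]]
    p <- model$params[[nm]]; p$value[idx] <- p$value[idx] - eps
    model$params[[nm]] <- p
    lm <- aopmeter:::tp_value(loss_of()$tp, res$id)
    num <- (lp - lm) / (2 * eps)
    expect_equal(g[idx], num, tolerance = 1e-3,
                 label = paste("gradient of", nm))
    for (nmr in names(snap)) model$params[[nmr]] <- snap[[nmr]]
  }
})

test_that("checkpoints round-trip to identical forward outputs", {
  model <- mtunet(tiny_config(c(32, 32)), seed = 14)
  x <- withr::with_seed(15, array(runif(32 * 32, -1, 1), c(32, 32, 1, 1)))
  out1 <- mtunet_forward(model, x)
  path <- withr::local_tempfile(fileext = ".ckpt")
  mtunet_save(model, path)
  model2 <- mtunet_load(path)
  out2 <- mtunet_forward(model2, x)
  expect_identical(out1$seg_probs, out2$seg_probs)
  expect_identical(out1$heatmaps, out2$heatmaps)
  expect_identical(out1$class_probs, out2$class_probs)
})
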