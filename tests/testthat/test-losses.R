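# Loss functions: closed-form identities, the brute-force oracle for the
# convex shape loss, Monte-Carlo convergence, and the uncertainty-weighted
# composition.

test_that("cross-entropy matches its closed forms", {
  expect_lt(cross_entropy(1, 1 - 1e-12), 1e-6)   # perfect prediction
  expect_equal(cross_entropy(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(0, 0.5), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
})

test_that("dice loss matches its closed forms and empty-empty convention", {
  y <- c(1, 1, 0, 0)
  expect_equal(dice_loss(y, y), 0)
  expect_equal(dice_loss(y, 1 - y), 1)
  expect_equal(dice_loss(c(1, 0, 0, 0), c(0.5, 0, 0, 0)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(dice_loss(numeric(4), numeric(4)), 0)
})

test_that("heatmap MSE is a per-pixel mean weighted by importance", {
  h <- array(runif(8 * 8 * 3), c(8, 8, 3))
  expect_equal(mse_heatmap_loss(h, h), 0)
  h2 <- h; h2[3, 4, 2] <- h[3, 4, 2] + 1
  expect_equal(mse_heatmap_loss(h2, h), 0.8 / 64, tolerance = 1e-12)
  h3 <- h + 2 * (h2 - h)
  expect_equal(mse_heatmap_loss(h3, h), 4 * mse_heatmap_loss(h2, h),
               tolerance = 1e-12)
  expect_error(mse_heatmap_loss(h, h[1:4, , , drop = FALSE]), "mismatch")
})

test_that("shape loss is zero at the optimum and for degenerate masks", {
  y <- matrix(0L, 12, 12); y[3:9, 3:9] <- 1L
  expect_equal(shape_constrained_loss(y, (y == 1) * 1, 1, exhaustive = TRUE),
               0, ignore_attr = TRUE)
  expect_equal(shape_constrained_loss(matrix(0L, 5, 5), matrix(0.5, 5, 5), 1), 0)
})

test_that("exhaustive shape loss equals the brute-force triple loop", {
  withr::with_seed(31, {
    for (k in 1:20) {
      yb <- random_blob_mask(12, seed = 1000 + k)
      p <- matrix(runif(144), 12, 12)
      mine <- shape_constrained_loss(yb * 1L, p, class_id = 1,
                                     exhaustive = TRUE)
      oracle <- slf_brute_force(yb, p)
      expect_lt(abs(as.numeric(mine) - as.numeric(oracle)), 1e-9)
      expect_lt(abs(attr(mine, "sum") - attr(oracle, "sum")), 1e-9)
    }
  })
})

test_that("Monte-Carlo shape loss converges to the exhaustive value", {
  yb <- random_blob_mask(12, seed = 77)
  p <- withr::with_seed(78, matrix(runif(144), 12, 12))
  exact <- as.numeric(shape_constrained_loss(yb * 1L, p, 1, exhaustive = TRUE))
  mc <- shape_constrained_loss(yb * 1L, p, 1, n_triplets = 1e5, seed = 5)
  expect_lt(abs(as.numeric(mc) - exact), 3 * attr(mc, "se"))
})

test_that("the shape loss penalizes a concave notch more than a convex fill", {
  y <- matrix(0L, 12, 12); y[3:10, 3:10] <- 1L
  convex <- matrix(0, 12, 12); convex[y == 1L] <- 0.9
  notch <- convex; notch[5:8, 5:8] <- 0.1  # depressed interior
  l_convex <- shape_constrained_loss(y, convex, 1, exhaustive = TRUE)
  l_notch <- shape_constrained_loss(y, notch, 1, exhaustive = TRUE)
  expect_gt(as.numeric(l_notch), as.numeric(l_convex))
  expect_gte(as.numeric(l_convex), 0)
})

test_that("total loss composes the components with uncertainty weighting", {
  expect_equal(total_loss(0.4, 0.1, 0.2, loss_weights()), 0.35,
               tolerance = 1e-12)
  expect_equal(total_loss(0, 0, 0, loss_weights()), 0)
  # with nonzero log-variances, theta = exp(-s) and the s/2 terms appear
  w <- loss_weights(s1 = 0.2, s2 = -0.1)
  expect_equal(total_loss(1, 1, 1, w),
               0.5 * (exp(-0.2) + exp(0.1)) + 0.5 + 0.1 - 0.05,
               tolerance = 1e-12)
})

test_that("tape losses agree with the numeric forms and drive s-gradients", {
  model <- mtunet(tiny_config(), seed = 2)
  tp <- aopmeter:::tape_new(model$params, TRUE)
  withr::with_seed(3, {
    p <- array(runif(16 * 16 * 3 * 1), c(16, 16, 3, 1))
    p <- p / array(rep(apply(p, c(1, 2, 4), sum), times = 3), dim(p))
  })
  mask <- array(0L, c(16, 16, 1)); mask[4:10, 4:10, 1] <- 2L
  y1h <- array(0, c(16, 16, 3, 1)); for (k in 0:2) y1h[, , k + 1, 1] <- (mask[, , 1] == k)
  hm <- array(0, c(16, 16, 3, 1))
  hm[, , , 1] <- make_heatmaps(c(3, 3), c(12, 10), c(16, 16), 2)
  pid <- aopmeter:::op_input(tp, p)
  ld <- aopmeter:::op_dice_loss(tp, pid, y1h)
  expect_equal(aopmeter:::tp_value(tp, ld),
               dice_loss(y1h[, , 2:3, ], p[, , 2:3, ]), tolerance = 1e-12)
  lmse <- aopmeter:::op_mse_heatmap(tp, pid, hm)
  expect_equal(aopmeter:::tp_value(tp, lmse),
               mse_heatmap_loss(p[, , , 1], hm[, , , 1]), tolerance = 1e-12)
  lsc <- withr::with_seed(5, aopmeter:::op_slf(tp, pid, mask, 2, 3, 256L))
  ltot <- aopmeter:::op_total_loss(tp, ld, lsc, lmse)
  expect_equal(aopmeter:::tp_value(tp, ltot),
               total_loss(aopmeter:::tp_value(tp, ld),
                          aopmeter:::tp_value(tp, lsc),
                          aopmeter:::tp_value(tp, lmse), loss_weights()),
               tolerance = 1e-12)
  aopmeter:::tape_backward(tp, ltot)
  # the log-variance gradients are -w1 theta L + 1/2, nonzero off equilibrium
  g1 <- model$params[["loss.s1"]]$grad
  expect_equal(g1, -0.5 * aopmeter:::tp_value(tp, ld) + 0.5, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(g1, 0)))
})
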