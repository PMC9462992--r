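# Ellipse algebra, direct least-squares fitting, tangent construction and
# the AoP angle computation.

test_that("conic and geometric ellipse forms agree and round-trip", {
  withr::with_seed(11, {
    for (k in 1:20) {
      ctr <- runif(2, -50, 50)
      a <- runif(1, 2, 30); b <- runif(1, 1, a)
      ang <- runif(1, 0, 180)
      e <- ellipse(ctr, a, b, ang)
      e2 <- conic_to_ellipse(e$conic)
      expect_equal(e2$center, e$center, tolerance = 1e-9)
      expect_equal(e2$a, e$a, tolerance = 1e-9)
      expect_equal(e2$b, e$b, tolerance = 1e-9)
      if (abs(a - b) > 1e-6)
        expect_lt(min(abs(e2$angle_deg - e$angle_deg),
                      180 - abs(e2$angle_deg - e$angle_deg)), 1e-6)
      # interior negative, boundary zero
      expect_lt(conic_value(e$conic, ctr[1], ctr[2]), 0)
      th <- ang * pi / 180
      bp <- ctr + a * c(cos(th), sin(th))
      expect_equal(conic_value(e$conic, bp[1], bp[2]), 0, tolerance = 1e-9)
    }
  })
})

test_that("direct least-squares fit recovers circles and ellipses exactly", {
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  ec <- fit_ellipse(cbind(cos(th), sin(th)))
  expect_equal(ec$center, c(0, 0), tolerance = 1e-9)
  expect_equal(ec$a, 1, tolerance = 1e-9)
  expect_equal(ec$b, 1, tolerance = 1e-9)

  th <- seq(0, 2 * pi, length.out = 201)[-201]
  rot <- 30 * pi / 180
  pts <- cbind(3 + 5 * cos(th) * cos(rot) - 2 * sin(th) * sin(rot),
               4 + 5 * cos(th) * sin(rot) + 2 * sin(th) * cos(rot))
  ef <- fit_ellipse(pts)
  expect_equal(ef$center, c(3, 4), tolerance = 1e-6)
  expect_equal(ef$a, 5, tolerance = 1e-6)
  expect_equal(ef$b, 2, tolerance = 1e-6)
  expect_equal(ef$angle_deg, 30, tolerance = 1e-6)
  # algebraic residuals vanish at the input points (noiseless case)
  expect_lt(max(abs(conic_value(ef$conic, pts[, 1], pts[, 2]))), 1e-9)
})

test_that("fit_ellipse rejects degenerate input", {
  expect_error(fit_ellipse(cbind(1:4, 1:4)), "at least 5")
  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10) + 3)), "fit failed")
})

test_that("circle tangency matches the closed form", {
  e <- ellipse(c(10, 0), 5, 5, 0)
  tp <- tangent_points(e, c(0, 0))
  tp <- tp[order(tp[, 2]), ]
  expect_equal(tp[, 1], c(7.5, 7.5), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tp[, 2], c(-sqrt(18.75), sqrt(18.75)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # both candidates give 150 deg here; the tie-break picks larger y
  sel <- select_tangent(tp, c(-10, 0), c(0, 0))
  expect_equal(sel, c(7.5, sqrt(18.75)), tolerance = 1e-9)
  expect_equal(compute_aop(c(-10, 0), c(0, 0), sel), 150, tolerance = 1e-9)
})

test_that("tangents from a point on the major axis are mirror images", {
  e <- ellipse(c(0, 0), 6, 3, 0)
  tp <- tangent_points(e, c(15, 0))
  expect_equal(tp[1, 1], tp[2, 1], tolerance = 1e-9)
  expect_equal(tp[1, 2], -tp[2, 2], tolerance = 1e-9)
})

test_that("tangent construction fails for interior points", {
  e <- ellipse(c(0, 0), 5, 3, 20)
  expect_error(tangent_points(e, c(1, 1)), "no tangent")
})

test_that("selection rule takes the larger-angle candidate and is rotation invariant", {
  left <- c(-20, 2); right <- c(0, 0)
  e <- ellipse(c(14, 9), 6, 4, 25)
  tp <- tangent_points(e, right)
  sel <- select_tangent(tp, left, right)
  angs <- apply(tp, 1, function(p) compute_aop(left, right, p))
  expect_equal(compute_aop(left, right, sel), max(angs))
  withr::with_seed(4, {
    for (k in 1:10) {
      th <- runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      rot <- function(p) as.numeric(R %*% p)
      er <- ellipse(rot(e$center), e$a, e$b, e$angle_deg + th * 180 / pi)
      selr <- select_tangent(tangent_points(er, rot(right)), rot(left), rot(right))
      expect_equal(selr, rot(sel), tolerance = 1e-6)
    }
  })
})

test_that("compute_aop reproduces simple angle fixtures", {
  expect_equal(compute_aop(c(0, 0), c(10, 0), c(10, 10)), 90)
  expect_equal(compute_aop(c(0, 0), c(10, 0), c(20, 0)), 180)
  expect_error(compute_aop(c(1, 1), c(1, 1), c(2, 2)), "coincident")
})

test_that("mask_boundary traces rectangles, disks, and largest components", {
  m <- matrix(0L, 30, 40)
  m[10:20, 5:25] <- 2L
  b <- mask_boundary(m, 2)
  # the 4 rectangle corner pixels (x, y): (4,9), (24,9), (4,19), (24,19)
  for (corner in list(c(4, 9), c(24, 9), c(4, 19), c(24, 19)))
    expect_true(any(b[, 1] == corner[1] & b[, 2] == corner[2]))

  # two components: only the larger contributes
  m2 <- m; m2[2:4, 30:32] <- 2L
  b2 <- mask_boundary(m2, 2)
  expect_true(all(b2[, 1] <= 25))

  # rasterized disk: boundary within 1 px of the analytic circle
  H <- 60; W <- 60
  md <- outer(0:(H - 1), 0:(W - 1),
              function(y, x) ((x - 30)^2 + (y - 28)^2 <= 20^2) * 2L)
  bd <- mask_boundary(md, 2)
  r <- sqrt((bd[, 1] - 30)^2 + (bd[, 2] - 28)^2)
  expect_true(all(abs(r - 20) <= 1))
})

test_that("measure_aop reports stage failures instead of raising", {
  m <- matrix(0L, 32, 32)
  res <- measure_aop(m, c(2, 2), c(10, 10))
  expect_false(res$valid)
  expect_equal(res$reason, "no FH region")

  m[10:25, 10:25] <- 2L
  res2 <- measure_aop(m, c(2, 2), c(15, 15))  # endpoint inside the region
  expect_false(res2$valid)
  expect_equal(res2$reason, "no tangent")
})

test_that("AoP is invariant under rigid motions and scaling of the key points", {
  left <- c(-18, 3); right <- c(0, 0)
  e <- ellipse(c(13, 10), 7, 4, 40)
  sel <- select_tangent(tangent_points(e, right), left, right)
  base <- compute_aop(left, right, sel)
  withr::with_seed(9, {
    for (k in 1:15) {
      th <- runif(1, 0, 2 * pi); tr <- runif(2, -30, 30); s <- runif(1, 0.2, 5)
      R <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      f <- function(p) as.numeric(R %*% p + tr)
      er <- ellipse(f(e$center), s * e$a, s * e$b, e$angle_deg + th * 180 / pi)
      selr <- select_tangent(tangent_points(er, f(right)), f(left), f(right))
      expect_equal(compute_aop(f(left), f(right), selr), base, tolerance = 1e-9)
    }
  })
})
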