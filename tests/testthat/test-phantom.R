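# The synthetic phantom generator: determinism, exact rasterization, class
# structure, and geometric consistency of the stored analytic AoP.

test_that("identical (spec, patient, seed) give bit-identical samples", {
  spec <- phantom_spec(64, 64)
  a <- generate_standard(spec, "P7", seed = 123)
  b <- generate_standard(spec, "P7", seed = 123)
  expect_identical(a, b)
  n1 <- generate_nonstandard(spec, "P7", seed = 55)
  n2 <- generate_nonstandard(spec, "P7", seed = 55)
  expect_identical(n1, n2)
})

test_that("noise-free rendering equals the exact shape rasterization", {
  spec <- phantom_spec(64, 64, speckle_strength = 0)
  s <- generate_standard(spec, "P1", seed = 4)
  expect_true(all(s$image[s$mask == 0L] == spec$bg_intensity))
  expect_true(all(s$image[s$mask == 1L] == spec$ps_intensity))
  expect_true(all(s$image[s$mask == 2L] == spec$fh_intensity))
  expect_setequal(unique(as.integer(s$mask)), c(0L, 1L, 2L))
})

test_that("standard samples satisfy their structural invariants", {
  spec <- phantom_spec(96, 96)
  for (seed in 1:25) {
    s <- generate_standard(spec, "P1", seed)
    expect_true(s$is_standard)
    expect_true(any(s$mask == 1L) && any(s$mask == 2L))
    expect_gt(s$aop_true, 0); expect_lt(s$aop_true, 180)
    expect_gt(s$right_endpoint[1], s$left_endpoint[1])
    expect_true(all(c(s$left_endpoint, s$right_endpoint) >= 0))
    expect_true(all(s$left_endpoint <= 95) && all(s$right_endpoint <= 95))
    # PS right endpoint lies outside the FH ellipse (a tangent exists)
    expect_gt(conic_value(s$shapes$fh$conic, s$right_endpoint[1],
                          s$right_endpoint[2]), 0)
    # every PS pixel lies strictly outside the FH ellipse
    ps_px <- which(s$mask == 1L, arr.ind = TRUE)
    expect_true(all(conic_value(s$shapes$fh$conic,
                                ps_px[, 2] - 1, ps_px[, 1] - 1) > 0))
  }
})

test_that("stored aop_true matches recomputation from the stored shapes", {
  spec <- phantom_spec(96, 96)
  for (seed in 1:200) {
    s <- generate_standard(spec, "P1", seed)
    tp <- select_tangent(tangent_points(s$shapes$fh, s$right_endpoint),
                         s$left_endpoint, s$right_endpoint)
    expect_lt(abs(compute_aop(s$left_endpoint, s$right_endpoint, tp) -
                    s$aop_true), 1e-9)
  }
})

test_that("nonstandard modes remove the advertised structures", {
  spec1 <- phantom_spec(64, 64, nonstandard_modes = "missing_fh")
  s1 <- generate_nonstandard(spec1, "P1", seed = 1)
  expect_false(s1$is_standard)
  expect_true(is.na(s1$aop_true))
  expect_equal(sum(s1$mask == 2L), 0)
  expect_gt(sum(s1$mask == 1L), 0)

  spec2 <- phantom_spec(64, 64, nonstandard_modes = "noise_only")
  s2 <- generate_nonstandard(spec2, "P1", seed = 2)
  expect_true(all(s2$mask == 0L))

  spec3 <- phantom_spec(64, 64, nonstandard_modes = "missing_ps")
  s3 <- generate_nonstandard(spec3, "P1", seed = 3)
  expect_equal(sum(s3$mask == 1L), 0)
  expect_gt(sum(s3$mask == 2L), 0)

  # truncated: the visible FH is a minority of the full ellipse area
  spec4 <- phantom_spec(64, 64, nonstandard_modes = "truncated")
  s4 <- generate_nonstandard(spec4, "P1", seed = 4)
  fh <- s4$shapes$fh
  expect_lt(sum(s4$mask == 2L), 0.5 * pi * fh$a * fh$b)
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(64, 64, gap_range = c(5, 2)), "invalid range")
  expect_error(phantom_spec(64, 64, nonstandard_modes = "foo"), "unknown")
  expect_error(phantom_spec(16, 16), "at least 32")
  # incompatible ranges exhaust the rejection budget
  spec <- phantom_spec(64, 64)
  spec$aop_range <- c(10, 11)  # essentially unreachable target window
  expect_error(generate_standard(spec, "P1", 1, max_attempts = 30),
               "rejection sampling failed")
})

test_that("generate_dataset writes exact counts, round-robin patients, reproducibly", {
  spec <- phantom_spec(64, 64)
  d1 <- withr::local_tempdir()
  man <- generate_dataset(spec, 10, 9, 4, seed = 2, out_dir = d1)
  expect_equal(nrow(man), 19)
  expect_equal(sum(man$is_standard), 10)
  expect_equal(man$patient_id[1:8], sprintf("P%03d", c(1:4, 1:4)))
  expect_true(all(file.exists(file.path(d1, man$image_path))))
  expect_true(all(file.exists(file.path(d1, man$mask_path))))

  # PNG round trip preserves image and mask exactly
  s <- generate_standard(spec, "P001", aopmeter:::derive_seed(2, 1))
  img <- read_phantom_image(file.path(d1, man$image_path[1]))
  msk <- read_phantom_image(file.path(d1, man$mask_path[1]), mask = TRUE)
  expect_equal(img, s$image, ignore_attr = TRUE)
  expect_equal(msk, s$mask, ignore_attr = TRUE)

  d2 <- withr::local_tempdir()
  man2 <- generate_dataset(spec, 10, 9, 4, seed = 2, out_dir = d2)
  expect_identical(man, man2)
})
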