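# Preprocessing, coordinate maps, heatmap construction/decoding,
# augmentation, and the patient-wise stratified split.

test_that("intensity normalization hits the endpoints of the linear map", {
  p <- preprocess(matrix(255, 10, 12), target_size = c(10, 12))
  expect_true(all(p$image == 1))
  expect_true(all(preprocess(matrix(0, 10, 12), c(10, 12))$image == -1))
  expect_true(all(preprocess(matrix(127.5, 10, 12), c(10, 12))$image == 0))
  expect_error(preprocess(matrix(numeric(0), 0, 0)), "empty")
})

test_that("the spatial map scales points like the resize and inverts exactly", {
  img <- matrix(runif(652 * 800, 0, 255), 652, 800)
  p <- preprocess(img, target_size = c(384, 416))
  expect_equal(dim(p$image), c(384, 416))
  u <- 0.3; v <- 0.7
  mapped <- sm_apply(p$spatial_map, c(800 * u, 652 * v))
  expect_equal(mapped, c(416 * u, 384 * v), tolerance = 1e-12)
  # invertibility on coordinates
  withr::with_seed(2, {
    pts <- cbind(runif(50, 0, 799), runif(50, 0, 651))
    back <- sm_apply(p$spatial_map, sm_apply(p$spatial_map, pts), inverse = TRUE)
    expect_lt(max(abs(back - pts)), 1e-9)
  })
})

test_that("heatmaps are unit-peak Gaussians in the documented order", {
  hm <- make_heatmaps(left = c(6, 20), right = c(30, 22), shape = c(32, 40),
                      sigma = 4)
  expect_equal(dim(hm), c(32, 40, 3))
  expect_equal(hm[23, 31, 1], 1)         # right endpoint peak (map 1)
  expect_equal(hm[21, 7, 2], 1)          # left endpoint peak (map 2)
  expect_equal(hm[22, 19, 3], 1)         # midpoint (18, 21) peak (map 3)
  # value at distance sigma from the peak is exp(-1/2)
  expect_equal(hm[23, 31 + 4, 1], exp(-0.5), tolerance = 1e-12)
  expect_true(all(hm >= 0 & hm <= 1))
  expect_error(make_heatmaps(c(1, 1), c(2, 2), c(8, 8), sigma = 0), "sigma")
})

test_that("endpoint decoding inverts heatmap construction and obeys the tie rule", {
  hm <- make_heatmaps(left = c(5, 20), right = c(30, 22), shape = c(32, 40),
                      sigma = 4)
  ep <- extract_endpoints(hm)
  expect_equal(ep$left, c(5, 20))
  expect_equal(ep$right, c(30, 22))

  # two equal maxima: row-major-first (smaller y, then smaller x) wins
  h <- array(0, c(8, 8, 2))
  h[3, 6, 1] <- 1; h[5, 2, 1] <- 1
  h[4, 4, 2] <- 1
  expect_equal(extract_endpoints(h)$right, c(5, 2))

  # spatial map applied on the way back: argmax (10, 7) with scale 2 in x
  sm <- aopmeter:::spatial_map(sx = 2, sy = 1.5, orig = c(24, 16),
                               target = c(36, 32))
  h2 <- array(0, c(36, 32, 2))
  h2[8, 11, 1] <- 1; h2[2, 2, 2] <- 1
  expect_equal(extract_endpoints(h2, sm)$right, c(10 / 2, 7 / 1.5))

  expect_error(extract_endpoints(array(0, c(8, 8, 2))), "detection failure")
})

test_that("degenerate augmentation ranges give the identity transform", {
  smp <- tiny_sample(32, seed = 3)
  out <- withr::with_seed(1, augment(smp, rot_range = c(0, 0),
                                     scale_range = c(1, 1)))
  expect_equal(out$endpoints, smp$endpoints, tolerance = 1e-12)
  expect_equal(out$mask, smp$mask)
  expect_equal(max(abs(out$image - smp$image)), 0, tolerance = 1e-9)
})

test_that("augmentation applies one affine map to endpoints, mask and image", {
  smp <- tiny_sample(32, seed = 5)
  out <- withr::with_seed(2, augment(smp, rot_range = c(30, 30),
                                     scale_range = c(1, 1)))
  th <- 30 * pi / 180; ctr <- c(31 / 2, 31 / 2)
  rot <- function(p) {
    d <- p - ctr
    ctr + c(cos(th) * d[1] - sin(th) * d[2], sin(th) * d[1] + cos(th) * d[2])
  }
  expect_equal(out$endpoints$left, rot(smp$endpoints$left), tolerance = 1e-9)
  expect_equal(out$endpoints$right, rot(smp$endpoints$right), tolerance = 1e-9)
  expect_equal(out$transform_record$angle_deg, 30)
  # nearest-neighbour warping introduces no new labels
  expect_true(all(unique(as.integer(out$mask)) %in% c(0L, 1L, 2L)))
  # heatmaps were rebuilt on the transformed endpoints
  expect_equal(extract_endpoints(out$heatmaps)$right,
               round(rot(smp$endpoints$right)))
  # the mask moved with the same map: the warped FH centroid matches
  on0 <- which(smp$mask == 2L, arr.ind = TRUE)
  on1 <- which(out$mask == 2L, arr.ind = TRUE)
  c0 <- rot(c(mean(on0[, 2]) - 1, mean(on0[, 1]) - 1))
  c1 <- c(mean(on1[, 2]) - 1, mean(on1[, 1]) - 1)
  expect_lt(max(abs(c1 - c0)), 1)
})

test_that("out-of-frame endpoints exhaust retries and fall back to identity", {
  smp <- tiny_sample(32, seed = 3)
  smp$endpoints$left <- c(0.5, 0.5)  # any rotation pushes it out
  out <- withr::with_seed(3, augment(smp, rot_range = c(29, 30),
                                     scale_range = c(1.4, 1.4),
                                     max_retries = 4))
  expect_equal(out$transform_record, list(angle_deg = 0, scale = 1))
  expect_equal(out$image, smp$image)
})

test_that("patient-wise split is exact for 10 x 1 images and always disjoint", {
  man <- tibble::tibble(patient_id = sprintf("P%02d", 1:10),
                        is_standard = TRUE)
  plan <- split_by_patient(man, c(5, 2, 3), seed = 1)
  expect_equal(length(plan$train_ids), 5)
  expect_equal(length(plan$val_ids), 2)
  expect_equal(length(plan$test_ids), 3)
  expect_equal(length(intersect(plan$train_ids, plan$val_ids)), 0)
  expect_equal(length(intersect(plan$train_ids, plan$test_ids)), 0)
  expect_setequal(c(plan$train_ids, plan$val_ids, plan$test_ids),
                  man$patient_id)
  expect_error(split_by_patient(man[1:2, ], c(5, 2, 3), 1), "at least 3")
})

test_that("stratified shares stay within one patient of the target", {
  # 50 standard + 30 nonstandard images over 16 patients (5 images each)
  withr::with_seed(7, {
    man <- tibble::tibble(
      patient_id = rep(sprintf("P%02d", 1:16), each = 5),
      is_standard = rep(c(TRUE, FALSE), c(50, 30)))
    plan <- split_by_patient(man, c(5, 2, 3), seed = 42)
    man2 <- apply_split(man, plan)
    test_std <- sum(man2$split == "test" & man2$is_standard)
    test_non <- sum(man2$split == "test" & !man2$is_standard)
    expect_lte(abs(test_std - 15), 5)  # within one patient's images of 30%
    expect_lte(abs(test_non - 9), 5)
  })
})
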