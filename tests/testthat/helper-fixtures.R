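# Shared fixtures: tiny network configs, in-memory phantom samples, and the
# independent brute-force oracle for the shape-constrained loss.

tiny_config <- function(size = c(16, 16), base = 2) {
  mtunet_config(base_channels = base, input_size = size)
}

# A small in-memory training sample at the given resolution.
tiny_sample <- function(size = 32, seed = 1, standard = TRUE) {
  spec <- phantom_spec(size, size, speckle_strength = 0.2)
  smp <- if (standard) generate_standard(spec, "P1", seed)
         else generate_nonstandard(spec, "P1", seed)
  pp <- preprocess(smp$image, c(size, size))
  ep <- if (standard) list(left = smp$left_endpoint, right = smp$right_endpoint)
        else NULL
  list(image = pp$image, mask = smp$mask, endpoints = ep, sigma = 3,
       class_label = as.integer(standard), aop_true = smp$aop_true,
       patient_id = smp$patient_id, spatial_map = pp$spatial_map)
}

# Independent brute-force evaluation of the convex shape loss: plain triple
# loops over ordered foreground pairs and the rasterized segment (lattice
# points at t = 0..Chebyshev distance, endpoints included), mean of the
# per-pair segment means. Returns the unnormalized triple sum as "sum".
slf_brute_force <- function(yb, p) {
  H <- nrow(yb)
  fg <- which(yb)
  xs <- (fg - 1) %/% H
  ys <- (fg - 1) %% H
  tot <- 0; tot_sum <- 0; np <- 0
  for (i in seq_along(fg)) {
    for (j in seq_along(fg)) {
      if (i == j) next
      L <- max(abs(xs[i] - xs[j]), abs(ys[i] - ys[j]))
      acc <- 0
      for (t in 0:L) {
        rx <- round(xs[i] + (xs[j] - xs[i]) * t / L)
        ry <- round(ys[i] + (ys[j] - ys[i]) * t / L)
        ridx <- ry + 1 + H * rx
        if (!yb[ridx]) next
        term <- (1 - p[fg[i]]) * (1 - p[fg[j]]) *
          (p[fg[i]] + p[fg[j]] - 2 * p[ridx])
        acc <- acc + term
      }
      tot <- tot + acc / (L + 1)
      tot_sum <- tot_sum + acc
      np <- np + 1
    }
  }
  out <- tot / np
  attr(out, "sum") <- tot_sum
  out
}

# Random blob mask (single 4-connected component) on an n x n grid.
random_blob_mask <- function(n, seed) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, n, n)
    cy <- sample(2:(n - 1), 1); cx <- sample(2:(n - 1), 1)
    m[cy, cx] <- TRUE
    for (k in seq_len(4 * n)) {
      on <- which(m, arr.ind = TRUE)
      px <- on[sample.int(nrow(on), 1), ]
      dy <- sample(c(-1, 0, 1), 1); dx <- sample(c(-1, 0, 1), 1)
      y2 <- min(max(px[1] + dy, 1), n); x2 <- min(max(px[2] + dx, 1), n)
      m[y2, x2] <- TRUE
    }
    m
  })
}
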