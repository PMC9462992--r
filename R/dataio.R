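# Manifest loading, preprocessing, augmentation, Gaussian endpoint heatmaps
# and the patient-wise stratified split.
#
# Network coordinates: images are bilinearly resized to (H', W') and
# intensities mapped linearly [0,255] -> [-1,1]. The spatial map is a pure
# per-axis scaling x' = x * sx, y' = y * sy recorded so predictions can be
# mapped back to original pixel coordinates exactly.

#' Preprocess a raw grayscale image for the network
#'
#' @param image_raw numeric matrix in [0, 255], rows = y.
#' @param target_size network input size as (H', W'); the default (384, 416)
#'   reads the clinical "416 x 384" as width x height.
#' @return list with `image` (matrix H' x W' in [-1, 1]) and `spatial_map`.
#' @examples
#' p <- preprocess(matrix(255, 10, 10), target_size = c(8, 8))
#' range(p$image)  # 1 1
#' @export
preprocess <- function(image_raw, target_size = c(384, 416)) {
  if (length(image_raw) == 0) stop("empty image")
  H <- nrow(image_raw); W <- ncol(image_raw)
  Hp <- target_size[1]; Wp <- target_size[2]
  sm <- spatial_map(sx = Wp / W, sy = Hp / H,
                    orig = c(H, W), target = c(Hp, Wp))
  img <- if (H == Hp && W == Wp) image_raw else
    cpp_warp_affine(image_raw, c(1 / sm$sx, 0, 0, 0, 1 / sm$sy, 0),
                    Hp, Wp, TRUE, 0)
  list(image = img / 127.5 - 1, spatial_map = sm)
}

spatial_map <- function(sx, sy, orig, target) {
  structure(list(sx = sx, sy = sy, orig = orig, target = target),
            class = "aop_spatial_map")
}

#' Apply a spatial map to (x, y) points
#' @param map an `aop_spatial_map` from [preprocess()].
#' @param xy numeric length-2 point or n x 2 matrix.
#' @param inverse map network coordinates back to original ones.
#' @export
sm_apply <- function(map, xy, inverse = FALSE) {
  s <- if (inverse) c(1 / map$sx, 1 / map$sy) else c(map$sx, map$sy)
  if (is.matrix(xy)) cbind(xy[, 1] * s[1], xy[, 2] * s[2])
  else c(xy[1] * s[1], xy[2] * s[2])
}

#' Build Gaussian endpoint heatmaps
#'
#' Heatmap k is \eqn{\exp(-((x-x_k)^2+(y-y_k)^2)/(2\sigma^2))} with peak 1.
#' Map 1 is the right (inferior) endpoint - the AoP vertex and the most
#' important landmark - map 2 the left endpoint, map 3 the PS-axis midpoint.
#'
#' @param left,right endpoint coordinates (x, y) in network pixels.
#' @param shape heatmap size (H, W).
#' @param sigma Gaussian width in pixels (> 0).
#' @return array (H, W, 3) in [0, 1].
#' @export
make_heatmaps <- function(left, right, shape, sigma = 6) {
  if (sigma <= 0) stop("sigma must be > 0")
  H <- shape[1]; W <- shape[2]
  pts <- rbind(right, left, (left + right) / 2)
  out <- array(0, c(H, W, 3))
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  for (k in 1:3) {
    gx <- exp(-(xs - pts[k, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ys - pts[k, 2])^2 / (2 * sigma^2))
    out[, , k] <- outer(gy, gx)
  }
  out
}

#' Decode endpoints from predicted heatmaps
#'
#' Per-heatmap argmax (maps 1 and 2), ties broken in row-major order
#' (first by y, then by x), mapped back to original coordinates through the
#' spatial map.
#'
#' @param heatmaps array (H, W, >=2); map 1 = right, map 2 = left endpoint.
#' @param map optional `aop_spatial_map`; if NULL coordinates stay in
#'   network pixels.
#' @return list with `left` and `right` (x, y) coordinates.
#' @export
extract_endpoints <- function(heatmaps, map = NULL) {
  peak <- function(h) {
    mx <- max(h)
    if (mx <= 0) stop("detection failure: all-zero heatmap")
    idx <- which(h == mx, arr.ind = TRUE)           # (row=y+1, col=x+1)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    as.numeric(c(idx[1, 2] - 1, idx[1, 1] - 1))      # (x, y), 0-based
  }
  r <- peak(heatmaps[, , 1]); l <- peak(heatmaps[, , 2])
  if (!is.null(map)) { r <- sm_apply(map, r, inverse = TRUE)
                       l <- sm_apply(map, l, inverse = TRUE) }
  list(left = l, right = r)
}

#' Randomly rotate and scale a training sample
#'
#' Rotation ~ Uniform(-30, 30) degrees about the image center and isotropic
#' scale ~ Uniform(0.9, 1.1), applied identically to image (bilinear), mask
#' (nearest-neighbour) and endpoints; heatmaps are rebuilt from the
#' transformed endpoints. If an endpoint leaves the frame the draw is
#' retried a bounded number of times, then the sample is passed through
#' unaugmented.
#'
#' @param smp sample list with `image` (normalized), `mask`, `endpoints`
#'   (list left/right or NULL), `sigma`.
#' @param rot_range,scale_range augmentation ranges.
#' @param max_retries bounded retry budget.
#' @return the transformed sample; `transform_record` holds the applied
#'   (angle, scale).
#' @export
augment <- function(smp, rot_range = c(-30, 30), scale_range = c(0.9, 1.1),
                    max_retries = 10L) {
  H <- nrow(smp$image); W <- ncol(smp$image)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  has_ep <- !is.null(smp$endpoints) && all(is.finite(unlist(smp$endpoints)))
  for (i in seq_len(max_retries)) {
    ang <- stats::runif(1, rot_range[1], rot_range[2]) * pi / 180
    sc <- stats::runif(1, scale_range[1], scale_range[2])
    fwd <- function(p) {
      dx <- p[1] - cx; dy <- p[2] - cy
      c(cx + sc * (cos(ang) * dx - sin(ang) * dy),
        cy + sc * (sin(ang) * dx + cos(ang) * dy))
    }
    if (has_ep) {
      l2 <- fwd(smp$endpoints$left); r2 <- fwd(smp$endpoints$right)
      if (any(c(l2, r2) < 0) || l2[1] > W - 1 || r2[1] > W - 1 ||
          l2[2] > H - 1 || r2[2] > H - 1) next
    }
    # inverse map (output pixel -> input coords) for the resampling kernel
    a <- cos(ang) / sc; b <- sin(ang) / sc
    m <- c(a, b, cx - a * cx - b * cy, -b, a, cy + b * cx - a * cy)
    smp$image <- cpp_warp_affine(smp$image, m, H, W, TRUE, -1)
    if (!is.null(smp$mask)) {
      mk <- cpp_warp_affine(smp$mask + 0, m, H, W, FALSE, 0)
      storage.mode(mk) <- "integer"
      smp$mask <- mk
    }
    if (has_ep) {
      smp$endpoints <- list(left = l2, right = r2)
      smp$heatmaps <- make_heatmaps(l2, r2, c(H, W),
                                    if (is.null(smp$sigma)) 6 else smp$sigma)
    }
    smp$transform_record <- list(angle_deg = ang * 180 / pi, scale = sc)
    return(smp)
  }
  smp$transform_record <- list(angle_deg = 0, scale = 1)
  smp
}

#' Patient-wise stratified split
#'
#' Patients are shuffled with the seed and greedily assigned to the set with
#' the largest remaining per-stratum image deficit, so the standard and
#' nonstandard image counts both approximate the requested ratios while no
#' patient ever appears in two sets.
#'
#' @param manifest tibble with `patient_id` and `is_standard` columns.
#' @param ratios length-3 positive weights for train/val/test.
#' @param seed shuffle seed.
#' @return a `split_plan`: list of `train_ids`, `val_ids`, `test_ids` and
#'   `ratios`.
#' @export
split_by_patient <- function(manifest, ratios = c(5, 2, 3), seed = 1L) {
  pats <- unique(manifest$patient_id)
  if (length(pats) < 3) stop("need at least 3 patients to split")
  counts <- manifest |>
    dplyr::count(.data$patient_id, .data$is_standard) |>
    tidyr::pivot_wider(names_from = "is_standard", values_from = "n",
                       values_fill = 0L)
  std <- stats::setNames(rep(0L, length(pats)), pats)
  non <- std
  if ("TRUE" %in% names(counts)) std[counts$patient_id] <- counts[["TRUE"]]
  if ("FALSE" %in% names(counts)) non[counts$patient_id] <- counts[["FALSE"]]
  frac <- ratios / sum(ratios)
  target_std <- sum(std) * frac
  target_non <- sum(non) * frac
  fill_std <- fill_non <- c(0, 0, 0)
  assign <- stats::setNames(integer(length(pats)), pats)
  ord <- with_seed_(seed, sample(pats))
  for (p in ord) {
    deficit <- (target_std - fill_std) + (target_non - fill_non)
    j <- which.max(deficit)
    assign[p] <- j
    fill_std[j] <- fill_std[j] + std[p]
    fill_non[j] <- fill_non[j] + non[p]
  }
  structure(list(train_ids = names(assign)[assign == 1],
                 val_ids = names(assign)[assign == 2],
                 test_ids = names(assign)[assign == 3],
                 ratios = ratios), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d/%d/%d patients (ratios %s)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              paste(x$ratios, collapse = ":")))
  invisible(x)
}

#' Attach the split label to a manifest
#' @param manifest a manifest tibble.
#' @param plan a `split_plan`.
#' @return the manifest with a `split` column (train/val/test).
#' @export
apply_split <- function(manifest, plan) {
  manifest |>
    dplyr::mutate(split = dplyr::case_when(
      .data$patient_id %in% plan$train_ids ~ "train",
      .data$patient_id %in% plan$val_ids ~ "val",
      TRUE ~ "test"))
}

#' Read a dataset manifest
#' @param path manifest CSV path (columns as written by [generate_dataset()]).
#' @export
read_manifest <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    image_path = "c", mask_path = "c", patient_id = "c",
                    is_standard = "l", .default = "d"))
}

# Load every manifest row into memory as network-ready samples.
load_samples <- function(manifest, dir, target_size, sigma = 6) {
  purrr::pmap(manifest, function(image_path, mask_path, patient_id,
                                 is_standard, xl, yl, xr, yr, aop_true, ...) {
    raw <- read_phantom_image(file.path(dir, image_path))
    pp <- preprocess(raw, target_size)
    mask <- read_phantom_image(file.path(dir, mask_path), mask = TRUE)
    if (!all(dim(mask) == target_size))
      stop("mask size must match target size for in-memory training")
    ep <- if (is.finite(xl)) {
      list(left = sm_apply(pp$spatial_map, c(xl, yl)),
           right = sm_apply(pp$spatial_map, c(xr, yr)))
    } else NULL
    list(image = pp$image, mask = mask, endpoints = ep, sigma = sigma,
         class_label = as.integer(is_standard), aop_true = aop_true,
         patient_id = patient_id, spatial_map = pp$spatial_map,
         image_path = image_path)
  })
}
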