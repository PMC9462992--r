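# Synthetic transperineal-ultrasound-like phantom generator.
#
# Each standard-plane phantom contains a bright convex elliptical fetal-head
# (FH) region and an elongated pubic-symphysis (PS) capsule whose two axis
# endpoints are the ground-truth landmarks; the analytic AoP of the drawn
# geometry is stored with the sample, so every stage of the pipeline can be
# scored against exact truth. Nonstandard planes lack or truncate one or
# both structures. Speckle is modelled as multiplicative Gaussian noise.

with_seed_ <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

runif_range <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])

#' Phantom generation specification
#'
#' Sampling ranges for the two anatomical stand-ins, noise level and pixel
#' spacing. Defaults scale with the image size so that the same spec works
#' at desk scale (96 x 96) and at clinical-like resolution.
#'
#' @param image_width,image_height image size in pixels.
#' @param fh_axes_range range of the FH semi-major axis, px.
#' @param fh_ratio_range range of the FH semi-minor/semi-major ratio.
#' @param fh_angle_range FH orientation range, degrees.
#' @param ps_length_range,ps_width_range PS capsule axis length and full
#'   width ranges, px.
#' @param ps_angle_range PS axis angle range, degrees (y down, so positive
#'   slopes toward the lower right, as in the clinical view).
#' @param gap_range range of the clearance between the PS right endpoint and
#'   the FH boundary, px.
#' @param aop_range admissible analytic AoP range, degrees; draws outside it
#'   are rejected and resampled.
#' @param speckle_strength multiplicative speckle level (unitless sd).
#' @param pixel_spacing_mm mm per pixel (0.2 by default, so distances land in
#'   clinically plausible magnitudes).
#' @param bg_intensity,ps_intensity,fh_intensity rendering intensities in
#'   [0, 255]; contrast levels are free parameters of the phantom.
#' @param nonstandard_modes subset of `c("missing_fh", "missing_ps",
#'   "truncated", "noise_only")`.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_width = 96, image_height = 96,
                         fh_axes_range = NULL, fh_ratio_range = c(0.70, 0.92),
                         fh_angle_range = c(0, 180),
                         ps_length_range = NULL, ps_width_range = NULL,
                         ps_angle_range = c(5, 30),
                         gap_range = NULL, aop_range = c(75, 165),
                         speckle_strength = 0.25, pixel_spacing_mm = 0.2,
                         bg_intensity = 30, ps_intensity = 230,
                         fh_intensity = 200,
                         nonstandard_modes = c("missing_fh", "missing_ps",
                                               "truncated", "noise_only")) {
  s <- min(image_width, image_height)
  if (is.null(fh_axes_range)) fh_axes_range <- c(0.20, 0.28) * s
  if (is.null(ps_length_range)) ps_length_range <- c(0.24, 0.34) * s
  if (is.null(ps_width_range)) ps_width_range <- c(0.055, 0.085) * s
  if (is.null(gap_range)) gap_range <- c(0.04, 0.10) * s
  spec <- list(image_width = as.integer(image_width),
               image_height = as.integer(image_height),
               fh_axes_range = fh_axes_range, fh_ratio_range = fh_ratio_range,
               fh_angle_range = fh_angle_range,
               ps_length_range = ps_length_range,
               ps_width_range = ps_width_range,
               ps_angle_range = ps_angle_range,
               gap_range = gap_range, aop_range = aop_range,
               speckle_strength = speckle_strength,
               pixel_spacing_mm = pixel_spacing_mm,
               bg_intensity = bg_intensity, ps_intensity = ps_intensity,
               fh_intensity = fh_intensity,
               nonstandard_modes = nonstandard_modes)
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  rngs <- c("fh_axes_range", "fh_ratio_range", "fh_angle_range",
            "ps_length_range", "ps_width_range", "ps_angle_range",
            "gap_range", "aop_range")
  for (r in rngs) {
    v <- spec[[r]]
    if (length(v) != 2 || v[2] < v[1]) stop("invalid range: ", r)
  }
  if (spec$image_width < 32 || spec$image_height < 32)
    stop("phantom image must be at least 32 px on a side")
  if (spec$speckle_strength < 0) stop("speckle_strength must be >= 0")
  bad <- setdiff(spec$nonstandard_modes,
                 c("missing_fh", "missing_ps", "truncated", "noise_only"))
  if (length(bad)) stop("unknown nonstandard modes: ", paste(bad, collapse = ", "))
  invisible(spec)
}

# Distance from grid pixels to a segment, vectorized over the pixel grid.
dist_to_segment <- function(px, py, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  L2 <- vx^2 + vy^2
  t <- ((px - p1[1]) * vx + (py - p1[2]) * vy) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (p1[1] + t * vx))^2 + (py - (p1[2] + t * vy))^2)
}

# Rasterize shapes into a {0 bg, 1 PS, 2 FH} label mask (rows = y).
rasterize_shapes <- function(spec, ps = NULL, fh = NULL) {
  H <- spec$image_height; W <- spec$image_width
  px <- matrix(rep(0:(W - 1), each = H), H, W)
  py <- matrix(rep(0:(H - 1), times = W), H, W)
  mask <- matrix(0L, H, W)
  if (!is.null(fh)) {
    inside <- conic_value(fh$conic, px, py) <= 0
    mask[inside] <- 2L
  }
  if (!is.null(ps)) {
    inside <- dist_to_segment(px, py, ps$p1, ps$p2) <= ps$half_width
    mask[inside] <- 1L
  }
  mask
}

render_phantom <- function(spec, mask, seed) {
  img <- matrix(spec$bg_intensity, spec$image_height, spec$image_width)
  img[mask == 1L] <- spec$ps_intensity
  img[mask == 2L] <- spec$fh_intensity
  if (spec$speckle_strength > 0) {
    g <- matrix(stats::rnorm(length(img)), nrow(img), ncol(img))
    img <- img * (1 + spec$speckle_strength * g)
  }
  round(pmin(pmax(img, 0), 255))
}

sample_ps <- function(spec) {
  H <- spec$image_height; W <- spec$image_width
  len <- runif_range(spec$ps_length_range)
  wid <- runif_range(spec$ps_width_range)
  ang <- runif_range(spec$ps_angle_range) * pi / 180
  cx <- stats::runif(1, 0.18 * W, 0.30 * W)
  cy <- stats::runif(1, 0.35 * H, 0.52 * H)
  d <- c(cos(ang), sin(ang))  # y down: positive angle slopes lower-right
  p1 <- c(cx, cy) - d * len / 2  # left endpoint
  p2 <- c(cx, cy) + d * len / 2  # right (inferior) endpoint
  list(p1 = p1, p2 = p2, half_width = wid / 2, length = len, angle_deg = ang * 180 / pi)
}

#' Generate a standard-plane phantom
#'
#' Draws PS and FH geometry by rejection sampling until the configuration is
#' admissible (shapes inside the frame and disjoint, PS right endpoint
#' outside the FH ellipse, analytic AoP inside `spec$aop_range`), rasterizes
#' the label mask, renders the speckled image and stores the analytic AoP.
#'
#' @param spec a [phantom_spec()].
#' @param patient_id identifier stored with the sample.
#' @param seed integer; identical (spec, patient_id, seed) give bit-identical
#'   samples.
#' @param max_attempts rejection-sampling budget before the spec is declared
#'   invalid.
#' @return a `phantom_sample`: image, mask, endpoints, `aop_true`,
#'   `is_standard`, `patient_id`, `seed` and the generating `shapes`.
#' @export
generate_standard <- function(spec, patient_id = "P001", seed = 1L,
                              max_attempts = 200L) {
  validate_phantom_spec(spec)
  with_seed_(seed, {
    H <- spec$image_height; W <- spec$image_width
    for (attempt in seq_len(max_attempts)) {
      ps <- sample_ps(spec)
      a <- runif_range(spec$fh_axes_range)
      b <- a * runif_range(spec$fh_ratio_range)
      fh_ang <- runif_range(spec$fh_angle_range)
      gap <- runif_range(spec$gap_range)
      # place the FH center so the max-angle tangent lands near the drawn
      # target AoP: the tangent sits ~asin(r_eff/d) beyond the center ray
      theta_u <- atan2(ps$p1[2] - ps$p2[2], ps$p1[1] - ps$p2[1])
      aop_target <- stats::runif(1, spec$aop_range[1], spec$aop_range[2])
      d <- gap + a
      off <- asin(min(1, (a + b) / (2 * d))) * 180 / pi
      phi <- theta_u + (aop_target - off) * pi / 180
      ctr <- ps$p2 + d * c(cos(phi), sin(phi))
      fh <- ellipse(ctr, a, b, fh_ang)
      # admissibility checks
      if (ctr[1] - a < 2 || ctr[1] + a > W - 3 ||
          ctr[2] - a < 2 || ctr[2] + a > H - 3) next
      if (min(ps$p1, ps$p2) < 2 || ps$p1[1] > W - 3 || ps$p2[1] > W - 3 ||
          ps$p1[2] > H - 3 || ps$p2[2] > H - 3) next
      if (conic_value(fh$conic, ps$p2[1], ps$p2[2]) <= 0) next
      mask <- rasterize_shapes(spec, ps, fh)
      if (!any(mask == 1L) || !any(mask == 2L)) next
      # shapes must be disjoint: no PS pixel may fall inside the FH ellipse
      fh_only <- rasterize_shapes(spec, ps = NULL, fh = fh)
      if (any(fh_only[mask == 1L] == 2L)) next
      aop <- tryCatch({
        tps <- tangent_points(fh, ps$p2)
        tp <- select_tangent(tps, ps$p1, ps$p2)
        compute_aop(ps$p1, ps$p2, tp)
      }, error = function(e) NA_real_)
      if (!is.finite(aop) || aop < spec$aop_range[1] ||
          aop > spec$aop_range[2]) next
      img <- render_phantom(spec, mask, seed)
      return(structure(list(
        image = img, mask = mask,
        left_endpoint = ps$p1, right_endpoint = ps$p2,
        aop_true = aop, is_standard = TRUE, mode = "standard",
        patient_id = patient_id, seed = as.integer(seed),
        shapes = list(ps = ps, fh = fh)), class = "phantom_sample"))
    }
    stop("rejection sampling failed after ", max_attempts,
         " attempts: phantom spec ranges are incompatible")
  })
}

#' Generate a nonstandard-plane phantom
#'
#' One of `spec$nonstandard_modes` is drawn (seeded): `missing_fh` renders
#' PS only, `missing_ps` FH only, `truncated` pushes the FH mostly out of
#' the frame, `noise_only` renders pure background speckle. `aop_true` is
#' NA and `is_standard` is FALSE.
#'
#' @inheritParams generate_standard
#' @export
generate_nonstandard <- function(spec, patient_id = "P001", seed = 1L,
                                 max_attempts = 200L) {
  validate_phantom_spec(spec)
  if (!length(spec$nonstandard_modes)) stop("nonstandard_modes is empty")
  with_seed_(seed, {
    H <- spec$image_height; W <- spec$image_width
    mode <- sample(spec$nonstandard_modes, 1)
    ps <- NULL; fh <- NULL
    if (mode == "missing_fh") {
      ps <- sample_ps(spec)
    } else if (mode == "missing_ps") {
      for (i in seq_len(max_attempts)) {
        a <- runif_range(spec$fh_axes_range)
        b <- a * runif_range(spec$fh_ratio_range)
        ctr <- c(stats::runif(1, 0.3 * W, 0.75 * W), stats::runif(1, 0.3 * H, 0.7 * H))
        if (ctr[1] - a >= 2 && ctr[1] + a <= W - 3 &&
            ctr[2] - a >= 2 && ctr[2] + a <= H - 3) {
          fh <- ellipse(ctr, a, b, runif_range(spec$fh_angle_range)); break
        }
      }
    } else if (mode == "truncated") {
      ps <- if (stats::runif(1) < 0.5) sample_ps(spec) else NULL
      a <- runif_range(spec$fh_axes_range)
      b <- a * runif_range(spec$fh_ratio_range)
      side <- sample(c("right", "bottom"), 1)
      ctr <- if (side == "right") {
        c(W - 1 + 0.6 * a, stats::runif(1, 0.3 * H, 0.7 * H))
      } else {
        c(stats::runif(1, 0.4 * W, 0.8 * W), H - 1 + 0.6 * a)
      }
      fh <- ellipse(ctr, a, b, runif_range(spec$fh_angle_range))
    }
    mask <- rasterize_shapes(spec, ps, fh)
    if (mode == "noise_only") mask[] <- 0L
    img <- render_phantom(spec, mask, seed)
    ep <- if (!is.null(ps)) list(l = ps$p1, r = ps$p2) else
      list(l = c(NA_real_, NA_real_), r = c(NA_real_, NA_real_))
    structure(list(
      image = img, mask = mask,
      left_endpoint = ep$l, right_endpoint = ep$r,
      aop_true = NA_real_, is_standard = FALSE, mode = mode,
      patient_id = patient_id, seed = as.integer(seed),
      shapes = list(ps = ps, fh = fh)), class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s  patient=%s  seed=%d  %dx%d  AoP=%s\n",
              x$mode, x$patient_id, x$seed, nrow(x$image), ncol(x$image),
              ifelse(is.na(x$aop_true), "NA", sprintf("%.2f deg", x$aop_true))))
  invisible(x)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 1009) %% 2147483647)
}

#' Generate a phantom dataset on disk
#'
#' Writes grayscale 8-bit PNG images, indexed {0,1,2} PNG masks and a CSV
#' manifest. Patients are assigned round-robin within each stratum so every
#' patient holds both standard and nonstandard images where counts allow.
#'
#' @inheritParams generate_standard
#' @param n_standard,n_nonstandard sample counts per stratum.
#' @param n_patients number of patients (>= 3 so a patient-wise split exists).
#' @param out_dir output directory (created if needed).
#' @return the manifest as a tibble (also written to
#'   `file.path(out_dir, "manifest.csv")`) with columns `image_path`,
#'   `mask_path`, `patient_id`, `is_standard`, `xl`, `yl`, `xr`, `yr`,
#'   `aop_true`.
#' @export
generate_dataset <- function(spec, n_standard, n_nonstandard, n_patients,
                             seed = 1L, out_dir) {
  if (n_patients < 3) stop("need at least 3 patients for a 3-way split")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  pid <- function(i) sprintf("P%03d", ((i - 1L) %% n_patients) + 1L)
  rows <- vector("list", n_standard + n_nonstandard)
  k <- 0L
  for (i in seq_len(n_standard)) {
    k <- k + 1L
    smp <- generate_standard(spec, pid(k), derive_seed(seed, k))
    rows[[k]] <- write_sample(smp, out_dir, k)
  }
  for (i in seq_len(n_nonstandard)) {
    k <- k + 1L
    smp <- generate_nonstandard(spec, pid(k), derive_seed(seed, k))
    rows[[k]] <- write_sample(smp, out_dir, k)
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

write_sample <- function(smp, out_dir, k) {
  ip <- file.path("images", sprintf("img_%04d.png", k))
  mp <- file.path("masks", sprintf("mask_%04d.png", k))
  png::writePNG(smp$image / 255, file.path(out_dir, ip))
  png::writePNG(smp$mask / 255, file.path(out_dir, mp))
  tibble::tibble(image_path = ip, mask_path = mp,
                 patient_id = smp$patient_id, is_standard = smp$is_standard,
                 xl = smp$left_endpoint[1], yl = smp$left_endpoint[2],
                 xr = smp$right_endpoint[1], yr = smp$right_endpoint[2],
                 aop_true = smp$aop_true)
}

#' Read an image or mask written by [generate_dataset()]
#'
#' @param path PNG (or BMP-free grayscale PNG) file path.
#' @param mask if TRUE, decode {0,1,2} labels instead of [0,255] intensities.
#' @return numeric (or integer) matrix, rows = y.
#' @export
read_phantom_image <- function(path, mask = FALSE) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  v <- round(a * 255)
  if (mask) storage.mode(v) <- "integer"
  v
}
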