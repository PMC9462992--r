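# End-to-end evaluation: run the trained network over a manifest, score
# every task against the ground truth and aggregate the report.

#' @importFrom rlang .data
NULL

#' Run inference over a manifest and score each image
#'
#' For every manifest row the full pipeline is run (classification;
#' segmentation, endpoint decoding and AoP measurement when the plane is
#' predicted standard). Ground-truth masks and endpoints from the manifest
#' are used for scoring only.
#'
#' @param model a trained `mtunet`.
#' @param manifest manifest tibble (see [generate_dataset()]).
#' @param dir dataset root containing the image/mask paths.
#' @param target_size network input (H', W'); defaults to the model config.
#' @param pixel_spacing_mm mm per pixel for distance metrics.
#' @return per-image tibble with the class decision, endpoint/AoP
#'   predictions and all per-image metrics.
#' @export
predict_manifest <- function(model, manifest, dir, target_size = NULL,
                             pixel_spacing_mm = 0.2) {
  if (is.null(target_size)) target_size <- model$config$input_size
  rows <- purrr::pmap(manifest, function(image_path, mask_path, patient_id,
                                         is_standard, xl, yl, xr, yr,
                                         aop_true, ...) {
    img <- read_phantom_image(file.path(dir, image_path))
    pr <- predict_aop(model, img, target_size)
    out <- tibble::tibble(
      image_path = image_path, patient_id = patient_id,
      is_standard_true = is_standard, is_standard_pred = pr$is_standard,
      p_standard = pr$class_probs[2],
      xl_pred = NA_real_, yl_pred = NA_real_, xr_pred = NA_real_,
      yr_pred = NA_real_, aop_pred = NA_real_, aop_true = aop_true,
      valid = FALSE, reason = NA_character_,
      dice_ps = NA_real_, dice_fh = NA_real_, dice_all = NA_real_,
      pixel_acc = NA_real_, dist_l_mm = NA_real_, dist_r_mm = NA_real_,
      apt_deg = NA_real_, delta_aop_deg = NA_real_)
    if (!is.null(pr$endpoints)) {
      out$xl_pred <- pr$endpoints$left[1]; out$yl_pred <- pr$endpoints$left[2]
      out$xr_pred <- pr$endpoints$right[1]; out$yr_pred <- pr$endpoints$right[2]
    }
    if (!is.null(pr$aop)) {
      out$valid <- pr$aop$valid
      out$reason <- pr$aop$reason
      out$aop_pred <- pr$aop$aop_deg
    }
    if (is_standard) {
      truem <- read_phantom_image(file.path(dir, mask_path), mask = TRUE)
      if (all(dim(truem) == dim(pr$seg_mask))) {
        ds <- dice_score(pr$seg_mask, truem)
        out$dice_ps <- ds$dice_ps; out$dice_fh <- ds$dice_fh
        out$dice_all <- ds$dice_all; out$pixel_acc <- ds$pixel_acc
      }
      if (!is.null(pr$endpoints) && is.finite(xl)) {
        out$dist_l_mm <- endpoint_distance(pr$endpoints$left, c(xl, yl),
                                           pixel_spacing_mm)
        out$dist_r_mm <- endpoint_distance(pr$endpoints$right, c(xr, yr),
                                           pixel_spacing_mm)
        out$apt_deg <- tryCatch(
          apt(pr$endpoints$left, pr$endpoints$right, c(xl, yl), c(xr, yr)),
          error = function(e) NA_real_)  # coincident predicted endpoints
      }
      if (is.finite(out$aop_pred) && is.finite(aop_true))
        out$delta_aop_deg <- delta_aop(out$aop_pred, aop_true)
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Aggregate a per-image table into an evaluation report
#'
#' Classification rates from the standard-vs-nonstandard confusion,
#' macro-averaged segmentation/endpoint/angle metrics over the true
#' standard planes, and Pearson/Bland-Altman agreement of the measured
#' versus reference AoP.
#'
#' @param per_image tibble from [predict_manifest()] (or any table with the
#'   same columns).
#' @return an `eval_report`: list with `classification`, `summary`,
#'   `agreement` and the `per_image` table.
#' @export
evaluate_report <- function(per_image) {
  tp <- sum(per_image$is_standard_true & per_image$is_standard_pred)
  fp <- sum(!per_image$is_standard_true & per_image$is_standard_pred)
  fn <- sum(per_image$is_standard_true & !per_image$is_standard_pred)
  tn <- sum(!per_image$is_standard_true & !per_image$is_standard_pred)
  cls <- classification_metrics(tp, fp, fn, tn)
  std <- dplyr::filter(per_image, .data$is_standard_true)
  mstat <- function(v) if (any(is.finite(v))) mean(v[is.finite(v)]) else NA_real_
  summary <- tibble::tibble(
    n_images = nrow(per_image), n_standard = nrow(std),
    dice_ps = mstat(std$dice_ps), dice_fh = mstat(std$dice_fh),
    dice_all = mstat(std$dice_all), pixel_acc = mstat(std$pixel_acc),
    dist_l_mm = mstat(std$dist_l_mm), dist_r_mm = mstat(std$dist_r_mm),
    apt_deg = mstat(std$apt_deg), delta_aop_deg = mstat(std$delta_aop_deg),
    sd_delta_aop_deg = if (sum(is.finite(std$delta_aop_deg)) > 1)
      stats::sd(std$delta_aop_deg[is.finite(std$delta_aop_deg)]) else NA_real_)
  agr <- NULL
  ok <- is.finite(std$aop_pred) & is.finite(std$aop_true)
  if (sum(ok) >= 3) agr <- agreement(std$aop_pred[ok], std$aop_true[ok])
  structure(list(classification = cls, summary = summary, agreement = agr,
                 per_image = per_image), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n  classification: ",
      sprintf("acc %.3f  pre %.3f  sen %.3f  spe %.3f\n",
              x$classification$acc, x$classification$pre,
              x$classification$sen, x$classification$spe))
  s <- x$summary
  cat(sprintf("  segmentation:   Dice PS %.3f  FH %.3f  ALL %.3f  acc %.3f\n",
              s$dice_ps, s$dice_fh, s$dice_all, s$pixel_acc))
  cat(sprintf("  endpoints:      Dist_L %.3f mm  Dist_R %.3f mm  APT %.2f deg\n",
              s$dist_l_mm, s$dist_r_mm, s$apt_deg))
  cat(sprintf("  AoP:            mean dAoP %.3f deg (sd %.3f)\n",
              s$delta_aop_deg, s$sd_delta_aop_deg))
  if (!is.null(x$agreement)) print(x$agreement)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Per-image rows as CSV and the aggregate summary as JSON.
#'
#' @param report an `eval_report`.
#' @param out_dir destination directory.
#' @export
write_eval_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$per_image, file.path(out_dir, "per_image.csv"))
  summ <- c(as.list(report$classification), as.list(report$summary))
  if (!is.null(report$agreement))
    summ <- c(summ, list(pearson_r = report$agreement$pearson_r,
                         mean_diff = report$agreement$mean_diff,
                         sd_diff = report$agreement$sd_diff,
                         loa_low = report$agreement$loa_low,
                         loa_high = report$agreement$loa_high,
                         pct_within_loa = report$agreement$pct_within_loa))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
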