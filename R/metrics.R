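# Evaluation metrics: classification rates from confusion counts, Dice
# scores, endpoint distances in mm, the PS-axis angle (APT), the absolute
# AoP difference, and Pearson/Bland-Altman agreement statistics.

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, sensitivity and specificity. A metric whose
#' denominator is zero is reported as NA.
#'
#' @param tp,fp,fn,tn nonnegative confusion counts.
#' @return tibble with columns `acc`, `pre`, `sen`, `spe`.
#' @examples
#' classification_metrics(8, 1, 2, 9)  # acc 0.85, pre 8/9, sen 0.8, spe 0.9
#' @export
classification_metrics <- function(tp, fp, fn, tn) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(acc = safe(tp + tn, tp + fp + fn + tn),
                 pre = safe(tp, tp + fp),
                 sen = safe(tp, tp + fn),
                 spe = safe(tn, fp + tn))
}

#' Per-class and pooled Dice scores of a segmentation
#'
#' Dice = 2TP / (2TP + FP + FN) per foreground class, a pooled foreground
#' Dice (micro-averaged TP/FP/FN over classes 1 and 2), and the per-pixel
#' accuracy over all classes. Empty-empty classes score 1.
#'
#' @param pred_mask,true_mask integer label matrices {0, 1, 2}.
#' @return tibble with `dice_ps`, `dice_fh`, `dice_all`, `pixel_acc`.
#' @export
dice_score <- function(pred_mask, true_mask) {
  stopifnot(all(dim(pred_mask) == dim(true_mask)))
  one <- function(cls) {
    p <- pred_mask == cls; y <- true_mask == cls
    tp <- sum(p & y)
    den <- 2 * tp + sum(p & !y) + sum(!p & y)
    if (den == 0) 1 else 2 * tp / den
  }
  tp_all <- sum(pred_mask == true_mask & true_mask > 0)
  fp_all <- sum(pred_mask > 0 & pred_mask != true_mask)
  fn_all <- sum(true_mask > 0 & pred_mask != true_mask)
  den <- 2 * tp_all + fp_all + fn_all
  tibble::tibble(dice_ps = one(1), dice_fh = one(2),
                 dice_all = if (den == 0) 1 else 2 * tp_all / den,
                 pixel_acc = mean(pred_mask == true_mask))
}

#' Euclidean endpoint distance in millimetres
#'
#' @param pred_pt,true_pt (x, y) coordinates in the same (original-image)
#'   frame.
#' @param pixel_spacing_mm mm per pixel.
#' @export
endpoint_distance <- function(pred_pt, true_pt, pixel_spacing_mm = 0.2) {
  sqrt(sum((pred_pt - true_pt)^2)) * pixel_spacing_mm
}

#' Angle between predicted and true PS axis lines (APT)
#'
#' The lines are treated as undirected, so the angle is reported in
#' [0, 90] degrees regardless of endpoint orientation.
#'
#' @param pred_left,pred_right,true_left,true_right endpoint coordinates.
#' @export
apt <- function(pred_left, pred_right, true_left, true_right) {
  u <- c(pred_right[1] - pred_left[1], pred_right[2] - pred_left[2])
  v <- c(true_right[1] - true_left[1], true_right[2] - true_left[2])
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("degenerate PS line: identical endpoints")
  ang <- acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
  min(ang, 180 - ang)
}

#' Absolute AoP difference in degrees
#' @param aop_pred,aop_true angles in degrees.
#' @export
delta_aop <- function(aop_pred, aop_true) abs(aop_pred - aop_true)

#' Pearson / Bland-Altman agreement between two angle series
#'
#' Pearson correlation, the ordinary least-squares line of predicted on
#' reference angles, and Bland-Altman statistics of the differences
#' (predicted - reference): mean, sample SD, limits of agreement
#' mean +/- 1.96 SD, and the percentage of pairs inside the limits.
#'
#' @param pred_angles,true_angles paired vectors (>= 3 finite pairs).
#' @return an `aop_agreement` object; see [tidy()][generics::tidy] and
#'   [autoplot()][ggplot2::autoplot] methods.
#' @export
agreement <- function(pred_angles, true_angles) {
  keep <- is.finite(pred_angles) & is.finite(true_angles)
  x <- true_angles[keep]; y <- pred_angles[keep]
  if (length(x) < 3) stop("agreement needs at least 3 pairs")
  fit <- stats::lm(y ~ x)
  d <- y - x
  m <- mean(d); s <- stats::sd(d)
  lo <- m - 1.96 * s; hi <- m + 1.96 * s
  structure(list(
    n = length(x),
    pearson_r = stats::cor(x, y),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    mean_diff = m, sd_diff = s, loa_low = lo, loa_high = hi,
    pct_within_loa = 100 * mean(d >= lo & d <= hi),
    pred = y, ref = x, fit = fit), class = "aop_agreement")
}

#' @export
print.aop_agreement <- function(x, ...) {
  cat(sprintf(paste0(
    "<aop_agreement> n=%d  R=%.3f  fit y=%.3fx%+.3f\n",
    "  differences: mean %.3f  sd %.3f  LoA [%.3f, %.3f]  %.1f%% within\n"),
    x$n, x$pearson_r, x$slope, x$intercept, x$mean_diff, x$sd_diff,
    x$loa_low, x$loa_high, x$pct_within_loa))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy aop_agreement
tidy.aop_agreement <- function(x, ...) {
  tibble::tibble(
    statistic = c("pearson_r", "slope", "intercept", "mean_diff", "sd_diff",
                  "loa_low", "loa_high", "pct_within_loa"),
    value = c(x$pearson_r, x$slope, x$intercept, x$mean_diff, x$sd_diff,
              x$loa_low, x$loa_high, x$pct_within_loa))
}

#' @export
#' @method glance aop_agreement
glance.aop_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, pearson_r = x$pearson_r, mean_diff = x$mean_diff,
                 sd_diff = x$sd_diff, loa_low = x$loa_low,
                 loa_high = x$loa_high)
}

#' Bland-Altman plot of an agreement object
#'
#' @param object an `aop_agreement`.
#' @param ... unused.
#' @export
#' @method autoplot aop_agreement
autoplot.aop_agreement <- function(object, ...) {
  df <- tibble::tibble(mean = (object$pred + object$ref) / 2,
                       diff = object$pred - object$ref)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = 2) +
    ggplot2::labs(x = "mean of automatic and reference AoP (deg)",
                  y = "difference (deg)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of predicted versus reference AoP with the fitted line
#' @param object an `aop_agreement`.
#' @export
plot_aop_regression <- function(object) {
  df <- tibble::tibble(ref = object$ref, pred = object$pred)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ref, y = .data$pred)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::labs(x = "reference AoP (deg)", y = "automatic AoP (deg)",
                  title = sprintf("R = %.3f", object$pearson_r)) +
    ggplot2::theme_minimal()
}
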