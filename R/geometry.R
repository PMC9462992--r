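# Ellipse-fit / tangent geometry turning a segmentation mask plus the two
# pubic-symphysis endpoints into the angle of progression.
#
# All coordinates are 0-based pixel coordinates, x rightward, y downward,
# pixel centers at integer positions. Angles returned in degrees. The AoP is
# measured at the right (inferior) PS endpoint, between the ray toward the
# left endpoint and the ray toward the tangent point on the fetal-head
# ellipse, so it is invariant under rigid motions and uniform scaling.

#' Construct an ellipse
#'
#' Geometric parameterization (center, semi-axes, orientation) together with
#' the conic form \eqn{Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0}, normalized so
#' that \eqn{4AC - B^2 = 1} and the interior is negative.
#'
#' @param center numeric length-2, ellipse center (x, y) in pixels.
#' @param a,b semi-major and semi-minor axes in pixels; `a >= b > 0`.
#' @param angle_deg orientation of the major axis versus +x, degrees.
#' @return An object of class `aop_ellipse` with fields `center`, `a`, `b`,
#'   `angle_deg` and `conic` (named A..F).
#' @examples
#' e <- ellipse(c(3, 4), a = 5, b = 2, angle_deg = 30)
#' conic_value(e$conic, 3, 4) < 0  # center is interior
#' @export
ellipse <- function(center, a, b, angle_deg) {
  stopifnot(length(center) == 2, a >= b, b > 0)
  structure(
    list(center = as.numeric(center), a = a, b = b,
         angle_deg = angle_deg %% 180,
         conic = ellipse_to_conic(center, a, b, angle_deg)),
    class = "aop_ellipse")
}

#' @export
print.aop_ellipse <- function(x, ...) {
  cat(sprintf("<ellipse> center=(%.3f, %.3f)  a=%.3f  b=%.3f  angle=%.2f deg\n",
              x$center[1], x$center[2], x$a, x$b, x$angle_deg))
  invisible(x)
}

#' Conic coefficients of an ellipse
#'
#' @inheritParams ellipse
#' @return named numeric vector (A, B, C, D, E, F) with `4AC - B^2 = 1` and
#'   negative values inside the ellipse.
#' @export
ellipse_to_conic <- function(center, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  Ap <- ct^2 / a^2 + st^2 / b^2
  Cp <- st^2 / a^2 + ct^2 / b^2
  Bp <- 2 * ct * st * (1 / a^2 - 1 / b^2)
  x0 <- center[1]; y0 <- center[2]
  co <- c(A = Ap, B = Bp, C = Cp,
          D = -2 * Ap * x0 - Bp * y0,
          E = -Bp * x0 - 2 * Cp * y0,
          F = Ap * x0^2 + Bp * x0 * y0 + Cp * y0^2 - 1)
  co / sqrt(4 * Ap * Cp - Bp^2)
}

#' Evaluate a conic at a point
#' @param conic named numeric vector (A, B, C, D, E, F).
#' @param x,y coordinates (vectorized).
#' @export
conic_value <- function(conic, x, y) {
  conic[["A"]] * x^2 + conic[["B"]] * x * y + conic[["C"]] * y^2 +
    conic[["D"]] * x + conic[["E"]] * y + conic[["F"]]
}

#' Recover the geometric ellipse from conic coefficients
#'
#' @param conic named numeric vector (A, B, C, D, E, F) with
#'   \eqn{B^2 - 4AC < 0}.
#' @return an `aop_ellipse`.
#' @export
conic_to_ellipse <- function(conic) {
  co <- as.numeric(conic)
  names(co) <- c("A", "B", "C", "D", "E", "F")
  if (co[["B"]]^2 - 4 * co[["A"]] * co[["C"]] >= 0)
    stop("conic is not an ellipse (B^2 - 4AC >= 0)")
  if (co[["A"]] + co[["C"]] < 0) co <- -co  # interior-negative convention
  den <- co[["B"]]^2 - 4 * co[["A"]] * co[["C"]]
  x0 <- (2 * co[["C"]] * co[["D"]] - co[["B"]] * co[["E"]]) / den
  y0 <- (2 * co[["A"]] * co[["E"]] - co[["B"]] * co[["D"]]) / den
  f0 <- conic_value(co, x0, y0)
  if (f0 >= 0) stop("degenerate conic: no real ellipse")
  M2 <- matrix(c(co[["A"]], co[["B"]] / 2, co[["B"]] / 2, co[["C"]]), 2, 2)
  ei <- eigen(M2, symmetric = TRUE)          # values decreasing
  ax <- sqrt(-f0 / ei$values)                # minor (big lambda) first
  vmaj <- ei$vectors[, 2]                    # eigenvector of smaller lambda
  ellipse(c(x0, y0), a = ax[2], b = ax[1],
          angle_deg = (atan2(vmaj[2], vmaj[1]) * 180 / pi) %% 180)
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic \eqn{Ax^2+Bxy+Cy^2+Dx+Ey+F=0} to scattered points under
#' the ellipse-specific constraint \eqn{4AC-B^2=1}, using the numerically
#' stable block decomposition of the direct method (data are centered before
#' solving). Always returns an ellipse, never a hyperbola.
#'
#' @param points two-column matrix or data frame of (x, y) coordinates;
#'   at least 5 non-collinear points.
#' @return an `aop_ellipse`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 50)
#' fit_ellipse(cbind(3 + 5 * cos(th), 4 + 2 * sin(th)))
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  if (nrow(pts) < 5) stop("ellipse fit needs at least 5 points")
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  x <- pts[, 1] - mx; y <- pts[, 2] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("ellipse fit failed: degenerate (collinear?) points"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ei <- eigen(M)
  cand <- NULL
  for (j in 1:3) {
    v <- ei$vectors[, j]
    if (any(Im(v) != 0)) next
    v <- Re(v)
    cond <- 4 * v[1] * v[3] - v[2]^2
    if (cond > 0) { cand <- v / sqrt(cond); break }
  }
  if (is.null(cand)) stop("ellipse fit failed: no elliptical solution")
  a1 <- cand
  a2 <- as.numeric(Tm %*% a1)
  co <- c(a1, a2)
  # undo the centering shift
  co <- c(A = co[1], B = co[2], C = co[3],
          D = co[4] - 2 * co[1] * mx - co[2] * my,
          E = co[5] - co[2] * mx - 2 * co[3] * my,
          F = co[6] + co[1] * mx^2 + co[2] * mx * my + co[3] * my^2 -
            co[4] * mx - co[5] * my)
  conic_to_ellipse(co)
}

#' Tangency points of an external point
#'
#' Intersects the polar line (chord of contact) of `p` with the ellipse,
#' yielding the two points where lines through `p` touch the ellipse.
#'
#' @param e an `aop_ellipse`.
#' @param p numeric length-2 external point (x, y).
#' @return 2 x 2 matrix, one tangency point per row.
#' @export
tangent_points <- function(e, p) {
  co <- e$conic
  if (conic_value(co, p[1], p[2]) <= 0)
    stop("no tangent: point is inside or on the ellipse")
  M3 <- matrix(c(co[["A"]], co[["B"]] / 2, co[["D"]] / 2,
                 co[["B"]] / 2, co[["C"]], co[["E"]] / 2,
                 co[["D"]] / 2, co[["E"]] / 2, co[["F"]]), 3, 3)
  l <- as.numeric(M3 %*% c(p[1], p[2], 1))  # polar line l1 x + l2 y + l3 = 0
  A <- co[["A"]]; B <- co[["B"]]; C <- co[["C"]]
  D <- co[["D"]]; E <- co[["E"]]; F <- co[["F"]]
  if (abs(l[1]) >= abs(l[2])) {
    # x = -(l2 y + l3) / l1
    u <- -l[2] / l[1]; v <- -l[3] / l[1]
    qa <- A * u^2 + B * u + C
    qb <- 2 * A * u * v + B * v + D * u + E
    qc <- A * v^2 + D * v + F
    ys <- quad_roots(qa, qb, qc)
    out <- cbind(u * ys + v, ys)
  } else {
    u <- -l[1] / l[2]; v <- -l[3] / l[2]
    qa <- C * u^2 + B * u + A
    qb <- 2 * C * u * v + B * v + E * u + D
    qc <- C * v^2 + E * v + F
    xs <- quad_roots(qa, qb, qc)
    out <- cbind(xs, u * xs + v)
  }
  colnames(out) <- c("x", "y")
  out
}

quad_roots <- function(a, b, c) {
  disc <- b^2 - 4 * a * c
  if (disc < 0) {
    if (disc < -1e-9 * max(b^2, abs(4 * a * c), 1))
      stop("polar line does not meet the ellipse")
    disc <- 0
  }
  q <- -0.5 * (b + sign(b + (b == 0)) * sqrt(disc))
  r1 <- q / a
  r2 <- if (q != 0) c / q else r1
  c(r1, r2)
}

#' Normalized tangency discriminant
#'
#' Substitutes the line through `p` and `tp` into the conic of `e`; for a
#' true tangent the quadratic in the line parameter has a double root, so
#' the returned relative discriminant is ~0.
#'
#' @param e an `aop_ellipse`.
#' @param p external point; @param tp candidate tangency point.
#' @return nonnegative scalar; <= 1e-6 certifies tangency.
#' @export
tangency_discriminant <- function(e, p, tp) {
  co <- e$conic
  dx <- tp[1] - p[1]; dy <- tp[2] - p[2]
  qa <- co[["A"]] * dx^2 + co[["B"]] * dx * dy + co[["C"]] * dy^2
  qb <- 2 * co[["A"]] * p[1] * dx + co[["B"]] * (p[1] * dy + p[2] * dx) +
    2 * co[["C"]] * p[2] * dy + co[["D"]] * dx + co[["E"]] * dy
  qc <- conic_value(co, p[1], p[2])
  abs(qb^2 - 4 * qa * qc) / (qb^2 + abs(4 * qa * qc) + .Machine$double.eps)
}

#' Angle of progression from three key points
#'
#' The angle at the right (inferior) PS endpoint between the ray toward the
#' left PS endpoint and the ray toward the fetal-head tangent point.
#'
#' @param left,right the two PS endpoints (x, y).
#' @param tangent the tangent point (x, y).
#' @return angle in degrees, in (0, 180].
#' @examples
#' compute_aop(c(0, 0), c(10, 0), c(10, 10))  # 90
#' @export
compute_aop <- function(left, right, tangent) {
  u <- c(left[1] - right[1], left[2] - right[2])
  v <- c(tangent[1] - right[1], tangent[2] - right[2])
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("coincident points: AoP undefined")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Select the AoP tangent among the two candidates
#'
#' Keeps the candidate tangency point along the leading (distal) fetal-head
#' contour: by default the one yielding the larger angle at the right
#' endpoint. Ties are broken toward larger y.
#'
#' @param candidates 2 x 2 matrix from [tangent_points()].
#' @param left,right the PS endpoints.
#' @param rule `"max-angle"` (default) or `"min-angle"`.
#' @return numeric length-2 tangency point.
#' @export
select_tangent <- function(candidates, left, right, rule = c("max-angle", "min-angle")) {
  rule <- match.arg(rule)
  angs <- apply(candidates, 1, function(tp) compute_aop(left, right, tp))
  if (abs(angs[1] - angs[2]) < 1e-9) {
    i <- which.max(candidates[, 2])
  } else {
    i <- if (rule == "max-angle") which.max(angs) else which.min(angs)
  }
  as.numeric(candidates[i, ])
}

#' Outer boundary of the largest region of a mask class
#'
#' Selects the largest connected component of `class_id` in the label mask
#' and returns its ordered outer contour.
#'
#' @param mask integer matrix, rows = y, cols = x, values in {0, 1, 2}.
#' @param class_id the class to trace (2 = fetal head by convention).
#' @return two-column matrix of 0-based (x, y) contour points.
#' @export
mask_boundary <- function(mask, class_id) {
  bw <- t(mask == class_id) * 1  # EBImage convention: first dim x
  if (sum(bw) < 5) stop("no region: fewer than 5 pixels of class ", class_id)
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  keep <- which.max(tab)
  oc <- EBImage::ocontour(EBImage::Image((EBImage::imageData(lab) == keep) * 1))
  pts <- oc[[which.max(vapply(oc, nrow, 0L))]]
  colnames(pts) <- c("x", "y")
  if (nrow(pts) < 5) stop("boundary underdetermined: fewer than 5 points")
  pts
}

# Fit an ellipse to rasterized boundary pixel centers with a half-pixel
# outward correction: centers of boundary pixels sit ~0.5 px inside the true
# region edge, so a first fit provides the outward normal (conic gradient)
# along which each point is pushed before the final fit.
fit_ellipse_raster <- function(pts, offset = 0.5) {
  e0 <- fit_ellipse(pts)
  co <- e0$conic
  gx <- 2 * co[["A"]] * pts[, 1] + co[["B"]] * pts[, 2] + co[["D"]]
  gy <- co[["B"]] * pts[, 1] + 2 * co[["C"]] * pts[, 2] + co[["E"]]
  nrm <- sqrt(gx^2 + gy^2)
  keep <- nrm > 0
  pts2 <- pts
  pts2[keep, 1] <- pts[keep, 1] + offset * gx[keep] / nrm[keep]
  pts2[keep, 2] <- pts[keep, 2] + offset * gy[keep] / nrm[keep]
  fit_ellipse(pts2)
}

#' Measure the angle of progression from a mask and PS endpoints
#'
#' Composes boundary extraction, direct least-squares ellipse fitting,
#' tangent construction from the right endpoint and tangent selection into
#' the final angle. Any stage failure is reported, not raised.
#'
#' @param mask label matrix (rows = y) with fetal-head pixels = `fh_class`.
#' @param left,right PS endpoints, 0-based (x, y).
#' @param fh_class mask value of the fetal head (default 2).
#' @param rule tangent selection rule, see [select_tangent()].
#' @return an `aop_result`: list with `left_endpoint`, `right_endpoint`,
#'   `tangent_point`, `aop_deg`, `ellipse`, `valid`, `reason`.
#' @export
measure_aop <- function(mask, left, right, fh_class = 2, rule = "max-angle") {
  fail <- function(reason) structure(
    list(left_endpoint = left, right_endpoint = right, tangent_point = NULL,
         aop_deg = NA_real_, ellipse = NULL, valid = FALSE, reason = reason),
    class = "aop_result")
  bnd <- tryCatch(mask_boundary(mask, fh_class), error = function(e) NULL)
  if (is.null(bnd)) return(fail("no FH region"))
  e <- tryCatch(fit_ellipse_raster(bnd), error = function(e) NULL)
  if (is.null(e)) return(fail("ellipse fit failed"))
  tps <- tryCatch(tangent_points(e, right), error = function(e) NULL)
  if (is.null(tps)) return(fail("no tangent"))
  res <- tryCatch({
    tp <- select_tangent(tps, left, right, rule)
    list(tp = tp, aop = compute_aop(left, right, tp))
  }, error = function(e) NULL)
  if (is.null(res)) return(fail("degenerate key points"))
  structure(
    list(left_endpoint = as.numeric(left), right_endpoint = as.numeric(right),
         tangent_point = res$tp, aop_deg = res$aop,
         ellipse = e, valid = TRUE, reason = NA_character_),
    class = "aop_result")
}

#' @export
print.aop_result <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<aop_result> AoP = %.2f deg  tangent=(%.2f, %.2f)\n",
                x$aop_deg, x$tangent_point[1], x$tangent_point[2]))
  } else {
    cat(sprintf("<aop_result> invalid (%s)\n", x$reason))
  }
  invisible(x)
}

#' @export
#' @method as_tibble aop_result
as_tibble.aop_result <- function(x, ...) {
  tibble::tibble(
    xl = x$left_endpoint[1], yl = x$left_endpoint[2],
    xr = x$right_endpoint[1], yr = x$right_endpoint[2],
    xt = if (x$valid) x$tangent_point[1] else NA_real_,
    yt = if (x$valid) x$tangent_point[2] else NA_real_,
    aop_deg = x$aop_deg, valid = x$valid, reason = x$reason)
}
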